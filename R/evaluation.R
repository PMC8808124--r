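#' One-vs-rest confusion counts
#'
#' Tallies TP/TN/FP/FN for one positive class against the rest.
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param positive the class treated as positive.
#' @return object of class `confusion_counts` (named integer vector).
#' @export
confusion_counts <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  structure(c(TP = tp, TN = tn, FP = fp, FN = fn), class = "confusion_counts")
}

counts_vec <- function(c) {
  if (inherits(c, "confusion_counts") ||
      (is.numeric(c) && all(c("TP", "TN", "FP", "FN") %in% names(c))))
    return(as.numeric(c[c("TP", "TN", "FP", "FN")]))
  stop("expected confusion_counts or a named TP/TN/FP/FN vector")
}

#' Evaluation index A
#'
#' `A = (TP + TN) / (TP + TN + FP + FN)`: the fraction of windows whose
#' one-vs-rest decision is correct. (This is the quantity commonly called
#' accuracy; it is reported here under the name A.)
#'
#' @param c a [confusion_counts()].
#' @return fraction in `[0, 1]`.
#' @export
precision_A <- function(c) {
  v <- counts_vec(c)
  if (sum(v) == 0) stop("undefined metric: empty counts")
  (v[1] + v[2]) / sum(v)
}

#' Evaluation index R
#'
#' As printed in the protocol this package follows, `R = TP / (TP + FP)`
#' (the denominator usually associated with precision); the conventional
#' recall `TP / (TP + FN)` is available via
#' `convention = "tp_fn"`.
#'
#' @param c a [confusion_counts()].
#' @param convention `"as_printed"` (TP/(TP+FP), default) or `"tp_fn"`
#'   (TP/(TP+FN)).
#' @return fraction in `[0, 1]`.
#' @export
recall_R <- function(c, convention = c("as_printed", "tp_fn")) {
  convention <- match.arg(convention)
  v <- counts_vec(c)
  den <- if (convention == "as_printed") v[1] + v[3] else v[1] + v[4]
  if (den == 0) stop("undefined metric: zero denominator for R")
  v[1] / den
}

#' F1 value
#'
#' Harmonic mean `2 A R / (A + R)` of the two indices above. When both
#' are zero the value is defined as 0 with a warning.
#'
#' @param c a [confusion_counts()].
#' @inheritParams recall_R
#' @export
f1_score <- function(c, convention = c("as_printed", "tp_fn")) {
  A <- precision_A(c)
  R <- recall_R(c, convention)
  if (A + R == 0) {
    warning("A + R = 0; F1 defined as 0")
    return(0)
  }
  2 * A * R / (A + R)
}

#' Per-class and macro-averaged metrics for multi-class predictions
#'
#' Computes one-vs-rest counts per class and the unweighted macro average
#' of A, R and F1, plus the plain multi-class accuracy (fraction of
#' correctly labeled windows).
#'
#' @param truth,pred character vectors of labels.
#' @param classes class set (default: union of labels observed).
#' @inheritParams recall_R
#' @return list with `per_class` (data.frame class/TP/TN/FP/FN/A/R/F1),
#'   `macro` (named vector A/R/F1) and `accuracy`.
#' @export
evaluate_predictions <- function(truth, pred, classes = NULL,
                                 convention = c("as_printed", "tp_fn")) {
  convention <- match.arg(convention)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(truth, pred, cl)
    A <- precision_A(cc)
    R <- tryCatch(recall_R(cc, convention), error = function(e) NA_real_)
    F1 <- if (is.na(R) || A + R == 0) 0 else 2 * A * R / (A + R)
    data.frame(class = cl, TP = cc["TP"], TN = cc["TN"], FP = cc["FP"],
               FN = cc["FN"], A = A, R = R, F1 = F1, row.names = NULL)
  })
  per_class <- do.call(rbind, rows)
  macro <- c(A = mean(per_class$A), R = mean(per_class$R, na.rm = TRUE),
             F1 = mean(per_class$F1))
  list(per_class = per_class, macro = macro,
       accuracy = mean(truth == pred))
}

#' Trimmed fold aggregation
#'
#' The cross-validation protocol discards the single best and single worst
#' fold values before averaging (guarding against one user with unusually
#' good or bad data). With fewer than 4 folds a plain mean is returned
#' with a warning.
#'
#' @param x numeric vector of per-fold values.
#' @return scalar aggregate.
#' @export
trimmed_fold_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    warning("fewer than 4 folds; plain mean used instead of trimmed mean")
    return(mean(x))
  }
  s <- sort(x)
  mean(s[2:(length(s) - 1)])
}

#' Leave-one-subject-out evaluation
#'
#' Trains a model on each fold's training windows, predicts the held-out
#' user's windows, computes per-fold macro metrics, and aggregates each
#' metric across folds with [trimmed_fold_mean()].
#'
#' @param folds folds from [loso_split()].
#' @param train_fn function `(train_windows) -> fitted model` accepted by
#'   `predict_fn`.
#' @param predict_fn function `(model, windows) -> character labels`
#'   (default [cnn_predict()]).
#' @inheritParams recall_R
#' @return list with `per_fold` (data.frame user/A/R/F1/accuracy/
#'   stop_reason), `aggregate` (named vector of trimmed fold means) and
#'   `models` (the per-fold fitted models).
#' @export
loso_evaluate <- function(folds, train_fn, predict_fn = cnn_predict,
                          convention = c("as_printed", "tp_fn")) {
  convention <- match.arg(convention)
  rows <- list(); models <- list()
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    model <- train_fn(f$train)
    models[[f$user]] <- model
    truth <- vapply(f$validation, function(w) w$label, character(1))
    pred <- predict_fn(model, f$validation)
    ev <- evaluate_predictions(truth, pred, convention = convention)
    sr <- attr(model, "stop_reason")
    rows[[i]] <- data.frame(user = f$user, A = ev$macro["A"], R = ev$macro["R"],
                            F1 = ev$macro["F1"], accuracy = ev$accuracy,
                            stop_reason = if (is.null(sr)) NA_character_ else sr,
                            row.names = NULL)
  }
  per_fold <- do.call(rbind, rows)
  aggregate <- c(A = trimmed_fold_mean(per_fold$A),
                 R = trimmed_fold_mean(per_fold$R),
                 F1 = trimmed_fold_mean(per_fold$F1),
                 accuracy = trimmed_fold_mean(per_fold$accuracy))
  list(per_fold = per_fold, aggregate = aggregate, models = models)
}
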
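#' Cut a labeled stream into fixed-length windows
#'
#' Slides a fixed window over the sample axis, either without overlap
#' (stride = `window_len`) or with half overlap (stride = `window_len / 2`).
#' Trailing samples that do not fill a window are dropped, so a stream of
#' length `L` yields `floor(L / window_len)` non-overlapping windows, or
#' `floor((L - window_len) / (window_len / 2)) + 1` half-overlapping
#' windows when `L >= window_len`. Each window is labeled with the
#' majority label of its samples; ties go to the label occurring earliest
#' within the window.
#'
#' @param seq a labeled [imu_sequence()].
#' @param window_len window length in samples (`>= 2`; even for
#'   `half_overlap`).
#' @param mode `"nonoverlap"` or `"half_overlap"`.
#' @param channels channel columns to place in the window matrix: a
#'   character vector of column names, or `NULL` for all nine sensor
#'   channels (the generator's `signal_channels` attribute, when present,
#'   is used as the default).
#' @param max_minority optional fraction in `[0, 1)`: windows whose
#'   non-majority labels exceed this fraction are discarded. `NULL`
#'   (default) keeps every window.
#' @return list of `labeled_window` objects, each a list with `data`
#'   (channels x window_len matrix), `label`, `user_id` and `start`
#'   (0-based start sample).
#' @export
slice_windows <- function(seq, window_len, mode = c("nonoverlap", "half_overlap"),
                          channels = NULL, max_minority = NULL) {
  stopifnot(inherits(seq, "imu_sequence"))
  mode <- match.arg(mode)
  if (window_len < 2 || window_len != round(window_len))
    stop("window_len must be an integer >= 2")
  if (mode == "half_overlap" && window_len %% 2 != 0)
    stop("window_len must be even for half-overlap slicing")
  if (is.null(seq$labels)) stop("sequence must carry per-sample labels")
  if (is.null(channels)) {
    channels <- attr(seq, "signal_channels")
    if (is.null(channels)) channels <- imu_channel_names()
  }
  if (!all(channels %in% names(seq$data)))
    stop("unknown channel(s): ",
         paste(setdiff(channels, names(seq$data)), collapse = ", "))
  L <- nrow(seq$data)
  if (L < window_len) {
    warning("stream shorter than one window; no windows produced")
    return(list())
  }
  stride <- if (mode == "nonoverlap") window_len else window_len %/% 2
  starts <- seq.int(0L, L - window_len, by = stride)
  X <- t(as.matrix(seq$data[channels]))
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):(starts[i] + window_len)
    labs <- seq$labels[idx]
    counts <- table(factor(labs, levels = unique(labs)))  # unique(): earliest first
    label <- names(counts)[which.max(counts)]             # ties -> earliest label
    minority <- 1 - max(counts) / window_len
    keep[i] <- is.null(max_minority) || minority <= max_minority
    out[[i]] <- structure(list(data = X[, idx, drop = FALSE], label = label,
                               user_id = seq$user_id, start = starts[i]),
                          class = "labeled_window")
  }
  out[keep]
}

#' Leave-one-subject-out folds
#'
#' One fold per distinct user: the fold's validation set is exactly that
#' user's windows and its training set is everything else, so the two
#' sides partition the input and no user ever appears on both.
#'
#' @param windows list of `labeled_window` objects (from
#'   [slice_windows()]) covering at least two distinct users.
#' @return list of folds, each `list(user, train, validation)` where
#'   `train` and `validation` are lists of windows.
#' @export
loso_split <- function(windows) {
  users <- vapply(windows, function(w) w$user_id, character(1))
  uu <- unique(users)
  if (length(uu) < 2)
    stop("leave-one-subject-out requires at least 2 distinct users")
  lapply(uu, function(u) {
    list(user = u,
         train = windows[users != u],
         validation = windows[users == u])
  })
}
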
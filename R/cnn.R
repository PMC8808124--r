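#' Multiply-accumulate primitive
#'
#' The innermost convolution operation: `N` feature values and `N` weights
#' are multiplied pairwise and the products accumulated.
#'
#' @param features,weights numeric vectors of equal length.
#' @return scalar sum of products.
#' @export
conv_mac <- function(features, weights) {
  if (length(features) != length(weights))
    stop("features and weights must have equal length")
  sum(features * weights)
}

#' Convolution layer hyper-parameters
#'
#' @param kernel_size `c(kh, kw)` kernel height and width.
#' @param kernels number of kernels `K` (output channels).
#' @param tile_n channel tile width `N`: input channels are processed in
#'   groups of `N`, partial sums accumulated along the channel direction.
#' @param stride convolution stride (both axes).
#' @param padding zero padding (both axes).
#' @return object of class `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kernel_size = c(3, 3), kernels = 8, tile_n = 4,
                            stride = 1, padding = 0) {
  v <- c(kernel_size, kernels, tile_n, stride)
  if (any(v < 1) || any(v != round(v)) || padding < 0 || padding != round(padding))
    stop("kernel_size, kernels, tile_n and stride must be positive integers; padding nonnegative")
  structure(list(kernel_size = as.integer(kernel_size),
                 kernels = as.integer(kernels), tile_n = as.integer(tile_n),
                 stride = as.integer(stride), padding = as.integer(padding)),
            class = "conv_layer_spec")
}

# Lift a CH x W matrix (time-series window) to a CH x 1 x W feature tensor.
as_feature_tensor <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), 1L, ncol(x))) else x
}

# im2col for a CH x H x W tensor: returns a (CH*kh*kw) x (Ho*Wo) matrix
# whose column j holds the receptive field of output position j (output
# positions ordered column-major, h fastest). Row ordering is ch fastest,
# then kernel row u, then kernel column v, matching as.vector(W[k, , , ]).
im2col2d <- function(x, kh, kw, stride = 1L, padding = 0L) {
  d <- dim(x); CH <- d[1]; H <- d[2]; W <- d[3]
  if (padding > 0) {
    xp <- array(0, c(CH, H + 2 * padding, W + 2 * padding))
    xp[, padding + seq_len(H), padding + seq_len(W)] <- x
    x <- xp; H <- H + 2 * padding; W <- W + 2 * padding
  }
  Ho <- (H - kh) %/% stride + 1L
  Wo <- (W - kw) %/% stride + 1L
  if (Ho < 1 || Wo < 1) stop("kernel larger than (padded) input")
  M <- matrix(0, CH * kh * kw, Ho * Wo)
  hs <- (0:(Ho - 1)) * stride
  ws <- (0:(Wo - 1)) * stride
  for (v in seq_len(kw)) {
    for (u in seq_len(kh)) {
      blk <- (v - 1L) * kh + (u - 1L)
      M[(blk * CH + 1):(blk * CH + CH), ] <-
        matrix(x[, u + hs, v + ws, drop = FALSE], CH, Ho * Wo)
    }
  }
  M
}

#' Channel-tiled multi-filter convolution
#'
#' Computes a dense 2-D convolution by the channel-tiled schedule: the
#' input channels are split into tiles of width `tile_n` (a shorter tail
#' tile when `CH` is not divisible), each tile's partial sums over all
#' kernel positions are computed for all `K` kernels at once, and the tile
#' results are accumulated along the channel direction. The schedule is a
#' dataflow choice only — the result equals direct dense convolution.
#'
#' @param x feature tensor, `CH x H x W` array (a `CH x W` matrix is
#'   treated as `H = 1`).
#' @param kernels weight array `K x CH x kh x kw`.
#' @param spec a [conv_layer_spec()]; its `kernel_size` and `kernels`
#'   must agree with `dim(kernels)`.
#' @return output feature tensor, `K x Ho x Wo` array.
#' @export
conv2d_tiled <- function(x, kernels, spec = conv_layer_spec(kernel_size = dim(kernels)[3:4],
                                                           kernels = dim(kernels)[1])) {
  x <- as_feature_tensor(x)
  kd <- dim(kernels)
  if (length(kd) != 4) stop("kernels must be a K x CH x kh x kw array")
  K <- kd[1]; CH <- kd[2]; kh <- kd[3]; kw <- kd[4]
  if (dim(x)[1] != CH)
    stop("kernel channel count (", CH, ") must equal input channels (", dim(x)[1], ")")
  if (K != spec$kernels || any(kd[3:4] != spec$kernel_size))
    stop("spec does not match kernel dimensions")
  N <- min(spec$tile_n, CH)
  tiles <- split(seq_len(CH), ceiling(seq_len(CH) / N))
  out <- NULL
  for (tile in tiles) {
    xt <- x[tile, , , drop = FALSE]
    M <- im2col2d(xt, kh, kw, spec$stride, spec$padding)
    Wf <- matrix(0, K, length(tile) * kh * kw)
    for (k in seq_len(K)) Wf[k, ] <- as.vector(kernels[k, tile, , , drop = FALSE])
    part <- Wf %*% M
    out <- if (is.null(out)) part else out + part
  }
  d <- dim(x)
  Hp <- d[2] + 2 * spec$padding; Wp <- d[3] + 2 * spec$padding
  Ho <- (Hp - kh) %/% spec$stride + 1L
  Wo <- (Wp - kw) %/% spec$stride + 1L
  array(out, c(K, Ho, Wo))
}

#' Two-stage max pooling
#'
#' `n x n` max pooling with stride `n`, factored into a horizontal pass
#' (each run of `n` values along a row is reduced to its maximum, width
#' becomes `floor(W/n)`) followed by a vertical pass (elementwise maximum
#' over groups of `n` rows, height becomes `floor(H/n)`). Incomplete edge
#' blocks are dropped. Equivalent to the naive `n x n` block maximum.
#'
#' @param x feature tensor `CH x H x W` (matrix treated as `H = 1`).
#' @param n pooling factor (`n = 1` is the identity). A length-2 vector
#'   `c(nh, nw)` pools rectangular `nh x nw` blocks, which the reference
#'   model uses to pool height-1 feature maps along time only.
#' @return pooled tensor `CH x floor(H/nh) x floor(W/nw)`.
#' @export
maxpool_two_stage <- function(x, n) {
  x <- as_feature_tensor(x)
  if (any(n < 1) || any(n != round(n)) || !length(n) %in% 1:2)
    stop("n must be one or two positive integers")
  n <- rep(as.integer(n), length.out = 2)
  nh <- n[1]; nw <- n[2]
  d <- dim(x); CH <- d[1]; H <- d[2]; W <- d[3]
  Hp <- H %/% nh; Wp <- W %/% nw
  if (Hp < 1 || Wp < 1) {
    warning("input smaller than one pooling block; empty output")
    return(array(numeric(0), c(CH, max(Hp, 0), max(Wp, 0))))
  }
  # horizontal pass: max over runs of nw along width
  mid <- array(-Inf, c(CH, H, Wp))
  for (j in seq_len(nw)) mid <- pmax(mid, x[, , (seq_len(Wp) - 1) * nw + j, drop = FALSE])
  # vertical pass: elementwise max over groups of nh rows
  out <- array(-Inf, c(CH, Hp, Wp))
  for (i in seq_len(nh)) out <- pmax(out, mid[, (seq_len(Hp) - 1) * nh + i, , drop = FALSE])
  out
}

#' Training protocol configuration
#'
#' Adadelta with a global learning-rate multiplier, cross-entropy loss,
#' and the early-stopping rule: training ends when the full-training-set
#' loss drops to `loss_stop` or after `max_iterations` iterations
#' (epochs), whichever comes first.
#'
#' @param learning_rate global multiplier applied to the Adadelta update.
#' @param rho Adadelta accumulator decay.
#' @param epsilon Adadelta stabilizer; also sets the warm-up step scale
#'   (the first step is about `learning_rate * sqrt(epsilon)` per unit
#'   gradient), which is why the default is larger than the value
#'   customary when the learning rate is 1.
#' @param max_iterations iteration (epoch) cap.
#' @param loss_stop stopping threshold on the mean training cross-entropy.
#' @param batch_size minibatch size; batches are taken in fixed order so
#'   training is deterministic.
#' @param seed integer seed for weight initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, rho = 0.95, epsilon = 1e-2,
                         max_iterations = 200, loss_stop = 0.2,
                         batch_size = 4, seed = 1L) {
  if (loss_stop <= 0) stop("loss_stop must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 loss_stop = loss_stop, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Construct the reference CNN classifier
#'
#' One channel-tiled convolution layer, a ReLU nonlinearity, two-stage
#' `n x n` max pooling, and a dense softmax classifier. Sensor windows
#' enter as `channels x width` features with height 1 by default, so the
#' convolution covers the 1-D-over-time case; the kernel height is capped
#' at the input height.
#'
#' @param input_shape `c(channels, height, width)` of one window (or
#'   `c(channels, width)`, implying height 1).
#' @param classes character vector of class labels (order fixes the
#'   output units).
#' @param conv a [conv_layer_spec()]; its kernel height is capped at the
#'   input height.
#' @param pool_n pooling factor.
#' @param activation `"relu"` or `"identity"`.
#' @param seed integer seed for the symmetric uniform fan-in-scaled
#'   weight initialization.
#' @return object of class `cnn_model`.
#' @export
cnn_model <- function(input_shape, classes, conv = conv_layer_spec(),
                      pool_n = 2, activation = c("relu", "identity"),
                      seed = 1L) {
  activation <- match.arg(activation)
  if (length(input_shape) == 2) input_shape <- c(input_shape[1], 1L, input_shape[2])
  stopifnot(length(input_shape) == 3, length(classes) >= 2)
  CH <- input_shape[1]; H <- input_shape[2]; W <- input_shape[3]
  kh <- min(conv$kernel_size[1], H); kw <- conv$kernel_size[2]
  conv <- conv_layer_spec(kernel_size = c(kh, kw), kernels = conv$kernels,
                          tile_n = conv$tile_n, stride = conv$stride,
                          padding = conv$padding)
  Ho <- (H + 2 * conv$padding - kh) %/% conv$stride + 1L
  Wo <- (W + 2 * conv$padding - kw) %/% conv$stride + 1L
  if (Ho < 1 || Wo < 1) stop("kernel larger than input")
  pool_n <- rep(as.integer(pool_n), length.out = 2)
  pool_n[1] <- min(pool_n[1], Ho)   # cap block height at the feature map
  Hp <- Ho %/% pool_n[1]; Wp <- Wo %/% pool_n[2]
  if (Hp < 1 || Wp < 1) stop("pooled feature map is empty; reduce pool_n")
  K <- conv$kernels
  nfeat <- K * Hp * Wp
  C <- length(classes)
  set.seed(seed)
  fan_c <- CH * kh * kw
  kernels <- array(stats::runif(K * fan_c, -1, 1) / sqrt(fan_c), c(K, CH, kh, kw))
  Wd <- matrix(stats::runif(C * nfeat, -1, 1) / sqrt(nfeat), C, nfeat)
  structure(list(kernels = kernels, conv_bias = rep(0, K),
                 dense_w = Wd, dense_b = rep(0, C),
                 classes = as.character(classes), conv = conv,
                 pool_n = as.integer(pool_n), activation = activation,
                 input_shape = as.integer(c(CH, H, W)),
                 dims = list(Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, nfeat = nfeat)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> input %s; conv %dx%d x%d (tile %d) -> %s -> pool %s -> dense %d -> softmax\n",
    paste(x$input_shape, collapse = "x"), x$conv$kernel_size[1],
    x$conv$kernel_size[2], x$conv$kernels, x$conv$tile_n, x$activation,
    paste(x$pool_n, collapse = "x"), length(x$classes)))
  invisible(x)
}

softmax <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

#' Forward pass: class probabilities for one window
#'
#' Pipeline: [conv2d_tiled()] + bias, nonlinearity, [maxpool_two_stage()],
#' flatten, dense layer, softmax.
#'
#' @param model a [cnn_model()].
#' @param window a `labeled_window`, or a `channels x width` matrix /
#'   `channels x height x width` array.
#' @return named numeric vector of class probabilities (sums to 1).
#' @export
cnn_forward <- function(model, window) {
  x <- if (inherits(window, "labeled_window")) window$data else window
  x <- as_feature_tensor(x)
  if (!all(dim(x) == model$input_shape))
    stop("window shape (", paste(dim(x), collapse = "x"),
         ") does not match model input (",
         paste(model$input_shape, collapse = "x"), ")")
  z <- conv2d_tiled(x, model$kernels, model$conv)
  z <- sweep(z, 1, model$conv_bias, "+")
  a <- if (model$activation == "relu") pmax(z, 0) else z
  p <- maxpool_two_stage(a, model$pool_n)
  f <- as.vector(p)
  logits <- as.numeric(model$dense_w %*% f + model$dense_b)
  stats::setNames(softmax(logits), model$classes)
}

#' Predict class labels for a list of windows
#' @param model a trained [cnn_model()].
#' @param windows list of `labeled_window` objects.
#' @return character vector of predicted labels.
#' @export
cnn_predict <- function(model, windows) {
  pr <- cnn_probabilities(model, windows)
  model$classes[max.col(t(pr))]
}

# ---- internal vectorized training path -------------------------------------

# Flat parameter view used by the trainer. Wc row k is
# as.vector(kernels[k, , , ]), matching the im2col row order.
model_theta <- function(model) {
  K <- model$conv$kernels
  Wc <- matrix(0, K, prod(dim(model$kernels)[2:4]))
  for (k in seq_len(K)) Wc[k, ] <- as.vector(model$kernels[k, , , ])
  list(Wc = Wc, bc = model$conv_bias, Wd = model$dense_w, bd = model$dense_b)
}

theta_into_model <- function(model, th) {
  K <- model$conv$kernels
  kd <- dim(model$kernels)
  for (k in seq_len(K)) model$kernels[k, , , ] <- array(th$Wc[k, ], kd[2:4])
  model$conv_bias <- th$bc
  model$dense_w <- th$Wd
  model$dense_b <- th$bd
  model
}

# Pooling gather index: members[m, cell] is the column (in the K x Ho*Wo
# conv activation matrix) of the m-th member of pooled cell `cell`
# (cells ordered column-major over Hp x Wp).
pool_members <- function(dims, n) {
  n <- rep(as.integer(n), length.out = 2)
  nh <- n[1]; nw <- n[2]
  with(dims, {
    members <- matrix(0L, nh * nw, Hp * Wp)
    cell <- 0L
    for (pw in seq_len(Wp)) for (ph in seq_len(Hp)) {
      cell <- cell + 1L
      m <- 0L
      for (v in seq_len(nw)) for (u in seq_len(nh)) {
        m <- m + 1L
        members[m, cell] <- ((pw - 1L) * nw + v - 1L) * Ho + (ph - 1L) * nh + u
      }
    }
    members
  })
}

# Batched forward through the flat-parameter view. M is the horizontally
# stacked im2col of `nb` windows. Returns caches needed for backprop.
cnn_forward_batch <- function(model, th, M, nb, members) {
  K <- model$conv$kernels
  npos <- model$dims$Ho * model$dims$Wo
  Z <- th$Wc %*% M + th$bc
  A <- if (model$activation == "relu") pmax(Z, 0) else Z
  ncell <- ncol(members)
  # gather: columns of A for every (member, cell, window)
  offs <- rep((0:(nb - 1)) * npos, each = length(members))
  gcols <- rep(as.vector(members), nb) + offs
  G <- A[, gcols, drop = FALSE]                       # K x (n2*ncell*nb)
  dim(G) <- c(K, nrow(members), ncell * nb)
  P <- matrix(-Inf, K, ncell * nb)
  for (m in seq_len(nrow(members)))
    P <- pmax(P, matrix(G[, m, ], K, ncell * nb))     # K x (ncell*nb)
  Fm <- matrix(P, K * ncell, nb)                      # features per window
  logits <- th$Wd %*% Fm + th$bd
  list(Z = Z, A = A, G = G, Fm = Fm, logits = logits,
       gcols = gcols, ncell = ncell)
}

batch_loss <- function(logits, yidx) {
  L <- sweep(logits, 2, apply(logits, 2, max))
  P <- exp(L); P <- sweep(P, 2, colSums(P), "/")
  -mean(log(pmax(P[cbind(yidx, seq_along(yidx))], 1e-300)))
}

# Mean cross-entropy and analytic gradients over a set of windows
# (already im2col'ed into M). Used by the trainer and by the gradient
# tests.
cnn_loss_and_grad <- function(model, th, M, nb, yidx, members) {
  K <- model$conv$kernels
  fw <- cnn_forward_batch(model, th, M, nb, members)
  L <- sweep(fw$logits, 2, apply(fw$logits, 2, max))
  P <- exp(L); P <- sweep(P, 2, colSums(P), "/")
  loss <- -mean(log(pmax(P[cbind(yidx, seq_len(nb))], 1e-300)))
  dL <- P; dL[cbind(yidx, seq_len(nb))] <- dL[cbind(yidx, seq_len(nb))] - 1
  dL <- dL / nb                                       # C x nb
  g <- list(Wd = dL %*% t(fw$Fm), bd = rowSums(dL))
  dF <- t(th$Wd) %*% dL                               # (K*ncell) x nb
  # route each pooled gradient to the argmax member of its block
  dA <- fw$A * 0
  n2 <- dim(fw$G)[2]
  ncb <- fw$ncell * nb
  Gm <- matrix(aperm(fw$G, c(2, 1, 3)), n2, K * ncb)
  am <- max.col(t(Gm), ties.method = "first")         # winner per (k, cell*win)
  gcols_mat <- matrix(fw$gcols, n2, ncb)
  jcell <- rep(seq_len(ncb), each = K)
  jK <- rep(seq_len(K), ncb)
  win_col <- gcols_mat[cbind(am, jcell)]
  # as.vector(dF) runs k fastest, then cell, then window: same order as
  # (jK, jcell). Pooling blocks are disjoint (stride n), but accumulate
  # with rowsum to stay correct for any index collision.
  agg <- rowsum(as.vector(dF), group = (win_col - 1) * K + jK)
  pos <- as.integer(rownames(agg))
  dA[cbind(((pos - 1) %% K) + 1, ((pos - 1) %/% K) + 1)] <- agg[, 1]
  dZ <- if (model$activation == "relu") dA * (fw$Z > 0) else dA
  g$Wc <- dZ %*% t(M)
  g$bc <- rowSums(dZ)
  list(loss = loss, grad = g[c("Wc", "bc", "Wd", "bd")])
}

windows_im2col <- function(model, windows) {
  do.call(cbind, lapply(windows, function(w) {
    x <- as_feature_tensor(if (inherits(w, "labeled_window")) w$data else w)
    im2col2d(x, model$conv$kernel_size[1], model$conv$kernel_size[2],
             model$conv$stride, model$conv$padding)
  }))
}

cnn_probabilities <- function(model, windows) {
  th <- model_theta(model)
  members <- pool_members(model$dims, model$pool_n)
  M <- windows_im2col(model, windows)
  fw <- cnn_forward_batch(model, th, M, length(windows), members)
  pr <- apply(fw$logits, 2, softmax)
  rownames(pr) <- model$classes
  pr
}

#' Train the CNN with Adadelta under the early-stopping protocol
#'
#' Minibatch gradient descent with Adadelta accumulators (decay `rho`,
#' stabilizer `epsilon`, global multiplier `learning_rate`) on the mean
#' cross-entropy. One iteration is one full pass over the training set in
#' fixed batch order, so training is deterministic. After each iteration
#' the full-training-set loss is recorded; training stops when it reaches
#' `loss_stop` or after `max_iterations` iterations.
#'
#' @param model a [cnn_model()] whose classes cover the window labels.
#' @param windows list of `labeled_window` objects (at least 2 classes).
#' @param config a [train_config()].
#' @return the trained model, with attributes `loss_history` (numeric,
#'   one entry per iteration) and `stop_reason` (`"loss_stop"` or
#'   `"max_iterations"`).
#' @export
cnn_train <- function(model, windows, config = train_config()) {
  if (!length(windows)) stop("empty training set")
  labs <- vapply(windows, function(w) w$label, character(1))
  if (length(unique(labs)) < 2) stop("training needs at least 2 classes")
  if (!all(labs %in% model$classes))
    stop("window label(s) not among model classes: ",
         paste(setdiff(labs, model$classes), collapse = ", "))
  yidx <- match(labs, model$classes)
  nb <- length(windows)
  th <- model_theta(model)
  members <- pool_members(model$dims, model$pool_n)
  Mall <- windows_im2col(model, windows)
  npos <- model$dims$Ho * model$dims$Wo

  Eg <- lapply(th, function(x) x * 0)
  Ed <- Eg
  batches <- split(seq_len(nb), ceiling(seq_len(nb) / config$batch_size))
  history <- numeric(0)
  stop_reason <- "max_iterations"
  for (it in seq_len(config$max_iterations)) {
    for (idx in batches) {
      cols <- as.vector(outer(seq_len(npos), (idx - 1) * npos, "+"))
      lg <- cnn_loss_and_grad(model, th, Mall[, cols, drop = FALSE],
                              length(idx), yidx[idx], members)
      for (nm in names(th)) {
        g <- lg$grad[[nm]]
        Eg[[nm]] <- config$rho * Eg[[nm]] + (1 - config$rho) * g^2
        d <- -sqrt(Ed[[nm]] + config$epsilon) / sqrt(Eg[[nm]] + config$epsilon) * g
        Ed[[nm]] <- config$rho * Ed[[nm]] + (1 - config$rho) * d^2
        th[[nm]] <- th[[nm]] + config$learning_rate * d
      }
    }
    fw <- cnn_forward_batch(model, th, Mall, nb, members)
    history[it] <- batch_loss(fw$logits, yidx)
    if (history[it] <= config$loss_stop) { stop_reason <- "loss_stop"; break }
  }
  model <- theta_into_model(model, th)
  attr(model, "loss_history") <- history
  attr(model, "stop_reason") <- stop_reason
  model
}

#' Save / load a CNN model as a plain-text key-value archive
#'
#' One `field <name> <value...>` line per scalar/string field and one
#' `tensor <name> <dims>` line followed by a line of values (17
#' significant digits) per weight tensor.
#'
#' @param model a [cnn_model()].
#' @param path file path.
#' @export
save_cnn_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("imuhar-cnn-model", "1")
  wl("field", "classes", paste(model$classes, collapse = ","))
  wl("field", "activation", model$activation)
  wl("field", "pool_n", paste(model$pool_n, collapse = ","))
  wl("field", "input_shape", paste(model$input_shape, collapse = ","))
  wl("field", "conv",
     paste(c(model$conv$kernel_size, model$conv$kernels, model$conv$tile_n,
             model$conv$stride, model$conv$padding), collapse = ","))
  wt <- function(name, x) {
    wl("tensor", name, paste(if (is.null(dim(x))) length(x) else dim(x),
                             collapse = ","))
    wl(paste(formatC(as.vector(x), digits = 17, format = "g"), collapse = " "))
  }
  wt("kernels", model$kernels)
  wt("conv_bias", model$conv_bias)
  wt("dense_w", model$dense_w)
  wt("dense_b", model$dense_b)
  invisible(path)
}

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "imuhar-cnn-model"))
    stop("not an imuhar model archive: ", path)
  fields <- list(); tensors <- list()
  i <- 2
  while (i <= length(ln)) {
    parts <- strsplit(ln[i], " ", fixed = TRUE)[[1]]
    if (parts[1] == "field") {
      fields[[parts[2]]] <- paste(parts[-(1:2)], collapse = " ")
      i <- i + 1
    } else if (parts[1] == "tensor") {
      dims <- as.integer(strsplit(parts[3], ",")[[1]])
      vals <- as.numeric(strsplit(trimws(ln[i + 1]), " +")[[1]])
      tensors[[parts[2]]] <- if (length(dims) > 1) array(vals, dims) else vals
      i <- i + 2
    } else stop("malformed model archive at line ", i)
  }
  cv <- as.integer(strsplit(fields$conv, ",")[[1]])
  model <- cnn_model(
    input_shape = as.integer(strsplit(fields$input_shape, ",")[[1]]),
    classes = strsplit(fields$classes, ",")[[1]],
    conv = conv_layer_spec(kernel_size = cv[1:2], kernels = cv[3],
                           tile_n = cv[4], stride = cv[5], padding = cv[6]),
    pool_n = as.integer(strsplit(fields$pool_n, ",")[[1]]),
    activation = fields$activation)
  model$kernels <- tensors$kernels
  model$conv_bias <- tensors$conv_bias
  model$dense_w <- tensors$dense_w
  model$dense_b <- tensors$dense_b
  model
}
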
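# Independent oracles used across the suite. These deliberately use the
# most naive formulation available (nested loops, central differences)
# and share no code with the implementation paths they check.

num_jacobian <- function(f, x, h = 1e-6) {
  y0 <- f(x)
  J <- matrix(0, length(y0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# dense valid convolution by four (six) nested loops
naive_conv2d <- function(x, kernels) {
  K <- dim(kernels)[1]; CH <- dim(kernels)[2]
  kh <- dim(kernels)[3]; kw <- dim(kernels)[4]
  Ho <- dim(x)[2] - kh + 1; Wo <- dim(x)[3] - kw + 1
  out <- array(0, c(K, Ho, Wo))
  for (k in seq_len(K)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- 0
    for (c in seq_len(CH)) for (u in seq_len(kh)) for (v in seq_len(kw))
      s <- s + x[c, i + u - 1, j + v - 1] * kernels[k, c, u, v]
    out[k, i, j] <- s
  }
  out
}

# block max with stride n, incomplete edge blocks dropped
naive_blockmax <- function(x, n) {
  n <- rep(n, length.out = 2)
  CH <- dim(x)[1]; Hp <- dim(x)[2] %/% n[1]; Wp <- dim(x)[3] %/% n[2]
  out <- array(-Inf, c(CH, Hp, Wp))
  for (c in seq_len(CH)) for (i in seq_len(Hp)) for (j in seq_len(Wp))
    out[c, i, j] <- max(x[c, (i - 1) * n[1] + seq_len(n[1]),
                          (j - 1) * n[2] + seq_len(n[2])])
  out
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# accuracy of a nearest-centroid classifier on per-channel window
# means and variances
nearest_centroid_accuracy <- function(windows) {
  feats <- t(vapply(windows, function(w)
    c(rowMeans(w$data), apply(w$data, 1, stats::var)),
    numeric(2 * nrow(windows[[1]]$data))))
  labs <- vapply(windows, function(w) w$label, character(1))
  cents <- lapply(split(seq_along(labs), labs), function(i)
    colMeans(feats[i, , drop = FALSE]))
  cls <- names(cents)
  pred <- vapply(seq_len(nrow(feats)), function(i) {
    d <- vapply(cents, function(ce) sum((feats[i, ] - ce)^2), numeric(1))
    cls[which.min(d)]
  }, character(1))
  mean(pred == labs)
}

# a tiny labeled-window fixture with arbitrary content
make_window <- function(data, label = "a", user = "u1", start = 0L) {
  structure(list(data = data, label = label, user_id = user, start = start),
            class = "labeled_window")
}
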
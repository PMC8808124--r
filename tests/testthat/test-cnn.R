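test_that("multiply-accumulate equals the naive dot product", {
  expect_equal(conv_mac(c(1, 1, 1), c(1, 1, 1)), 3)
  expect_equal(conv_mac(stats::rnorm(5), rep(0, 5)), 0)
  set.seed(1)
  f <- stats::rnorm(8); w <- stats::rnorm(8)
  acc <- 0
  for (i in 1:8) acc <- acc + f[i] * w[i]
  expect_equal(conv_mac(f, w), acc, tolerance = 1e-12)
  expect_error(conv_mac(1:3, 1:4), "equal length")
})

test_that("channel-tiled convolution equals dense convolution across shapes", {
  # identity: 1x1 unit kernel passes the input through
  x1 <- array(stats::rnorm(1 * 4 * 5), c(1, 4, 5))
  k1 <- array(1, c(1, 1, 1, 1))
  sp1 <- conv_layer_spec(kernel_size = c(1, 1), kernels = 1, tile_n = 1)
  expect_equal(conv2d_tiled(x1, k1, sp1), x1)

  # all-ones 3x3 kernel on all-ones 5x5 input: every output is 9
  xo <- array(1, c(1, 5, 5))
  ko <- array(1, c(1, 1, 3, 3))
  out <- conv2d_tiled(xo, ko, conv_layer_spec(kernel_size = c(3, 3), kernels = 1,
                                              tile_n = 1))
  expect_equal(out, array(9, c(1, 3, 3)))

  # sweep: channel counts divisible and not divisible by the tile width
  set.seed(5)
  cases <- expand.grid(CH = c(1, 3, 8), N = c(1, 3, 4, 16), K = c(1, 4))
  for (i in seq_len(nrow(cases))) {
    CH <- cases$CH[i]; N <- cases$N[i]; K <- cases$K[i]
    x <- array(stats::rnorm(CH * 6 * 9), c(CH, 6, 9))
    k <- array(stats::rnorm(K * CH * 3 * 3), c(K, CH, 3, 3))
    sp <- conv_layer_spec(kernel_size = c(3, 3), kernels = K, tile_n = N)
    expect_lt(max(abs(conv2d_tiled(x, k, sp) - naive_conv2d(x, k))), 1e-9)
  }

  # a CH x W matrix is lifted to height 1
  xm <- matrix(stats::rnorm(3 * 10), 3, 10)
  km <- array(stats::rnorm(2 * 3 * 1 * 3), c(2, 3, 1, 3))
  spm <- conv_layer_spec(kernel_size = c(1, 3), kernels = 2, tile_n = 2)
  expect_equal(conv2d_tiled(xm, km, spm),
               naive_conv2d(array(xm, c(3, 1, 10)), km), tolerance = 1e-12)

  expect_error(conv2d_tiled(array(0, c(2, 4, 4)),
                            array(0, c(1, 3, 3, 3))), "channel")
})

test_that("two-stage pooling equals the naive block maximum", {
  m <- array(matrix(1:16, 4, 4, byrow = TRUE), c(1, 4, 4))
  expect_equal(maxpool_two_stage(m, 2)[1, , ],
               matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  expect_equal(maxpool_two_stage(m, 1), m)  # identity at n = 1
  set.seed(6)
  for (dims in list(c(1, 7, 9), c(3, 6, 8), c(2, 5, 5))) {
    x <- array(stats::rnorm(prod(dims)), dims)
    for (n in c(1, 2, 3)) {
      if (dims[2] %/% n < 1 || dims[3] %/% n < 1) next
      expect_equal(maxpool_two_stage(x, n), naive_blockmax(x, n),
                   tolerance = 0)
    }
  }
  # rectangular blocks (used for height-1 feature maps)
  x <- array(stats::rnorm(2 * 1 * 12), c(2, 1, 12))
  expect_equal(maxpool_two_stage(x, c(1, 3)), naive_blockmax(x, c(1, 3)))
  expect_warning(out <- maxpool_two_stage(array(0, c(1, 1, 3)), 4), "empty")
  expect_equal(dim(out), c(1, 0, 0))
})

test_that("forward pass produces a well-formed probability simplex", {
  set.seed(7)
  model <- cnn_model(c(3, 32), c("a", "b", "c"), seed = 1)
  w <- make_window(matrix(stats::rnorm(3 * 32), 3, 32))
  p <- cnn_forward(model, w)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_named(p, c("a", "b", "c"))

  # all-zero weights: symmetry forces uniform probabilities
  m0 <- model
  m0$kernels[] <- 0; m0$dense_w[] <- 0
  expect_equal(unname(cnn_forward(m0, w)), rep(1 / 3, 3), tolerance = 1e-12)

  # raising one logit raises its probability
  m1 <- model
  m1$dense_b[2] <- m1$dense_b[2] + 0.5
  expect_gt(cnn_forward(m1, w)["b"], p["b"])

  # softmax is invariant to a common logit shift
  m2 <- model
  m2$dense_b <- m2$dense_b + 3.7
  expect_equal(cnn_forward(m2, w), p, tolerance = 1e-9)

  expect_error(cnn_forward(model, matrix(0, 4, 32)), "shape")
})

test_that("batched training forward agrees with the single-window forward", {
  set.seed(8)
  wins <- lapply(1:5, function(i)
    make_window(matrix(stats::rnorm(3 * 32), 3, 32),
                label = c("a", "b")[(i %% 2) + 1]))
  model <- cnn_model(c(3, 32), c("a", "b"), seed = 3)
  pb <- imuhar:::cnn_probabilities(model, wins)
  for (i in seq_along(wins))
    expect_equal(unname(pb[, i]), unname(cnn_forward(model, wins[[i]])),
                 tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences on a tiny model", {
  set.seed(9)
  wins <- lapply(1:6, function(i)
    make_window(array(stats::rnorm(2 * 4 * 4), c(2, 4, 4)),
                label = c("a", "b")[(i %% 2) + 1]))
  for (pool in c(1, 2)) {
    model <- cnn_model(c(2, 4, 4), c("a", "b"),
                       conv = conv_layer_spec(kernel_size = c(2, 2), kernels = 3,
                                              tile_n = 1),
                       pool_n = pool, seed = 2)
    th <- imuhar:::model_theta(model)
    members <- imuhar:::pool_members(model$dims, model$pool_n)
    M <- imuhar:::windows_im2col(model, wins)
    yidx <- match(vapply(wins, function(w) w$label, character(1)), model$classes)
    lg <- imuhar:::cnn_loss_and_grad(model, th, M, length(wins), yidx, members)
    loss_at <- function(th2)
      imuhar:::cnn_loss_and_grad(model, th2, M, length(wins), yidx, members)$loss
    for (nm in names(th)) {
      for (j in seq_along(th[[nm]])) {
        h <- 1e-5
        thp <- th; thp[[nm]][j] <- thp[[nm]][j] + h
        thm <- th; thm[[nm]][j] <- thm[[nm]][j] - h
        num <- (loss_at(thp) - loss_at(thm)) / (2 * h)
        expect_lt(abs(num - lg$grad[[nm]][j]) / max(1e-6, abs(num)), 1e-5)
      }
    }
  }
})

test_that("training stops by the loss rule or the iteration cap, deterministically", {
  streams <- simulate_activity_streams(n_users = 3, seed = 4)
  wins <- unlist(lapply(streams, slice_windows, window_len = 32),
                 recursive = FALSE)
  labs <- sort(unique(vapply(wins, function(w) w$label, character(1))))
  shape <- c(nrow(wins[[1]]$data), ncol(wins[[1]]$data))

  # unreachable loss threshold: exactly max_iterations run
  m1 <- cnn_model(shape, labs, seed = 1)
  cfg1 <- train_config(loss_stop = 1e-12, max_iterations = 5)
  t1 <- cnn_train(m1, wins, cfg1)
  expect_length(attr(t1, "loss_history"), 5)
  expect_equal(attr(t1, "stop_reason"), "max_iterations")

  # identical configuration: identical history and weights
  t1b <- cnn_train(cnn_model(shape, labs, seed = 1), wins, cfg1)
  expect_identical(attr(t1, "loss_history"), attr(t1b, "loss_history"))
  expect_identical(t1$kernels, t1b$kernels)

  # the high-SNR fixture trains to the loss threshold with high accuracy
  m2 <- cnn_model(shape, labs, seed = 1)
  t2 <- cnn_train(m2, wins, train_config())
  expect_equal(attr(t2, "stop_reason"), "loss_stop")
  expect_lte(utils::tail(attr(t2, "loss_history"), 1), 0.2)
  acc <- mean(cnn_predict(t2, wins) ==
                vapply(wins, function(w) w$label, character(1)))
  expect_gte(acc, 0.95)

  expect_error(cnn_train(m2, list()), "empty")
  expect_error(cnn_train(m2, wins[vapply(wins, function(w) w$label, character(1)) == "class1"]),
               "2 classes")
})

test_that("a model archive round-trips through the text format", {
  streams <- simulate_activity_streams(n_users = 2, windows_per_class = 2, seed = 6)
  wins <- unlist(lapply(streams, slice_windows, window_len = 32),
                 recursive = FALSE)
  labs <- sort(unique(vapply(wins, function(w) w$label, character(1))))
  model <- cnn_train(cnn_model(c(3, 32), labs, seed = 2), wins,
                     train_config(max_iterations = 3, loss_stop = 1e-12))
  p <- withr::local_tempfile(fileext = ".txt")
  save_cnn_model(model, p)
  back <- load_cnn_model(p)
  expect_equal(back$kernels, model$kernels, tolerance = 1e-15)
  expect_equal(back$dense_w, model$dense_w, tolerance = 1e-15)
  expect_identical(back$classes, model$classes)
  w1 <- wins[[1]]
  expect_equal(cnn_forward(back, w1), cnn_forward(model, w1), tolerance = 1e-12)
  expect_error(load_cnn_model(withr::local_tempfile(lines = "nonsense")),
               "archive")
})
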
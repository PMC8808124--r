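test_that("initial Euler angles recover tilt from gravity and heading from the compass", {
  e <- initial_euler(c(0, 0, 1), c(0, 1, 0))
  expect_equal(as.numeric(e), c(0, 0, 0), tolerance = 1e-14)
  # with zero tilt the heading reduces to atan2(mx, my)
  e2 <- initial_euler(c(0, 0, 1), c(1, 0, 0))
  expect_equal(unname(e2["yaw"]), pi / 2, tolerance = 1e-14)
  a <- c(0, sin(10 * pi / 180), cos(10 * pi / 180))
  e3 <- initial_euler(a, c(0.3, 0.5, -0.2))
  expect_equal(unname(e3["pitch"]), 10 * pi / 180, tolerance = 1e-12)
  expect_error(initial_euler(c(0, 0, 0), c(0, 1, 0)), "degenerate")
  # consistency: for any simulated orientation, accel+mag reproduce it
  sim <- simulate_imu(trajectory_spec(
    duration = 0.1, rate = 50, pitch = c(0, 0, 0, 0.4), roll = c(0, 0, 0, -0.7),
    yaw = c(0, 0, 0, 2.1), gyro_bias_true = c(0, 0, 0),
    noise_sd = list(gyro = 0, accel = 0, mag = 0)))
  d <- sim$sequence$data[1, ]
  e4 <- initial_euler(as.numeric(d[c("accel_x", "accel_y", "accel_z")]),
                      as.numeric(d[c("mag_x", "mag_y", "mag_z")]))
  expect_equal(as.numeric(e4), c(0.4, -0.7, 2.1), tolerance = 1e-10)
})

test_that("prediction is exact at zero net rate and integrates a constant rate", {
  noise <- noise_config()
  st <- ekf_state(q = quat_from_euler(euler_angles(0.2, -0.1, 0.5)),
                  bias = c(0.01, -0.02, 0.005))
  # gyro reading equal to the bias: net rate zero, quaternion unchanged
  pr <- ekf_predict(st, imuhar:::rad2deg(st$bias), 0.01, noise)
  expect_equal(pr$q, st$q, tolerance = 1e-15)
  # uncertainty grows: process noise inflates the covariance trace
  expect_gt(sum(diag(pr$P)), sum(diag(st$P)))
  expect_equal(pr$P, t(pr$P), tolerance = 1e-12)

  # constant body rate about z: yaw grows at the commanded rate
  st <- ekf_state()
  w <- 0.2  # rad/s
  for (i in 1:500) st <- ekf_predict(st, c(0, 0, imuhar:::rad2deg(w)), 0.01, noise)
  expect_equal(unname(euler_from_quat(st$q)["yaw"]), w * 5, tolerance = 1e-3)
  expect_equal(sum(st$q^2), 1, tolerance = 1e-12)

  # covariance stays symmetric
  expect_equal(st$P, t(st$P), tolerance = 1e-10)
  expect_error(ekf_predict(st, c(NA, 0, 0), 0.01, noise), "non-finite")
  expect_error(ekf_predict(st, c(0, 0, 0), -1, noise), "positive")
})

test_that("transition and measurement Jacobians match central finite differences", {
  set.seed(11)
  for (i in 1:25) {
    q <- random_unit_quat()
    x <- c(q, stats::rnorm(3, sd = 0.01))
    w <- stats::rnorm(3)
    G <- imuhar:::ekf_transition_jacobian(x, w, 0.01)
    Gn <- num_jacobian(function(z) imuhar:::ekf_transition_fn(z, w, 0.01), x)
    expect_lt(max(abs(G - Gn)) / max(abs(Gn)), 1e-6)
    mu <- stats::rnorm(3)
    mu <- mu / sqrt(sum(mu^2))
    H <- imuhar:::ekf_measurement_jacobian(q, mu)
    Hn <- num_jacobian(function(z) imuhar:::ekf_measurement_fn(z[1:4], mu), x)
    expect_lt(max(abs(H - Hn)) / max(abs(Hn)), 1e-6)
  }
})

test_that("predicted measurements follow the east-collapse model", {
  # identity orientation, field already east-free: prediction is the input
  h <- ekf_predict_measurement(c(1, 0, 0, 0), c(0, 0.3, -0.4))
  expect_equal(h[1:3], c(0, 0, 1), tolerance = 1e-14)
  expect_equal(h[4:6], c(0, 0.3, -0.4), tolerance = 1e-14)
  # an east component is folded into north, preserving horizontal magnitude
  h2 <- ekf_predict_measurement(c(1, 0, 0, 0), c(0.3, 0.4, -0.2))
  expect_equal(h2[4:6], c(0, 0.5, -0.2), tolerance = 1e-14)
  # predicted gravity direction is unit for any orientation
  set.seed(2)
  for (i in 1:10) {
    h3 <- ekf_predict_measurement(random_unit_quat(), stats::rnorm(3))
    expect_equal(sqrt(sum(h3[1:3]^2)), 1, tolerance = 1e-12)
  }
  expect_error(ekf_predict_measurement(c(1, 0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("correction leaves a consistent state untouched and fades out as R grows", {
  noise <- noise_config()
  # identity orientation, exactly representable measurements: the zero
  # innovation leaves the state bitwise unchanged
  st0 <- ekf_state()
  post0 <- ekf_update(st0, c(0, 0, 1), c(0, 0.6, -0.8), noise)
  expect_identical(post0$q, st0$q)
  expect_identical(post0$bias, st0$bias)

  q <- quat_from_euler(euler_angles(0.1, 0.2, -0.4))
  st <- ekf_state(q = q)
  h <- ekf_predict_measurement(q, c(0, 0.3, -0.4))
  # measurements equal to the prediction: state unchanged to rounding
  post <- ekf_update(st, h[1:3], h[4:6], noise)
  expect_equal(post$q, st$q, tolerance = 1e-12)
  expect_equal(post$bias, st$bias, tolerance = 1e-12)
  # posterior covariance never exceeds the prior in the psd order
  expect_true(all(eigen(st$P - post$P, only.values = TRUE)$values > -1e-10))

  # huge measurement noise: gain collapses, posterior ~ prior
  big <- noise_config(accel_noise = 1e12, mag_noise = 1e12)
  post2 <- ekf_update(st, c(0.2, 0.1, 0.95), c(0.1, 0.25, -0.45), big)
  expect_lt(max(abs(post2$q - st$q)), 1e-6)
  expect_lt(max(abs(post2$bias - st$bias)), 1e-6)

  # free fall: accelerometer half skipped with a warning
  expect_warning(ekf_update(st, c(0, 0, 0), c(0, 0.3, -0.4), noise),
                 "accelerometer")
})

test_that("the filter is stationary on a noise-free static stream", {
  sim <- simulate_imu(trajectory_spec(
    duration = 2, rate = 100, gyro_bias_true = c(0, 0, 0),
    noise_sd = list(gyro = 0, accel = 0, mag = 0)))
  fit <- run_filter(sim$sequence)
  est <- fit$estimates
  expect_lt(max(abs(est$pitch)), 1e-8)
  expect_lt(max(abs(est$roll)), 1e-8)
  expect_lt(max(abs(est$yaw)), 1e-8)
  expect_equal(nrow(est), length(sim$sequence))
})

test_that("a constant gyro bias is recovered on static data", {
  sim <- simulate_imu(trajectory_spec(duration = 30, rate = 100, seed = 21))
  fit <- run_filter(sim$sequence)
  b_end <- as.numeric(fit$estimates[nrow(fit$estimates),
                                    c("bias_x", "bias_y", "bias_z")])
  expect_lt(abs(b_end[1] - 0.5) / 0.5, 0.1)
  expect_lt(max(abs(b_end[2:3])), 0.05)
})

test_that("fusion beats gyro-only dead reckoning on a moving noisy stream", {
  sim <- simulate_imu(trajectory_spec(
    duration = 20, rate = 100, yaw = c(pi / 6, 0.5, 0, 0), seed = 8))
  fit <- run_filter(sim$sequence)
  dr <- dead_reckoning(sim$sequence)
  rms_yaw <- function(est) sqrt(mean((est$yaw - sim$truth$yaw)^2))
  expect_lt(rms_yaw(fit$estimates), rms_yaw(dr))
})

test_that("accel-only correction fixes tilt while yaw drifts", {
  # bias on the z axis is invisible to the accelerometer
  sim <- simulate_imu(trajectory_spec(duration = 20, rate = 100,
                                      gyro_bias_true = c(0, 0, 0.5), seed = 13))
  # disable the magnetometer by making its noise huge
  fit <- run_filter(sim$sequence, noise_config(mag_noise = 1e12))
  est_end <- fit$estimates[nrow(fit$estimates), ]
  expect_lt(abs(est_end$pitch), 0.02)
  expect_lt(abs(est_end$roll), 0.02)
  # yaw accumulates the uncorrected bias drift: ~0.5 deg/s * 20 s
  expect_gt(abs(est_end$yaw), 0.05)
})

test_that("filter output can be written as an orientation CSV", {
  sim <- simulate_imu(trajectory_spec(duration = 0.5, rate = 50, seed = 2))
  fit <- run_filter(sim$sequence)
  p <- withr::local_tempfile(fileext = ".csv")
  write_orientation_csv(fit, p)
  back <- utils::read.csv(p)
  expect_named(back, c("t", "q0", "q1", "q2", "q3", "pitch", "roll", "yaw",
                       "bias_x", "bias_y", "bias_z"))
  expect_equal(nrow(back), length(sim$sequence))
})
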
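#' Extended Kalman filter for quaternion attitude with gyro-bias estimation
#'
#' The filter state is `x = c(q, b)`: a unit quaternion (sensor frame to
#' navigation frame) and a 3-vector gyro bias in rad/s, with a 7x7 error
#' covariance `P`. Gyro readings drive the prediction through the
#' discretized quaternion kinematics `q' = (I + T/2 * Omega(omega_hat)) q`
#' with `omega_hat = omega_meas - b`; accelerometer and magnetometer
#' readings correct the prediction against the gravity reference
#' `g = c(0, 0, 1)` and a navigation-frame magnetic field with north and
#' vertical components only. The quaternion is renormalized after every
#' prediction and every correction.
#'
#' @name ekf
NULL

#' Filter noise configuration
#'
#' Per-axis noise variances, all user-configurable since real sensors vary
#' widely. Units: `gyro_noise` in (rad/s)^2, `gyro_bias_noise` in
#' (rad/s)^2 per second (bias random-walk intensity), `accel_noise` and
#' `mag_noise` in normalized measurement units squared (the measurement
#' vector is normalized before use). `p0_quat` and `p0_bias` set the
#' initial error-covariance diagonal.
#'
#' @param gyro_noise,gyro_bias_noise,accel_noise,mag_noise nonnegative
#'   variances.
#' @param p0_quat,p0_bias nonnegative initial variances for the quaternion
#'   and bias blocks of `P`.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(gyro_noise = 3e-5, gyro_bias_noise = 1e-8,
                         accel_noise = 1e-3, mag_noise = 1e-3,
                         p0_quat = 1e-4, p0_bias = 3e-4) {
  v <- c(gyro_noise, gyro_bias_noise, accel_noise, mag_noise, p0_quat, p0_bias)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all noise variances must be finite and nonnegative")
  structure(list(gyro_noise = gyro_noise, gyro_bias_noise = gyro_bias_noise,
                 accel_noise = accel_noise, mag_noise = mag_noise,
                 p0_quat = p0_quat, p0_bias = p0_bias),
            class = "noise_config")
}

#' Filter state
#'
#' @param q unit quaternion.
#' @param bias gyro bias, rad/s.
#' @param P 7x7 error covariance (symmetric positive semidefinite).
#' @return object of class `ekf_state`.
#' @export
ekf_state <- function(q = c(1, 0, 0, 0), bias = c(0, 0, 0),
                      P = diag(c(rep(1e-4, 4), rep(3e-4, 3)))) {
  q <- quat_normalize(q)
  if (!isTRUE(all.equal(P, t(P), tolerance = 1e-8)))
    stop("P must be symmetric")
  structure(list(q = q, bias = as.numeric(bias), P = (P + t(P)) / 2),
            class = "ekf_state")
}

#' Initial Euler angles from one accelerometer and magnetometer reading
#'
#' Tilt from gravity, heading from the tilt-compensated compass: with
#' `a` the static accelerometer reading and `m` the magnetometer reading,
#' `pitch = asin(a_y / |a|)`, `roll = atan2(-a_x, a_z)` and the yaw is the
#' heading of the de-tilted horizontal magnetic field.
#'
#' @param accel length-3 accelerometer reading (any scale, g typical).
#' @param mag length-3 magnetometer reading (any scale, Gauss typical).
#' @return an [euler_angles()] object.
#' @export
initial_euler <- function(accel, mag) {
  na <- sqrt(sum(accel^2))
  if (na == 0) stop("degenerate input: zero accelerometer vector")
  if (sqrt(sum(mag^2)) == 0) stop("degenerate input: zero magnetometer vector")
  a <- accel / na
  x0 <- asin(max(-1, min(1, a[2])))
  y0 <- atan2(-a[1], a[3])
  mx <- mag[1]; my <- mag[2]; mz <- mag[3]
  num <- mx * cos(y0) + mz * sin(y0)
  den <- mx * sin(y0) * sin(x0) + my * cos(x0) - mz * cos(y0) * sin(x0)
  z0 <- atan2(num, den)
  euler_angles(x0, y0, z0)
}

# State-transition map x -> f(x): quaternion kinematics with bias-corrected
# rate, identity propagation of the bias. No normalization here (the
# Jacobian is taken of this map; run_filter renormalizes afterwards).
ekf_transition_fn <- function(x, omega_rad, T) {
  q <- x[1:4]; b <- x[5:7]
  A <- diag(4) + (T / 2) * omega_matrix(omega_rad - b)
  c(A %*% q, b)
}

# Analytic Jacobian of ekf_transition_fn.
ekf_transition_jacobian <- function(x, omega_rad, T) {
  q <- x[1:4]; b <- x[5:7]
  G <- matrix(0, 7, 7)
  G[1:4, 1:4] <- diag(4) + (T / 2) * omega_matrix(omega_rad - b)
  G[1:4, 5:7] <- -(T / 2) * xi_matrix(q)
  G[5:7, 5:7] <- diag(3)
  G
}

#' EKF prediction step
#'
#' Propagates the state with one gyro reading over time step `T`:
#' `q' = (I + T/2 * Omega(omega_meas - bias)) q` followed by
#' renormalization; the bias propagates as identity. The covariance
#' becomes `G P G' + Q` with `G` the transition Jacobian and the process
#' noise `Q = blockdiag((T/2)^2 * gyro_noise * Xi(q) Xi(q)', T *
#' gyro_bias_noise * I3)` — the gyro noise mapped onto the quaternion
#' coordinates and scaled by the step.
#'
#' @param state an [ekf_state()].
#' @param omega_meas gyro reading, deg/s (converted internally).
#' @param T time step in seconds.
#' @param noise a [noise_config()].
#' @return the prior [ekf_state()].
#' @export
ekf_predict <- function(state, omega_meas, T, noise) {
  if (!is.finite(T) || T <= 0) stop("T must be a positive time step")
  if (any(!is.finite(omega_meas))) stop("non-finite gyro input")
  w <- deg2rad(as.numeric(omega_meas))
  x <- c(state$q, state$bias)
  xn <- ekf_transition_fn(x, w, T)
  G <- ekf_transition_jacobian(x, w, T)
  Xi <- xi_matrix(state$q)
  Q <- matrix(0, 7, 7)
  Q[1:4, 1:4] <- (T / 2)^2 * noise$gyro_noise * (Xi %*% t(Xi))
  Q[5:7, 5:7] <- T * noise$gyro_bias_noise * diag(3)
  P <- G %*% state$P %*% t(G) + Q
  ekf_state(q = quat_normalize(xn[1:4]), bias = xn[5:7], P = (P + t(P)) / 2)
}

# Measurement map h(q): predicted normalized accelerometer and magnetometer
# readings given the prior orientation. The magnetometer half uses the
# measured field itself: it is rotated to the navigation frame, its east
# component is collapsed (horizontal magnitude folded into north), and the
# result is rotated back to the body frame. mag_unit must be pre-normalized.
ekf_measurement_fn <- function(q, mag_unit) {
  a_pred <- quat_rotate(quat_conjugate(q), c(0, 0, 1))
  m_n <- quat_rotate(q, mag_unit)
  h <- sqrt(m_n[1]^2 + m_n[2]^2)
  m_bar_n <- c(0, h, m_n[3])
  m_pred <- quat_rotate(quat_conjugate(q), m_bar_n)
  c(a_pred, m_pred)
}

# Analytic 6x7 Jacobian of ekf_measurement_fn with respect to the state
# (bias columns are zero). The magnetometer rows account for the full
# dependence on q: both the rotation to {n} (through the east collapse)
# and the rotation back to {b}.
ekf_measurement_jacobian <- function(q, mag_unit) {
  H <- matrix(0, 6, 7)
  H[1:3, 1:4] <- drotate_inv_dq(q, c(0, 0, 1))
  m_n <- quat_rotate(q, mag_unit)
  h <- sqrt(m_n[1]^2 + m_n[2]^2)
  m_bar_n <- c(0, h, m_n[3])
  D_mn <- drotate_dq(q, mag_unit)
  Jv <- matrix(0, 3, 3)
  if (h > 0) Jv[2, 1:2] <- m_n[1:2] / h
  Jv[3, 3] <- 1
  H[4:6, 1:4] <- drotate_inv_dq(q, m_bar_n) +
    t(quat_to_matrix(q)) %*% Jv %*% D_mn
  H
}

#' Predicted measurement for a prior orientation
#'
#' Returns the stacked 6-vector `c(a_pred, m_pred)`: the gravity reference
#' rotated into the body frame, and the measured magnetic field after its
#' east component is collapsed in the navigation frame (horizontal
#' magnitude folded into north) and rotated back into the body frame.
#' The magnetometer reading keeps its scale here; normalization happens
#' in the correction step, where both sides of the innovation are
#' normalized together.
#'
#' @param q unit quaternion (prior orientation estimate).
#' @param mag_meas magnetometer reading (Gauss or any scale).
#' @export
ekf_predict_measurement <- function(q, mag_meas) {
  if (sqrt(sum(mag_meas^2)) == 0)
    stop("degenerate input: zero magnetometer vector")
  ekf_measurement_fn(q, mag_meas)
}

#' EKF correction step
#'
#' Normalizes the accelerometer and magnetometer readings into the
#' measurement vector `Z`, forms the innovation against the predicted
#' measurement, and applies the Kalman gain
#' `K = P H' (H P H' + R)^-1` with `R = blockdiag(accel_noise * I3,
#' mag_noise * I3)`; then `P = (I - K H) P` (symmetrized) and the
#' quaternion is renormalized. A near-zero accelerometer reading
#' (free fall) skips the accelerometer half of the update with a warning;
#' a near-zero magnetometer reading likewise skips the magnetic half.
#'
#' @param state prior [ekf_state()].
#' @param accel_meas accelerometer reading in g.
#' @param mag_meas magnetometer reading in Gauss.
#' @param noise a [noise_config()].
#' @return the posterior [ekf_state()].
#' @export
ekf_update <- function(state, accel_meas, mag_meas, noise) {
  na <- sqrt(sum(accel_meas^2)); nm <- sqrt(sum(mag_meas^2))
  use_a <- na > 1e-6; use_m <- nm > 1e-6
  if (!use_a) warning("near-zero accelerometer reading; skipping accelerometer update")
  if (!use_m) warning("near-zero magnetometer reading; skipping magnetometer update")
  if (!use_a && !use_m) return(state)
  q <- state$q
  mag_unit <- if (use_m) mag_meas / nm else c(0, 1, 0)
  hfull <- ekf_measurement_fn(q, mag_unit)
  Hfull <- ekf_measurement_jacobian(q, mag_unit)
  Zfull <- c(if (use_a) accel_meas / na else rep(0, 3),
             if (use_m) mag_unit else rep(0, 3))
  rows <- c(if (use_a) 1:3, if (use_m) 4:6)
  Rdiag <- c(rep(noise$accel_noise, 3), rep(noise$mag_noise, 3))[rows]
  H <- Hfull[rows, , drop = FALSE]
  S <- H %*% state$P %*% t(H) + diag(Rdiag, nrow = length(rows))
  K <- tryCatch(state$P %*% t(H) %*% solve(S),
                error = function(e)
                  stop("singular innovation covariance (condition ",
                       format(kappa(S)), "): ", conditionMessage(e)))
  innov <- Zfull[rows] - hfull[rows]
  x <- c(q, state$bias) + as.numeric(K %*% innov)
  P <- (diag(7) - K %*% H) %*% state$P
  ekf_state(q = quat_normalize(x[1:4]), bias = x[5:7], P = (P + t(P)) / 2)
}

#' Run the full fusion filter over a sequence
#'
#' Initializes the orientation from the first sample's accelerometer and
#' magnetometer via [initial_euler()] (bias starts at zero), then
#' alternates prediction (with the previous sample's gyro reading) and
#' correction (with the current sample's accelerometer and magnetometer)
#' for every subsequent sample.
#'
#' @param seq an [imu_sequence()] (uniform rate).
#' @param noise a [noise_config()]; its `p0_*` entries set the initial
#'   covariance.
#' @return object of class `ekf_fit`: list with `estimates` (data.frame
#'   `t`, `q0..q3`, `pitch`, `roll`, `yaw`, `bias_x..z` with bias in
#'   deg/s; one row per input sample) and `final_state`.
#' @export
run_filter <- function(seq, noise = noise_config()) {
  stopifnot(inherits(seq, "imu_sequence"))
  d <- seq$data
  n <- nrow(d)
  T <- 1 / seq$rate
  gyro <- as.matrix(d[c("gyro_x", "gyro_y", "gyro_z")])
  accel <- as.matrix(d[c("accel_x", "accel_y", "accel_z")])
  mag <- as.matrix(d[c("mag_x", "mag_y", "mag_z")])

  e0 <- initial_euler(accel[1, ], mag[1, ])
  st <- ekf_state(q = quat_from_euler(e0),
                  P = diag(c(rep(noise$p0_quat, 4), rep(noise$p0_bias, 3))))
  out_q <- matrix(0, n, 4); out_e <- matrix(0, n, 3); out_b <- matrix(0, n, 3)
  record <- function(i, st) {
    out_q[i, ] <<- st$q
    out_e[i, ] <<- as.numeric(euler_from_quat(st$q))
    out_b[i, ] <<- rad2deg(st$bias)
  }
  record(1, st)
  for (i in 2:n) {
    st <- ekf_predict(st, gyro[i - 1, ], T, noise)
    st <- ekf_update(st, accel[i, ], mag[i, ], noise)
    record(i, st)
  }
  estimates <- data.frame(t = d$t,
                          q0 = out_q[, 1], q1 = out_q[, 2],
                          q2 = out_q[, 3], q3 = out_q[, 4],
                          pitch = out_e[, 1], roll = out_e[, 2], yaw = out_e[, 3],
                          bias_x = out_b[, 1], bias_y = out_b[, 2], bias_z = out_b[, 3])
  structure(list(estimates = estimates, final_state = st,
                 user_id = seq$user_id, rate = seq$rate),
            class = "ekf_fit")
}

#' @export
print.ekf_fit <- function(x, ...) {
  cat(sprintf("<ekf_fit> %d samples at %g Hz; final bias estimate (deg/s): %s\n",
              nrow(x$estimates), x$rate,
              paste(sprintf("%.4f", rad2deg(x$final_state$bias)), collapse = ", ")))
  invisible(x)
}

#' Gyro-only dead reckoning
#'
#' Integrates the gyro channel alone from the same initial orientation the
#' filter uses, with no bias estimation and no accelerometer/magnetometer
#' correction. The drift of this baseline is what the fusion filter is
#' measured against.
#'
#' @inheritParams run_filter
#' @return data.frame `t`, `q0..q3`, `pitch`, `roll`, `yaw`.
#' @export
dead_reckoning <- function(seq) {
  stopifnot(inherits(seq, "imu_sequence"))
  d <- seq$data
  n <- nrow(d)
  T <- 1 / seq$rate
  gyro <- as.matrix(d[c("gyro_x", "gyro_y", "gyro_z")])
  q <- quat_from_euler(initial_euler(
    as.numeric(d[1, c("accel_x", "accel_y", "accel_z")]),
    as.numeric(d[1, c("mag_x", "mag_y", "mag_z")])))
  out_q <- matrix(0, n, 4); out_e <- matrix(0, n, 3)
  out_q[1, ] <- q; out_e[1, ] <- as.numeric(euler_from_quat(q))
  for (i in 2:n) {
    A <- diag(4) + (T / 2) * omega_matrix(deg2rad(gyro[i - 1, ]))
    q <- quat_normalize(as.numeric(A %*% q))
    out_q[i, ] <- q; out_e[i, ] <- as.numeric(euler_from_quat(q))
  }
  data.frame(t = d$t, q0 = out_q[, 1], q1 = out_q[, 2], q2 = out_q[, 3],
             q3 = out_q[, 4], pitch = out_e[, 1], roll = out_e[, 2],
             yaw = out_e[, 3])
}

#' Write filter output as CSV
#' @param fit an `ekf_fit` from [run_filter()].
#' @param path file path.
#' @export
write_orientation_csv <- function(fit, path) {
  stopifnot(inherits(fit, "ekf_fit"))
  utils::write.csv(fit$estimates, path, row.names = FALSE)
  invisible(path)
}
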
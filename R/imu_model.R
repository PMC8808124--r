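#' IMU sequences
#'
#' An `imu_sequence` holds one user's timestamped inertial stream: gyroscope
#' in deg/s, accelerometer in g, magnetometer in Gauss, sampled at a uniform
#' rate, with optional per-sample activity labels. These are the units the
#' sensors report; conversion to SI happens inside the filter.
#'
#' @param data data.frame with columns `t`, `gyro_x`, `gyro_y`, `gyro_z`,
#'   `accel_x`, `accel_y`, `accel_z`, `mag_x`, `mag_y`, `mag_z`.
#' @param user_id character scalar identifying the subject.
#' @param rate sampling rate in Hz.
#' @param labels optional character/factor vector of per-sample activity
#'   labels, one per row of `data`.
#' @return an object of class `imu_sequence`.
#' @export
imu_sequence <- function(data, user_id = "user1", rate = NULL, labels = NULL) {
  req <- imu_channel_names()
  missing_cols <- setdiff(c("t", req), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(vapply(data[c("t", req)], function(x) all(is.finite(x)), TRUE)))
    stop("non-finite values in sensor channels or timestamps")
  dt <- diff(data$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    stop("timestamps not strictly increasing at sample ", bad)
  }
  if (is.null(rate)) {
    if (nrow(data) < 2) stop("rate must be given for a single-sample sequence")
    rate <- 1 / stats::median(dt)
  }
  if (rate <= 0) stop("rate must be positive")
  if (nrow(data) > 1) {
    T <- 1 / rate
    if (any(abs(dt - T) > 1e-6 * T))
      stop("sampling interval is not uniform at rate ", rate, " Hz")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(data))
      stop("labels must align one-to-one with samples")
    labels <- as.character(labels)
  }
  structure(list(user_id = as.character(user_id), data = data,
                 labels = labels, rate = rate),
            class = "imu_sequence")
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> user %s: %d samples at %g Hz (%.2f s)%s\n",
              x$user_id, nrow(x$data), x$rate, nrow(x$data) / x$rate,
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
length.imu_sequence <- function(x) nrow(x$data)

imu_channel_names <- function() {
  c("gyro_x", "gyro_y", "gyro_z",
    "accel_x", "accel_y", "accel_z",
    "mag_x", "mag_y", "mag_z")
}

#' Specification of a simulated orientation trajectory
#'
#' Each Euler angle follows `offset + amplitude * sin(2*pi*freq*t + phase)`
#' (radians); constants are obtained with zero amplitude. The magnetic
#' reference is expressed in the navigation frame (x east, y north, z up)
#' and must have a zero east component: the measurement model assumes the
#' local field has only north and vertical parts.
#'
#' @param duration length of the trajectory in seconds.
#' @param rate sampling rate in Hz.
#' @param pitch,roll,yaw numeric `c(amplitude, freq, phase, offset)` per
#'   angle (radians, Hz, radians, radians); shorter vectors are padded
#'   with zeros.
#' @param gyro_bias_true constant gyro bias in deg/s (3-vector).
#' @param noise_sd list with elements `gyro` (deg/s), `accel` (g),
#'   `mag` (Gauss): per-axis white-noise standard deviations.
#' @param mag_reference navigation-frame magnetic field in Gauss,
#'   `c(east = 0, north, up)`.
#' @param seed integer seed making the generator a pure function.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(duration = 60, rate = 100,
                            pitch = c(0, 0, 0, 0), roll = c(0, 0, 0, 0),
                            yaw = c(0, 0, 0, 0),
                            gyro_bias_true = c(0.5, 0, 0),
                            noise_sd = list(gyro = 0.3, accel = 0.01,
                                            mag = 0.005),
                            mag_reference = c(0, 0.33, -0.45),
                            seed = 1L) {
  pad4 <- function(v) { v <- as.numeric(v); c(v, rep(0, 4 - length(v)))[1:4] }
  if (duration <= 0 || rate <= 0) stop("duration and rate must be positive")
  if (abs(mag_reference[1]) > 0)
    stop("mag_reference must have zero east component")
  if (sqrt(sum(mag_reference^2)) == 0) stop("mag_reference must be nonzero")
  sds <- unlist(noise_sd[c("gyro", "accel", "mag")])
  if (length(sds) != 3 || any(!is.finite(sds)) || any(sds < 0))
    stop("noise_sd must give nonnegative gyro, accel and mag standard deviations")
  if (length(gyro_bias_true) != 3 || any(!is.finite(gyro_bias_true)))
    stop("gyro_bias_true must be a finite 3-vector (deg/s)")
  structure(list(duration = duration, rate = rate,
                 pitch = pad4(pitch), roll = pad4(roll), yaw = pad4(yaw),
                 gyro_bias_true = as.numeric(gyro_bias_true),
                 noise_sd = as.list(sds |> stats::setNames(c("gyro", "accel", "mag"))),
                 mag_reference = as.numeric(mag_reference),
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate an IMU stream with known ground truth
#'
#' Generates a smooth orientation trajectory from the Euler-angle waveforms
#' of a [trajectory_spec()] and synthesizes consistent sensor readings:
#' the gyroscope measures the exact body angular rate (computed analytically
#' from the Euler rates) plus the constant bias plus white noise; the
#' accelerometer measures the gravity reference `g = c(0, 0, 1)` rotated
#' into the body frame plus noise; the magnetometer measures the
#' navigation-frame reference field rotated into the body frame plus noise.
#'
#' @param spec a [trajectory_spec()].
#' @return list with elements `sequence` (an [imu_sequence()]) and `truth`
#'   (data.frame `t`, `q0..q3`, `pitch`, `roll`, `yaw` of the noise-free
#'   orientation).
#' @export
simulate_imu <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stop("spec must be a trajectory_spec")
  n <- round(spec$duration * spec$rate)
  t <- (0:(n - 1)) / spec$rate
  wave <- function(p) p[4] + p[1] * sin(2 * pi * p[2] * t + p[3])
  dwave <- function(p) p[1] * 2 * pi * p[2] * cos(2 * pi * p[2] * t + p[3])
  x <- wave(spec$pitch); y <- wave(spec$roll); z <- wave(spec$yaw)
  xd <- dwave(spec$pitch); yd <- dwave(spec$roll); zd <- dwave(spec$yaw)

  qs <- matrix(0, n, 4)
  om <- matrix(0, n, 3)  # body angular rate, rad/s
  for (i in seq_len(n)) {
    e <- c(x[i], y[i], z[i])
    qs[i, ] <- quat_from_euler(e)
    # body rate for the z-x-y order:
    #   omega_b = Ry' Rx' e_z * zdot + Ry' e_x * xdot + e_y * ydot
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    ez_b <- c(-cx * sy, sx, cx * cy) * zd[i]
    ex_b <- c(cy, 0, sy) * xd[i]
    om[i, ] <- ez_b + ex_b + c(0, yd[i], 0)
  }

  set.seed(spec$seed)
  gyro <- rad2deg(om) +
    matrix(spec$gyro_bias_true, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, sd = spec$noise_sd$gyro), n, 3)
  accel <- t(apply(qs, 1, function(q) quat_rotate(quat_conjugate(q), c(0, 0, 1)))) +
    matrix(stats::rnorm(3 * n, sd = spec$noise_sd$accel), n, 3)
  mag <- t(apply(qs, 1, function(q) quat_rotate(quat_conjugate(q), spec$mag_reference))) +
    matrix(stats::rnorm(3 * n, sd = spec$noise_sd$mag), n, 3)

  data <- data.frame(t = t,
                     gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
                     accel_x = accel[, 1], accel_y = accel[, 2], accel_z = accel[, 3],
                     mag_x = mag[, 1], mag_y = mag[, 2], mag_z = mag[, 3])
  truth <- data.frame(t = t, q0 = qs[, 1], q1 = qs[, 2], q2 = qs[, 3],
                      q3 = qs[, 4], pitch = x, roll = y, yaw = z)
  list(sequence = imu_sequence(data, rate = spec$rate), truth = truth)
}

#' Simulate labeled activity streams for several users
#'
#' Produces per-user multichannel streams in which each activity class has
#' a distinct deterministic signature: a dominant oscillation frequency
#' (`base_freq + freq_step * (class - 1)` Hz) and a per-channel amplitude
#' pattern in which one rotating channel carries a large amplitude
#' (`amp_major`) and the others a small one (`amp_minor`). Class
#' separability is controlled by the additive noise level `noise_sd`.
#' Default frequencies are deliberately incommensurate with typical window
#' lengths so the oscillation phase drifts across consecutive windows of
#' one user, as it would in a continuously recorded stream.
#'
#' The class signals occupy the first `channels` sensor columns (in
#' gyro/accel/mag order); remaining columns carry pure noise. The names of
#' the signal-bearing columns are attached as attribute `signal_channels`.
#'
#' @param n_users,classes,windows_per_class,window_len,channels positive
#'   integer counts. Each user's stream holds `windows_per_class *
#'   window_len` contiguous samples per class.
#' @param rate sampling rate in Hz.
#' @param noise_sd additive white-noise standard deviation (signal units).
#' @param base_freq,freq_step,amp_major,amp_minor class-signature
#'   parameters (Hz, Hz, signal units, signal units).
#' @param seed integer seed.
#' @return list of labeled [imu_sequence()] objects, one per user.
#' @export
simulate_activity_streams <- function(n_users = 5, classes = 3,
                                      windows_per_class = 8, window_len = 32,
                                      channels = 3, rate = 32,
                                      noise_sd = 0.1,
                                      base_freq = 3.3, freq_step = 2.4,
                                      amp_major = 2, amp_minor = 0.5,
                                      seed = 1L) {
  counts <- c(n_users, classes, windows_per_class, window_len, channels)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("n_users, classes, windows_per_class, window_len and channels must be positive integers")
  if (channels > 9) stop("at most 9 sensor channels are available")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  freqs <- base_freq + freq_step * (seq_len(classes) - 1)
  amp <- matrix(amp_minor, classes, channels)
  for (cl in seq_len(classes)) amp[cl, ((cl - 1) %% channels) + 1] <- amp_major

  cols <- imu_channel_names()
  out <- vector("list", n_users)
  for (u in seq_len(n_users)) {
    L <- windows_per_class * window_len
    seg <- vector("list", classes)
    for (cl in seq_len(classes)) {
      tt <- (0:(L - 1)) / rate
      ph <- stats::runif(channels, 0, 2 * pi)
      X <- vapply(seq_len(channels),
                  function(ch) amp[cl, ch] * sin(2 * pi * freqs[cl] * tt + ph[ch]),
                  numeric(L))
      seg[[cl]] <- t(X)
    }
    sig <- do.call(cbind, seg)                      # channels x (classes * L)
    ntot <- ncol(sig)
    full <- matrix(stats::rnorm(9 * ntot, sd = noise_sd), 9, ntot)
    full[seq_len(channels), ] <- full[seq_len(channels), ] + sig
    data <- as.data.frame(t(full))
    names(data) <- cols
    data <- cbind(t = (0:(ntot - 1)) / rate, data)
    labels <- rep(sprintf("class%d", seq_len(classes)), each = L)
    sq <- imu_sequence(data, user_id = sprintf("user%d", u),
                       rate = rate, labels = labels)
    attr(sq, "signal_channels") <- cols[seq_len(channels)]
    out[[u]] <- sq
  }
  out
}

#' Read / write IMU sequences as CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal. Columns `t`,
#' `gyro_x..z`, `accel_x..z`, `mag_x..z`, optional `label` and `user`.
#' Values are written with 15 significant digits so a write/read round
#' trip preserves them to 12 significant digits.
#'
#' @param path file path.
#' @return [imu_sequence()] for `read_imu_csv`; invisibly `path` for
#'   `write_imu_csv`.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE, comment.char = "#")
  req <- c("t", imu_channel_names())
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("parse error in ", path, " (line 1): missing column(s) ",
         paste(missing_cols, collapse = ", "))
  dt <- diff(df$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    stop("parse error in ", path, " (line ", bad + 1,
         "): timestamps not strictly increasing")
  }
  user <- if ("user" %in% names(df)) as.character(df$user[1]) else "user1"
  labels <- if ("label" %in% names(df)) as.character(df$label) else NULL
  imu_sequence(df[req], user_id = user, labels = labels)
}

#' @rdname read_imu_csv
#' @param seq an [imu_sequence()].
#' @export
write_imu_csv <- function(seq, path) {
  stopifnot(inherits(seq, "imu_sequence"))
  df <- seq$data
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  if (!is.null(seq$labels)) df$label <- seq$labels
  df$user <- seq$user_id
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
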
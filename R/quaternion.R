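#' Quaternion and Euler-angle utilities
#'
#' Orientation is represented throughout the package by a unit quaternion
#' `q = c(q0, q1, q2, q3)` (scalar first, Hamilton product convention)
#' encoding the passive rotation from the sensor frame `{b}` to the
#' navigation frame `{n}`: a body-frame vector `v` maps to the navigation
#' frame as `q (x) v (x) q*`.
#'
#' The Euler-angle convention is intrinsic z-x-y: yaw about the navigation
#' z axis, then pitch about the intermediate x axis, then roll about the
#' body y axis, so that `R_b2n = Rz(yaw) %*% Rx(pitch) %*% Ry(roll)`.
#' Pitch lies in `[-pi/2, pi/2]`; roll and yaw in `(-pi, pi]`. This is the
#' convention under which the tilt-compensated compass initialisation
#' ([initial_euler()]) takes its standard closed form.
#'
#' @name quaternion
NULL

#' Construct an Euler-angle triple
#'
#' @param pitch,roll,yaw angles in radians (pitch about x, roll about y,
#'   yaw about z; see [quaternion] for the rotation order).
#' @return an object of class `euler_angles` (named numeric vector).
#' @export
euler_angles <- function(pitch, roll, yaw) {
  stopifnot(is.finite(pitch), is.finite(roll), is.finite(yaw))
  if (pitch < -pi / 2 - 1e-9 || pitch > pi / 2 + 1e-9)
    stop("pitch must lie in [-pi/2, pi/2]")
  structure(c(pitch = pitch, roll = roll, yaw = yaw), class = "euler_angles")
}

#' Quaternion from Euler angles
#'
#' Composes `qz(yaw) (x) qx(pitch) (x) qy(roll)` (Hamilton product,
#' scalar-first), the quaternion equivalent of the z-x-y rotation order.
#'
#' @param e an [euler_angles()] object or numeric `c(pitch, roll, yaw)`.
#' @return unit quaternion `c(q0, q1, q2, q3)`.
#' @export
quat_from_euler <- function(e) {
  e <- as.numeric(e)
  qx <- c(cos(e[1] / 2), sin(e[1] / 2), 0, 0)
  qy <- c(cos(e[2] / 2), 0, sin(e[2] / 2), 0)
  qz <- c(cos(e[3] / 2), 0, 0, sin(e[3] / 2))
  quat_normalize(quat_multiply(quat_multiply(qz, qx), qy))
}

#' Euler angles from a quaternion
#'
#' Inverse of [quat_from_euler()] away from gimbal lock
#' (`|pitch| = pi/2`).
#'
#' @param q unit quaternion.
#' @return an [euler_angles()] object.
#' @export
euler_from_quat <- function(q) {
  R <- quat_to_matrix(q)
  pitch <- asin(max(-1, min(1, R[3, 2])))
  roll <- atan2(-R[3, 1], R[3, 3])
  yaw <- atan2(-R[1, 2], R[2, 2])
  euler_angles(pitch, roll, yaw)
}

#' Hamilton product of two quaternions
#' @param p,q quaternions, scalar first.
#' @return `p (x) q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' @rdname quat_multiply
#' @param q quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit length
#' @param q quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotate a body-frame vector into the navigation frame
#'
#' Evaluates the sandwich product `q (x) [0, v] (x) q*` and returns its
#' vector part. For unit `q` this is the rotation `R_b2n %*% v`.
#'
#' @param q unit quaternion (frame `{b}` to `{n}`).
#' @param v length-3 vector in `{b}`.
#' @export
quat_rotate <- function(q, v) {
  p <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  p[2:4]
}

#' Rotation matrix (body to navigation) from a quaternion
#' @param q unit quaternion.
#' @return 3x3 rotation matrix `R_b2n`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
}

#' Angular-rate matrix of the quaternion kinematic equation
#'
#' Returns the antisymmetric 4x4 matrix `Omega(omega)` for which the
#' continuous-time quaternion kinematics read `dq/dt = 0.5 * Omega %*% q`,
#' with `omega` the body-frame angular rate in rad/s.
#'
#' @param omega length-3 angular rate (rad/s).
#' @return 4x4 antisymmetric matrix.
#' @export
omega_matrix <- function(omega) {
  wx <- omega[1]; wy <- omega[2]; wz <- omega[3]
  matrix(c(
    0,  -wx, -wy, -wz,
    wx,  0,   wz, -wy,
    wy, -wz,  0,   wx,
    wz,  wy, -wx,  0
  ), 4, 4, byrow = TRUE)
}

# Xi(q): the 4x3 matrix with Omega(omega) %*% q == Xi(q) %*% omega.
# Used for the bias block of the transition Jacobian and for mapping
# gyro noise onto the quaternion coordinates.
xi_matrix <- function(q) {
  matrix(c(
    -q[2], -q[3], -q[4],
     q[1], -q[4],  q[3],
     q[4],  q[1], -q[2],
    -q[3],  q[2],  q[1]
  ), 4, 3, byrow = TRUE)
}

# Jacobian of the polynomial map q -> R(q) %*% v with v held constant,
# as a 3x4 matrix. Valid for any q (no unit-norm assumption), which is
# what makes it consistent with finite differencing the sandwich product.
drotate_dq <- function(q, v) {
  w <- q[1]; qv <- q[2:4]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  skew <- function(a) matrix(c(0, -a[3], a[2],
                               a[3], 0, -a[1],
                               -a[2], a[1], 0), 3, 3, byrow = TRUE)
  col0 <- 2 * w * v + 2 * cross(qv, v)
  Jv <- -2 * outer(v, qv) + 2 * outer(qv, v) +
    2 * sum(qv * v) * diag(3) - 2 * w * skew(v)
  cbind(col0, Jv, deparse.level = 0)
}

# Jacobian of q -> R(q)^T %*% v (navigation -> body) with v constant.
drotate_inv_dq <- function(q, v) {
  drotate_dq(quat_conjugate(q), v) %*% diag(c(1, -1, -1, -1))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
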
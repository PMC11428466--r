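# Quaternion and rotation utilities.
#
# Conventions used throughout the package:
#  * quaternions are scalar-first numeric vectors c(w, x, y, z), unit norm,
#    right-handed, and encode the body -> spatial rotation: v_spatial = R(q) v_body;
#  * Euler angles are intrinsic Tait-Bryan z-y'-x'' (yaw, pitch, roll),
#    R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll);
#  * q and -q encode the same attitude; time series are kept hemisphere-
#    continuous by sign flips.

#' Normalize a quaternion to unit length
#'
#' @param q numeric length-4 quaternion, scalar first.
#' @return unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n == 0) stop("cannot normalize zero or non-finite quaternion")
  q / n
}

#' Quaternion (Hamilton) product
#'
#' Composition `quat_multiply(q2, q1)` is the rotation q1 followed by q2,
#' matching `R(q2) %*% R(q1)`.
#'
#' @param q,p scalar-first quaternions.
#' @return quaternion product q * p.
#' @export
quat_multiply <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q scalar-first quaternion.
#' @return conjugate quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotation matrix from a unit quaternion
#' @param q scalar-first unit quaternion (body -> spatial).
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Uses Shepperd's method (largest diagonal pivot) for numerical stability.
#' The scalar part is returned non-negative.
#'
#' @param R 3x3 rotation matrix.
#' @return scalar-first unit quaternion.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= R[1, 1] && tr >= R[2, 2] && tr >= R[3, 3]) {
    w <- sqrt(max(0, 1 + tr)) / 2
    q <- c(w,
           (R[3, 2] - R[2, 3]) / (4 * w),
           (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    x <- sqrt(max(0, 1 + R[1, 1] - R[2, 2] - R[3, 3])) / 2
    q <- c((R[3, 2] - R[2, 3]) / (4 * x),
           x,
           (R[1, 2] + R[2, 1]) / (4 * x),
           (R[1, 3] + R[3, 1]) / (4 * x))
  } else if (R[2, 2] >= R[3, 3]) {
    y <- sqrt(max(0, 1 + R[2, 2] - R[1, 1] - R[3, 3])) / 2
    q <- c((R[1, 3] - R[3, 1]) / (4 * y),
           (R[1, 2] + R[2, 1]) / (4 * y),
           y,
           (R[2, 3] + R[3, 2]) / (4 * y))
  } else {
    z <- sqrt(max(0, 1 + R[3, 3] - R[1, 1] - R[2, 2])) / 2
    q <- c((R[2, 1] - R[1, 2]) / (4 * z),
           (R[1, 3] + R[3, 1]) / (4 * z),
           (R[2, 3] + R[3, 2]) / (4 * z),
           z)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Quaternion from an axis-angle rotation
#' @param axis length-3 rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return scalar-first unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be nonzero")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Axis-angle decomposition of a unit quaternion
#'
#' @param q scalar-first unit quaternion.
#' @return list with `angle` in `[0, pi]` and unit `axis` (arbitrary axis for
#'   the identity rotation).
#' @export
quat_to_axis_angle <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q            # angle in [0, pi]
  s <- sqrt(sum(q[2:4]^2))
  angle <- 2 * atan2(s, q[1])
  axis <- if (s < 1e-15) c(1, 0, 0) else q[2:4] / s
  list(angle = angle, axis = axis)
}

#' Rotate 3D points by a quaternion
#' @param q scalar-first unit quaternion (body -> spatial).
#' @param v length-3 vector or n x 3 matrix of row vectors.
#' @return rotated vector or matrix, same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

#' Elementary rotation matrices
#' @param a angle, radians.
#' @return 3x3 rotation matrix about the named axis.
#' @keywords internal
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Euler angles (intrinsic z-y'-x'': yaw, pitch, roll) to quaternion
#'
#' The reference orientation (0, 0, 0) has the body axes aligned with the
#' spatial axes (x cranial, y lateral, z dorsal, Z vertical up).
#'
#' @param yaw,pitch,roll angles in radians.
#' @return scalar-first unit quaternion.
#' @export
euler_to_quat <- function(yaw, pitch, roll) {
  matrix_to_quat(rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll))
}

#' Euler angles from a quaternion
#'
#' Returns intrinsic Tait-Bryan z-y'-x'' angles with yaw, roll in (-pi, pi]
#' and pitch in [-pi/2, pi/2]. At gimbal lock (|pitch| = pi/2) roll is set to
#' 0 and the remaining freedom folded into yaw, deterministically.
#'
#' @param q scalar-first unit quaternion.
#' @return named numeric vector c(yaw, pitch, roll) in radians.
#' @export
quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  sp <- -R[3, 1]
  if (abs(sp) >= 1 - 1e-10) {
    pitch <- if (sp > 0) pi / 2 else -pi / 2
    roll <- 0
    yaw <- atan2(-R[1, 2], R[2, 2])
  } else {
    pitch <- asin(sp)
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  c(yaw = yaw, pitch = pitch, roll = roll)
}

#' Enforce hemisphere continuity along a quaternion time series
#'
#' Flips the sign of quaternions so consecutive samples satisfy
#' `sum(q[t] * q[t-1]) >= 0`; q and -q encode the same attitude.
#'
#' @param Q n x 4 matrix of scalar-first quaternions (rows; may contain NA rows).
#' @return n x 4 matrix with continuous signs.
#' @export
quat_continuity <- function(Q) {
  stopifnot(is.matrix(Q), ncol(Q) == 4)
  prev <- NULL
  for (i in seq_len(nrow(Q))) {
    if (anyNA(Q[i, ])) next
    if (!is.null(prev) && sum(Q[i, ] * prev) < 0) Q[i, ] <- -Q[i, ]
    prev <- Q[i, ]
  }
  Q
}

#' Vector cross product
#' @param a,b length-3 numeric vectors.
#' @return a x b.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle) {
  quat_to_matrix(quat_from_axis_angle(axis, angle))
}
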
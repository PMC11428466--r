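# Rigid-body attitude estimation from tracked landmarks, angular velocity,
# and the dorsoventral orientation index Z_dv.

#' Least-squares rigid attitude from matched landmark sets
#'
#' Solves the absolute-orientation problem: the rotation + translation (no
#' scaling) that best maps a reference landmark configuration (body frame)
#' onto an observed configuration (spatial frame) in the least-squares sense,
#' via SVD of the cross-covariance (Kabsch/Horn).
#'
#' @param reference n x 3 matrix of landmark positions in the body frame.
#' @param observed n x 3 matrix of the same landmarks in the spatial frame.
#'   Rows with missing values in either matrix are dropped pairwise.
#' @return list with `q` (scalar-first unit quaternion, body -> spatial),
#'   `translation` (body origin in the spatial frame), `rmsd` (m), and `n_used`.
#' @export
estimate_attitude <- function(reference, observed) {
  reference <- as.matrix(reference); observed <- as.matrix(observed)
  stopifnot(ncol(reference) == 3, ncol(observed) == 3,
            nrow(reference) == nrow(observed))
  ok <- stats::complete.cases(reference) & stats::complete.cases(observed)
  ref <- reference[ok, , drop = FALSE]
  obs <- observed[ok, , drop = FALSE]
  if (nrow(ref) < 3) stop("attitude estimation needs >= 3 common landmarks")
  cr <- colMeans(ref); co <- colMeans(obs)
  A <- sweep(ref, 2, cr); B <- sweep(obs, 2, co)
  # degenerate (collinear) configurations have rank < 2 cross-covariance
  M <- t(B) %*% A                     # maps reference axes -> observed
  s <- svd(M)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300)) {
    stop("degenerate (collinear) landmark configuration")
  }
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- co - as.numeric(R %*% cr)
  resid <- obs - (ref %*% t(R) + matrix(t_vec, nrow(obs), 3, byrow = TRUE))
  list(q = matrix_to_quat(R),
       translation = t_vec,
       rmsd = sqrt(mean(rowSums(resid^2))),
       n_used = nrow(ref))
}

#' Angular velocity from two attitudes
#'
#' Decomposes the relative rotation `q2 * q1^-1` (spatial frame) into
#' axis-angle and returns `omega = (angle / dt) * axis`.
#'
#' @param q1,q2 scalar-first unit quaternions at times t and t + dt.
#' @param dt time step, s (> 0).
#' @return list with `omega` (rad/s 3-vector, spatial frame), `axis` (unit),
#'   and `angle` (rad, in `[0, pi]`).
#' @export
angular_velocity <- function(q1, q2, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive finite scalar")
  }
  q_rel <- quat_multiply(q2, quat_conjugate(q1))
  aa <- quat_to_axis_angle(q_rel)
  list(omega = (aa$angle / dt) * aa$axis, axis = aa$axis, angle = aa$angle)
}

#' Angular velocity series from a quaternion time series
#'
#' Central differences over attitude pairs (one-sided at the ends); frames
#' without two valid neighbouring attitudes yield NA.
#'
#' @param Q n x 4 matrix of scalar-first quaternions (rows, NA rows allowed).
#' @param times numeric times, s.
#' @return n x 3 matrix of angular velocity vectors, rad/s, spatial frame.
#' @export
angular_velocity_series <- function(Q, times) {
  n <- nrow(Q)
  W <- matrix(NA_real_, n, 3)
  valid <- !apply(Q, 1, anyNA)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    lo <- if (i > 1 && valid[i - 1]) i - 1 else i
    hi <- if (i < n && valid[i + 1]) i + 1 else i
    if (lo == hi) next
    dt <- times[hi] - times[lo]
    if (dt <= 0) next
    W[i, ] <- angular_velocity(Q[lo, ], Q[hi, ], dt)$omega
  }
  W
}

#' Vertical component of the dorsoventral axis, Z_dv
#'
#' The dorsal -> ventral unit axis is the body-frame (0, 0, -1) direction
#' (body z points ventral -> dorsal). Z_dv is its Z-component in the spatial
#' frame: +1 when overturned flat on the back, 0 at the flipping point, -1
#' when upright with the axis pointing straight down.
#'
#' @param q scalar-first unit quaternion or n x 4 matrix of quaternions.
#' @return numeric Z_dv in `[-1, 1]` (vector for matrix input).
#' @export
compute_Zdv <- function(q) {
  one <- function(qi) {
    if (anyNA(qi)) return(NA_real_)
    qi <- quat_normalize(qi)
    # -R[3,3] = 2 (x^2 + y^2) - 1
    2 * (qi[2]^2 + qi[3]^2) - 1
  }
  if (is.matrix(q)) apply(q, 1, one) else one(q)
}

#' Roll + pitch component of the spin rate
#'
#' Magnitude of the angular velocity after removing the component along the
#' body yaw (dorsoventral) axis, i.e. the spin rate about the body roll and
#' pitch axes only.
#'
#' @param omega length-3 angular velocity, spatial frame, rad/s.
#' @param q attitude quaternion at the same frame.
#' @return scalar rad/s.
#' @export
spin_rate_rollpitch <- function(omega, q) {
  if (anyNA(omega) || anyNA(q)) return(NA_real_)
  zb <- quat_rotate(q, c(0, 0, 1))   # body yaw axis in spatial frame
  w_yaw <- sum(omega * zb) * zb
  sqrt(sum((omega - w_yaw)^2))
}
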
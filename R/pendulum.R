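# Inverted-physical-pendulum template: the insect modelled as a rigid body
# rotating about a fixed pivot point on the ground. Supplies the pivot
# estimate, orbital kinematics, pendulum inertia and available kinetic
# energy, natural period, and net/reaction torque and per-leg force.

GRAVITY <- 9.81  # m s^-2

#' Locate the ground pivot point
#'
#' The pivot is the time-mean position of the most stationary in-contact
#' landmark over the window. Body (non-tarsus) landmarks are preferred;
#' if none is in contact, the in-contact tarsus with minimal displacement
#' is used.
#'
#' @param trial a `tracked_trial` (smoothed positions recommended).
#' @param contact_sets list (one element per frame) of character vectors of
#'   in-contact landmark names.
#' @param frames frame indices defining the window (default all).
#' @param min_contact_frac minimum fraction of window frames a landmark must
#'   be in contact to qualify (default 0.5).
#' @return list with `pivot` (length-3, NA if undefined), `landmark` name,
#'   `stationarity` (RMS displacement about the mean, m), and `defined`.
#' @export
locate_pivot <- function(trial, contact_sets, frames = seq_along(trial$times),
                         min_contact_frac = 0.5) {
  cs <- contact_sets[frames]
  all_contact <- unique(unlist(cs))
  if (length(all_contact) == 0) {
    return(list(pivot = rep(NA_real_, 3), landmark = NA_character_,
                stationarity = NA_real_, defined = FALSE))
  }
  frac <- vapply(all_contact, function(nm) {
    mean(vapply(cs, function(s) nm %in% s, logical(1)))
  }, numeric(1))
  score <- function(nm) {
    P <- trial$landmarks[[nm]][frames, , drop = FALSE]
    P <- P[stats::complete.cases(P), , drop = FALSE]
    if (nrow(P) == 0) return(list(rms = Inf, mean = rep(NA_real_, 3)))
    mu <- colMeans(P)
    list(rms = sqrt(mean(rowSums(sweep(P, 2, mu)^2))), mean = mu)
  }
  is_body <- !grepl("^tarsus_", all_contact)
  cand <- all_contact[is_body & frac >= min_contact_frac]
  if (length(cand) == 0) cand <- all_contact[frac >= min_contact_frac]
  if (length(cand) == 0) cand <- all_contact
  scores <- lapply(cand, score)
  rms <- vapply(scores, `[[`, numeric(1), "rms")
  best <- which.min(rms)
  list(pivot = scores[[best]]$mean, landmark = cand[best],
       stationarity = rms[best], defined = is.finite(rms[best]))
}

#' Orbital kinematics of the COM about the pivot
#'
#' COM speed `v_orbital` (norm of the smoothed COM velocity), pivot-COM
#' distance `d`, orbital angular velocity `omega_orbital = v_orbital / d`,
#' and its time derivative `alpha_orbital`, all computed with the local
#' quadratic derivative operator.
#'
#' @param com n x 3 matrix of whole-insect COM positions, m.
#' @param times sample times, s.
#' @param pivot length-3 pivot point, m.
#' @param window_ms derivative window, ms (default 25).
#' @param d_min minimum pivot-COM distance, m; frames with `d <= d_min` get
#'   NA angular values (division guard, flagged in `guarded`).
#' @return data.frame with columns `d`, `v_orbital`, `omega_orbital`,
#'   `alpha_orbital`, `guarded`.
#' @export
orbital_kinematics <- function(com, times, pivot, window_ms = 25,
                               d_min = 1e-3) {
  if (anyNA(pivot)) stop("pivot must be defined")
  rel <- sweep(com, 2, pivot)
  d <- sqrt(rowSums(rel^2))
  v <- cbind(derivative_series(com[, 1], times, window_ms),
             derivative_series(com[, 2], times, window_ms),
             derivative_series(com[, 3], times, window_ms))
  v_orb <- sqrt(rowSums(v^2))
  guarded <- !is.na(d) & d <= d_min
  omega <- ifelse(guarded, NA_real_, v_orb / d)
  alpha <- derivative_series(omega, times, window_ms)
  data.frame(d = d, v_orbital = v_orb, omega_orbital = omega,
             alpha_orbital = alpha, guarded = guarded)
}

#' Pendulum moment of inertia and available kinetic energy
#'
#' `I_pendulum` is the whole-insect spin inertia about the rotation axis
#' through the COM transferred to the pivot by the parallel-axis theorem;
#' the available kinetic energy is that of the equivalent pendulum,
#' `KE_avail = 1/2 I_pendulum omega_orbital^2`.
#'
#' @param I_spin spin moment of inertia about the COM along the rotation
#'   axis, kg m^2 (vectorized).
#' @param M whole-insect mass, kg.
#' @param d pivot-COM distance, m (vectorized).
#' @param omega_orbital orbital angular velocity, rad/s (vectorized).
#' @return data.frame with `I_pendulum` and `KE_avail`.
#' @export
pendulum_inertia_and_ke <- function(I_spin, M, d, omega_orbital) {
  I_pend <- I_spin + M * d^2
  data.frame(I_pendulum = I_pend,
             KE_avail = 0.5 * I_pend * omega_orbital^2)
}

#' Natural period of the inverted physical pendulum
#'
#' `T = 2 pi sqrt(I_pendulum / (M g d))`: the timescale both for toppling
#' if support is lost and for rotating upright from a given start.
#'
#' @param I_pendulum pendulum moment of inertia about the pivot, kg m^2.
#' @param M mass, kg.
#' @param d pivot-COM distance, m.
#' @param g gravitational acceleration, m s^-2 (default 9.81).
#' @return period, s.
#' @export
pendulum_period <- function(I_pendulum, M, d, g = GRAVITY) {
  if (any(c(I_pendulum, M, d, g) <= 0)) {
    stop("pendulum_period requires positive I, M, d, g")
  }
  2 * pi * sqrt(I_pendulum / (M * g * d))
}

#' Time for a constant torque to rotate an object through an angle
#'
#' From `theta = 1/2 (tau / I) t^2`.
#'
#' @param theta rotation angle, rad (> 0).
#' @param I moment of inertia about the rotation axis, kg m^2.
#' @param tau constant applied torque, N m (> 0).
#' @return time, s.
#' @export
rotation_time <- function(theta, I, tau) {
  if (any(c(theta, I, tau) <= 0)) stop("rotation_time requires positive inputs")
  sqrt(2 * theta * I / tau)
}

#' Net and reaction torque about the pivot, and force per leg
#'
#' `tau_net = I_pendulum * alpha_orbital`; gravity contributes
#' `tau_grav = -M g * arm` where the arm is, by default, the horizontal
#' distance `r_com` between the pivot and the COM's ground projection (the
#' physically correct arm for a vertical force); set
#' `gravity_arm = "d"` to use the full pivot-COM distance instead. The net
#' ground reaction torque is `tau_reaction = tau_net - tau_grav`, the net
#' ground reaction force `F_reaction = tau_reaction / r_perp`, and the mean
#' force per leg divides by the number of tarsi in contact.
#'
#' @param I_pendulum pendulum inertia, kg m^2 (vectorized).
#' @param alpha_orbital orbital angular acceleration, rad s^-2.
#' @param M mass, kg.
#' @param r_com horizontal pivot to COM-ground-projection distance, m.
#' @param r_perp mean in-contact tarsus-pivot moment arm, m (NA or 0 flags
#'   the frame).
#' @param n_tarsi number of tarsi in contact (0 flags `F_leg` undefined).
#' @param d pivot-COM distance, m; required when `gravity_arm = "d"`.
#' @param gravity_arm `"r_com"` (default) or `"d"`.
#' @param g gravitational acceleration, m s^-2.
#' @return data.frame with `tau_net`, `tau_grav`, `tau_reaction`,
#'   `F_reaction`, `F_leg`, `F_leg_bw` (body weights).
#' @export
reaction_torque_and_force <- function(I_pendulum, alpha_orbital, M, r_com,
                                      r_perp, n_tarsi, d = NULL,
                                      gravity_arm = c("r_com", "d"),
                                      g = GRAVITY) {
  gravity_arm <- match.arg(gravity_arm)
  arm <- if (gravity_arm == "r_com") r_com else {
    if (is.null(d)) stop("gravity_arm = 'd' requires d")
    d
  }
  tau_net <- I_pendulum * alpha_orbital
  tau_grav <- -M * g * arm
  tau_reaction <- tau_net - tau_grav
  r_ok <- !is.na(r_perp) & r_perp > 0
  F_reaction <- ifelse(r_ok, tau_reaction / r_perp, NA_real_)
  n_ok <- !is.na(n_tarsi) & n_tarsi >= 1
  F_leg <- ifelse(n_ok, F_reaction / n_tarsi, NA_real_)
  data.frame(tau_net = tau_net, tau_grav = tau_grav,
             tau_reaction = tau_reaction, F_reaction = F_reaction,
             F_leg = F_leg, F_leg_bw = F_leg / (M * g))
}
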
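# Synthetic righting trials with exact ground truth.
#
# The generator emulates the study conditions: a rigid flattened body (an
# ellipsoid stand-in with analytically checkable inertia, or any supplied
# mesh) rotating about a fixed horizontal axis through a ground pivot
# (inverted physical pendulum), with six articulated two-segment legs that
# either stay planted on the ground (no-slip stance) or follow prescribed
# body-frame swing trajectories, sampled at 1000 fps with mm-scale Gaussian
# landmark noise. Dynamics integrate tau = I * alpha about the pivot axis
# (fixed-step 4th-order Runge-Kutta at the frame interval) under gravity
# plus a piecewise-constant applied-torque program; the same config and
# seed always reproduce the identical trial.

#' Configuration for a synthetic righting trial
#'
#' @param mode righting mode to emulate: `"diagonal_rotating"` (body pivot,
#'   rotation axis oblique to the lateral axis), `"lifted_rotating"` (body
#'   airborne, legs-only support, roll about the stance line),
#'   `"pitching"` (rotation about the lateral axis, caudal pivot), or
#'   `"failed"` (diagonal geometry, every attempt released early).
#' @param n_attempts number of attempts; in non-failed modes the last one
#'   succeeds.
#' @param frame_rate sampling rate, frames/s (default 1000).
#' @param noise_sd landmark observation noise SD per coordinate, m
#'   (default 0.2 mm).
#' @param seed integer RNG seed; same config + seed gives identical output.
#' @param semi_axes body ellipsoid semi-axes (x cranial, y lateral, z
#'   dorsoventral), m; default half the 8.9 mm standardized body length,
#'   1.8 mm, 1.1 mm.
#' @param total_mass whole-insect mass, kg (default 28.4 mg); body mass is
#'   the remainder after the morphometrics' leg masses.
#' @param morph leg morphometrics table.
#' @param legs_rigid if TRUE the legs stay frozen in the body frame (the
#'   purely rigid pendulum; mechanical energy is exactly conserved when no
#'   torque is applied).
#' @param torque_margin applied-torque safety factor over the peak gravity
#'   deficit (default 1.4).
#' @param applied_torque optional override, N m: constant torque used during
#'   the up-stroke of every attempt.
#' @param swing_peak fraction of the success stroke at which the swing legs
#'   reach peak elevation (default 0.68, i.e. shortly after the flip).
#' @param swing_freq swing oscillation frequency, Hz (default 12).
#' @param pre_quiescent_s overturned rest before the first attempt, s.
#' @param post_rest_s upright rest recorded after success, s.
#' @param fail_gap_s quiescent gap after a failed attempt, s.
#' @param mesh optional `body_mesh` to use instead of the ellipsoid.
#' @param mesh_n ellipsoid tessellation `c(n_theta, n_phi)`.
#' @return list of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(mode = c("diagonal_rotating",
                                            "lifted_rotating", "pitching",
                                            "failed"),
                                   n_attempts = 1, frame_rate = 1000,
                                   noise_sd = 2e-4, seed = 1,
                                   semi_axes = c(4.45e-3, 1.8e-3, 1.1e-3),
                                   total_mass = 28.4e-6,
                                   morph = default_leg_morphometrics(),
                                   legs_rigid = FALSE, torque_margin = 1.4,
                                   applied_torque = NULL, swing_peak = 0.68,
                                   swing_freq = 12,
                                   pre_quiescent_s = 0.05, post_rest_s = 0.25,
                                   fail_gap_s = 0.08, mesh = NULL,
                                   mesh_n = c(24, 36)) {
  mode <- match.arg(mode)
  stopifnot(n_attempts >= 1, frame_rate > 0, noise_sd >= 0,
            all(semi_axes > 0), total_mass > 0)
  morph <- validate_leg_morphometrics(morph)
  if (total_leg_mass(morph) >= total_mass) {
    stop("leg mass exceeds total mass")
  }
  structure(as.list(environment()), class = "synthetic_trial_config")
}

#' Integrate rotation about a fixed pivot axis
#'
#' Fixed-step classical Runge-Kutta integration of
#' `I dphi^2/dt^2 = tau_gravity(phi) + tau_applied(t)`.
#'
#' @param I moment of inertia about the axis, kg m^2.
#' @param tau_grav function(phi) -> gravity torque about the axis, N m.
#' @param tau_applied function(t) -> applied torque, N m.
#' @param phi0,omega0 initial angle (rad) and rate (rad/s).
#' @param times output times, s (uniform; the integrator step).
#' @return data.frame with `t`, `phi`, `omega`.
#' @export
integrate_pivoted_rotation <- function(I, tau_grav, tau_applied, phi0,
                                       omega0, times) {
  n <- length(times)
  phi <- numeric(n); omega <- numeric(n)
  phi[1] <- phi0; omega[1] <- omega0
  deriv <- function(t, y) {
    c(y[2], (tau_grav(y[1]) + tau_applied(t)) / I)
  }
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    y <- c(phi[i], omega[i])
    k1 <- deriv(times[i], y)
    k2 <- deriv(times[i] + h / 2, y + h / 2 * k1)
    k3 <- deriv(times[i] + h / 2, y + h / 2 * k2)
    k4 <- deriv(times[i] + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (abs(y[2]) > 1e3) stop("integration unstable: |omega| > 1000 rad/s (bad torque program)")
    phi[i + 1] <- y[1]; omega[i + 1] <- y[2]
  }
  data.frame(t = times, phi = phi, omega = omega)
}

# body-frame coxa positions given ellipsoid semi-axes
.coxa_body <- function(ax) {
  xs <- c(0.50, 0.07, -0.40) * ax[1]
  data.frame(leg = leg_names(),
             x = rep(xs, 2),
             y = rep(c(0.85, -0.85), each = 3) * ax[2] *
               c(1, 1, 1, 1, 1, 1),
             z = -0.35 * ax[3])
}

# fixed body-frame landmark set
.body_landmarks <- function(ax) {
  rbind(cranial = c(ax[1], 0, 0),
        caudal = c(-ax[1], 0, 0),
        dorsum_mid = c(0, 0, ax[3]))
}

# simple elbow placement between coxa and tarsus with a bend offset
.elbow_point <- function(coxa, tarsus, bend_dir) {
  v <- tarsus - coxa
  L <- sqrt(sum(v^2))
  bd <- bend_dir - sum(bend_dir * v) * v / max(L^2, 1e-12)
  nb <- sqrt(sum(bd^2))
  mid <- coxa + 0.45 * v
  if (nb < 1e-9 || L < 1e-9) return(mid)
  mid + 0.30 * L * bd / nb
}

# mode geometry: initial attitude, rotation axis, pivot, stance assignment
.mode_geometry <- function(cfg) {
  ax <- cfg$semi_axes
  a <- ax[1]; b <- ax[2]; c_ <- ax[3]
  mode <- if (cfg$mode == "failed") "diagonal_rotating" else cfg$mode
  if (mode %in% c("diagonal_rotating", "pitching")) {
    gam <- -asin(c_ / a)              # pitch tilt dropping the caudal end
    yaw0 <- if (mode == "diagonal_rotating") 42 * pi / 180 else 0
    R0 <- rot_z(yaw0) %*% rot_y(gam) %*% rot_x(pi)
    origin0 <- c(0, 0, c_)
    caudal0 <- origin0 + as.numeric(R0 %*% c(-a, 0, 0))
    axis <- c(0, -1, 0)               # spatial; positive rotation lifts COM
    pivot <- caudal0
    pivot_landmark <- "caudal"
    stance <- c("R1", "R2", "R3", "L3")
    swing <- c("L1", "L2")
    if (mode == "pitching") { stance <- c("L3", "R3"); swing <- c("L1", "R1", "L2", "R2") }
    lift <- 0
  } else {                            # lifted_rotating
    gam <- 0; yaw0 <- 0
    lift <- 1.5e-3
    R0 <- rot_x(pi)
    origin0 <- c(0, 0, c_ + lift)
    axis <- c(1, 0, 0)
    pivot <- c(0, -2.1e-3, 0)         # on the stance-foot line
    pivot_landmark <- NA_character_
    stance <- c("R1", "R2", "R3")
    swing <- c("L1", "L2", "L3")
    caudal0 <- origin0 + as.numeric(R0 %*% c(-a, 0, 0))
  }
  # flip axis sign so positive phi raises the COM
  r0 <- origin0 - pivot
  if (cross3(axis, r0)[3] < 0) axis <- -axis
  list(R0 = R0, q0 = matrix_to_quat(R0), origin0 = origin0, axis = axis,
       pivot = pivot, pivot_landmark = pivot_landmark, stance = stance,
       swing = swing, gamma = gam, yaw0 = yaw0, lift = lift)
}

# stance-foot ground targets (spatial, z = 0) for the overturned phase
.stance_targets <- function(cfg, geo) {
  ax <- cfg$semi_axes
  a <- ax[1]
  mode <- if (cfg$mode == "failed") "diagonal_rotating" else cfg$mode
  tg <- switch(mode,
    diagonal_rotating = rbind(
      R1 = c(0.75 * a, -1.2e-3, 0),
      R2 = c(0.0, -3.0e-3, 0),
      R3 = c(-1.25 * a, -2.4e-3, 0),
      L3 = c(-1.25 * a, 2.4e-3, 0)),
    pitching = rbind(
      L3 = c(-1.15 * a, 1.8e-3, 0),
      R3 = c(-1.15 * a, -1.8e-3, 0)),
    lifted_rotating = rbind(
      # stance feet on the roll axis line: a line support can never
      # enclose the COM projection, so SM stays <= 0 until upright
      R1 = c(0.65 * a, -2.1e-3, 0),
      R2 = c(0.0, -2.1e-3, 0),
      R3 = c(-0.75 * a, -2.1e-3, 0)))
  tg
}

# swing tarsus trajectory, prescribed in the spatial frame relative to the
# moving coxa: the raised leg arcs up and over the body, peaking at
# swing_peak of the stroke (i.e. around/after the flip), with a per-leg
# phase-lagged oscillation; s in [0,1] is stroke progress, t_att seconds
# since attempt start
.swing_phase_lag <- function(leg) {
  switch(leg, L1 = 0, R1 = 0.25, L2 = 0.3, R2 = 0.55, L3 = 0.35, R3 = 0.6)
}

.swing_tarsus_spatial <- function(leg, cfg, s, t_att, coxa_sp, origin,
                                  fwd = c(1, 0, 0)) {
  lag <- .swing_phase_lag(leg)
  centre <- cfg$swing_peak + 0.10 * lag
  lateral <- coxa_sp - origin
  lateral[3] <- 0
  nl <- sqrt(sum(lateral^2))
  dir <- if (nl > 1e-9) lateral / nl else c(1, 0, 0)
  active <- s > 0.02
  h <- 2.2e-3 * (1 - s)^0.5 +
    7.0e-3 * exp(-((s - centre) / 0.14)^2) +
    (if (active) 0.8e-3 * exp(-((s - centre) / 0.25)^2) *
       sin(2 * pi * cfg$swing_freq * t_att - 2 * pi * lag) else 0)
  # forward reach: fore/mid legs grasp ahead of the body; largest during
  # pitching, where the insect levers itself forward over its caudal end
  reach <- if (cfg$mode == "pitching") 2.6e-3 else 1.2e-3
  coxa_sp + dir * 2.0e-3 + fwd * reach + c(0, 0, h)
}

# righted standing stance around the body at attitude q, origin o
.righted_stance <- function(cfg, q, o) {
  cox <- .coxa_body(cfg$semi_axes)
  out <- list()
  for (i in seq_len(nrow(cox))) {
    cs <- o + quat_rotate(q, c(cox$x[i], cox$y[i], cox$z[i]))
    lateral <- cs - o
    lateral[3] <- 0
    nl <- sqrt(sum(lateral^2))
    dir <- if (nl > 1e-9) lateral / nl else c(1, 0, 0)
    out[[cox$leg[i]]] <- c(cs[1] + 1.7e-3 * dir[1], cs[2] + 1.7e-3 * dir[2], 0)
  }
  out
}

#' Simulate a synthetic righting trial
#'
#' @param cfg a [synthetic_trial_config()].
#' @return list of class `synthetic_trial` with `trial` (a
#'   [tracked_trial()] with observation noise), `truth` (noise-free
#'   per-frame ground truth: phase labels, rotation angle/rate, COM,
#'   orbital rate, potential/kinetic energy, applied torque), and `config`.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_trial_config"))
  ax <- cfg$semi_axes
  geo <- .mode_geometry(cfg)
  morph <- cfg$morph
  m_legs <- total_leg_mass(morph)
  m_body <- cfg$total_mass - m_legs
  mesh <- if (is.null(cfg$mesh)) {
    ellipsoid_mesh(ax, n_theta = cfg$mesh_n[1], n_phi = cfg$mesh_n[2])
  } else cfg$mesh
  body_mp <- mesh_mass_properties(mesh, m_body)
  dt <- 1 / cfg$frame_rate
  g <- GRAVITY
  cox <- .coxa_body(ax)
  bl <- .body_landmarks(ax)
  stance_tg <- .stance_targets(cfg, geo)

  rot_about_pivot <- function(x0, phi) {
    geo$pivot + as.numeric(axis_angle_matrix(geo$axis, phi) %*% (x0 - geo$pivot))
  }
  att_q <- function(phi) quat_multiply(quat_from_axis_angle(geo$axis, phi), geo$q0)

  # --- initial (overturned) leg endpoint layout, spatial frame -------------
  leg_points0 <- list()
  for (i in seq_len(nrow(cox))) {
    leg <- cox$leg[i]
    coxa_sp <- geo$origin0 + as.numeric(geo$R0 %*% c(cox$x[i], cox$y[i], cox$z[i]))
    if (leg %in% rownames(stance_tg) && !cfg$legs_rigid) {
      tars <- stance_tg[leg, ]
    } else {
      fw0 <- as.numeric(geo$R0 %*% c(1, 0, 0)); fw0[3] <- 0
      fw0 <- fw0 / max(sqrt(sum(fw0^2)), 1e-9)
      tars <- .swing_tarsus_spatial(leg, cfg, s = 0, t_att = 0,
                                    coxa_sp = coxa_sp, origin = geo$origin0,
                                    fwd = fw0)
    }
    elbow <- .elbow_point(coxa_sp, tars, bend_dir = c(0, 0, 1))
    leg_points0[[leg]] <- list(coxa = coxa_sp, femur_tibia = elbow,
                               tarsus = tars)
  }

  # --- rigid dynamic model: body + leg segments frozen at t0 ---------------
  comps <- list(list(m = m_body,
                     p = geo$origin0 + as.numeric(geo$R0 %*% body_mp$com)))
  for (i in seq_len(nrow(cox))) {
    leg <- cox$leg[i]; lp <- leg_points0[[leg]]
    comps[[length(comps) + 1]] <- list(m = morph$seg2_mass[i],
                                       p = (lp$coxa + lp$femur_tibia) / 2)
    comps[[length(comps) + 1]] <- list(m = morph$seg1_mass[i],
                                       p = (lp$femur_tibia + lp$tarsus) / 2)
  }
  # inertia about the pivot axis: body tensor term + point/rod terms
  R0 <- geo$R0
  I_body_sp <- R0 %*% body_mp$inertia_tensor %*% t(R0)
  rb <- comps[[1]]$p - geo$pivot
  d2b <- sum(rb^2) - sum(rb * geo$axis)^2
  I_dyn <- inertia_about_axis((I_body_sp + t(I_body_sp)) / 2, geo$axis) +
    m_body * max(0, d2b)
  k <- 2
  for (i in seq_len(nrow(cox))) {
    leg <- cox$leg[i]; lp <- leg_points0[[leg]]
    I_dyn <- I_dyn +
      .rod_about_line(lp$coxa, lp$femur_tibia, morph$seg2_mass[i],
                      geo$pivot, geo$axis)$I +
      .rod_about_line(lp$femur_tibia, lp$tarsus, morph$seg1_mass[i],
                      geo$pivot, geo$axis)$I
    k <- k + 2
  }

  tau_grav <- function(phi) {
    R <- axis_angle_matrix(geo$axis, phi)
    tot <- 0
    for (cp in comps) {
      r <- as.numeric(R %*% (cp$p - geo$pivot))
      tot <- tot - cp$m * g * (r[2] * geo$axis[1] - r[1] * geo$axis[2])
    }
    tot
  }
  pe_rigid <- function(phi) {
    R <- axis_angle_matrix(geo$axis, phi)
    sum(vapply(comps, function(cp) {
      cp$m * g * (geo$pivot[3] + as.numeric(R %*% (cp$p - geo$pivot))[3])
    }, numeric(1)))
  }

  # stroke plan: apex and end angles of the rigid assembly
  phig <- seq(0, pi, length.out = 721)
  peg <- vapply(phig, pe_rigid, numeric(1))
  phi_apex <- phig[which.max(peg)]
  zdv_of <- function(phi) compute_Zdv(att_q(phi))
  zg <- vapply(phig, zdv_of, numeric(1))
  zdv_target <- if (cfg$mode == "lifted_rotating") -0.45 else -0.85
  past <- which(zg <= zdv_target & phig > phi_apex)
  phi_end <- if (length(past)) phig[past[1]] else phig[which.min(zg)]
  # the body must stay clear of the ground at the final pose
  clear_of <- function(phi) {
    R <- axis_angle_matrix(geo$axis, phi)
    min(vapply(rownames(bl), function(nm) {
      x0 <- geo$origin0 + as.numeric(geo$R0 %*% bl[nm, ])
      (geo$pivot + as.numeric(R %*% (x0 - geo$pivot)))[3]
    }, numeric(1)))
  }
  if (clear_of(phi_end) < 4.5e-4) {
    ok_clear <- phig[phig > phi_apex &
                       vapply(phig, clear_of, numeric(1)) >= 4.5e-4]
    if (length(ok_clear)) phi_end <- max(ok_clear)
  }
  deficit <- max(0, max(-vapply(seq(0, phi_apex + 0.09, length.out = 200),
                                tau_grav, numeric(1))))
  tau_up <- if (!is.null(cfg$applied_torque)) cfg$applied_torque else
    cfg$torque_margin * max(deficit, 1e-8)

  # --- frame-by-frame state machine ---------------------------------------
  max_T <- cfg$pre_quiescent_s + cfg$n_attempts * 1.2 +
    (cfg$n_attempts - 1) * cfg$fail_gap_s + cfg$post_rest_s + 0.5
  n_max <- ceiling(max_T / dt) + 1
  phase <- character(n_max); phi_v <- numeric(n_max); om_v <- numeric(n_max)
  tau_v <- numeric(n_max); att_v <- integer(n_max)
  state <- "pre"; phi <- 0; om <- 0; attempt <- 0L
  t_state <- 0; released <- FALSE
  final_success <- cfg$mode != "failed"
  frames <- 0L
  t_att_start <- 0
  righted_at <- NA_integer_
  step <- function(phi, om, tau_app) {
    dfun <- function(t, y) c(y[2], (tau_grav(y[1]) + tau_app) / I_dyn)
    y <- c(phi, om)
    k1 <- dfun(0, y); k2 <- dfun(dt / 2, y + dt / 2 * k1)
    k3 <- dfun(dt / 2, y + dt / 2 * k2); k4 <- dfun(dt, y + dt * k3)
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  i <- 0L
  t_now <- 0
  while (i < n_max) {
    i <- i + 1L
    t_now <- (i - 1) * dt
    if (state == "pre") {
      if (t_now - t_state >= cfg$pre_quiescent_s) {
        state <- "attempt"; attempt <- attempt + 1L
        released <- FALSE; t_state <- t_now; t_att_start <- t_now
      }
    } else if (state == "gap") {
      if (t_now - t_state >= cfg$fail_gap_s) {
        state <- "attempt"; attempt <- attempt + 1L
        released <- FALSE; t_state <- t_now; t_att_start <- t_now
      }
    } else if (state == "righted") {
      if (t_now - t_state >= cfg$post_rest_s) { frames <- i - 1L; break }
    }
    tau_app <- 0
    if (state == "attempt") {
      last <- attempt == cfg$n_attempts
      succeed <- final_success && last
      # successful attempts release once the work done clears the rigid
      # potential barrier with a 15% margin (the body then coasts over the
      # apex); failed attempts release early enough that the work done can
      # never carry the body over the barrier
      barrier <- pe_rigid(phi_apex) - pe_rigid(0)
      phi_release <- if (succeed) {
        min(phi_apex - 0.05, 1.15 * barrier / tau_up)
      } else {
        min(0.5 * phi_apex, 0.85 * barrier / tau_up)
      }
      if (!released && phi >= phi_release) released <- TRUE
      if (!released) {
        tau_app <- tau_up
      } else if (succeed && phi > phi_apex + 0.12) {
        # recovery: legs brake the fall after the apex (viscous resistance)
        tau_app <- -I_dyn * om / 0.025
      }
      yy <- step(phi, om, tau_app)
      phi <- yy[1]; om <- yy[2]
      if (abs(om) > 1e3) {
        stop("integration unstable: |omega| > 1000 rad/s (bad torque program)")
      }
      if (succeed && phi >= phi_end) {
        phi <- phi_end; om <- 0; state <- "righted"; t_state <- t_now + dt
        righted_at <- i
      } else if (!succeed && released && phi <= 1e-6) {
        phi <- 0; om <- 0
        state <- if (attempt < cfg$n_attempts) "gap" else "post_fail"
        t_state <- t_now + dt
      }
    } else if (state == "post_fail") {
      if (t_now - t_state >= cfg$post_rest_s) { frames <- i - 1L; break }
    }
    phase[i] <- switch(state, pre = "overturned", gap = "overturned",
                       attempt = "righting", righted = "righted",
                       post_fail = "overturned")
    phi_v[i] <- phi; om_v[i] <- om; tau_v[i] <- tau_app; att_v[i] <- attempt
  }
  if (frames == 0L) frames <- n_max
  n <- frames
  times <- (seq_len(n) - 1) * dt
  phase <- phase[1:n]; phi_v <- phi_v[1:n]; om_v <- om_v[1:n]
  tau_v <- tau_v[1:n]; att_v <- att_v[1:n]

  # --- landmark trajectories ----------------------------------------------
  lm_names <- c(rownames(bl), paste0("coxa_", leg_names()),
                paste0("femur_tibia_", leg_names()),
                paste0("tarsus_", leg_names()))
  clean <- lapply(lm_names, function(x) matrix(NA_real_, n, 3))
  names(clean) <- lm_names
  com_t <- matrix(NA_real_, n, 3)
  pe_tot <- numeric(n); pe_body <- numeric(n); pe_legs <- numeric(n)
  stance_now <- NULL
  blend_from <- NULL; blend_t0 <- NA_real_
  blend_dur <- 0.05
  for (i in seq_len(n)) {
    qi <- att_q(phi_v[i])
    orig <- rot_about_pivot(geo$origin0, phi_v[i])
    for (nm in rownames(bl)) {
      clean[[nm]][i, ] <- orig + quat_rotate(qi, bl[nm, ])
    }
    s <- min(1, phi_v[i] / phi_end)
    if (phase[i] == "righted" && is.null(stance_now)) {
      stance_now <- .righted_stance(cfg, qi, orig)
      blend_from <- lapply(leg_names(), function(leg) last_tarsus[[leg]])
      names(blend_from) <- leg_names()
      blend_t0 <- times[i]
    }
    cur_tarsus <- list()
    for (j in seq_len(nrow(cox))) {
      leg <- cox$leg[j]
      coxa_sp <- orig + quat_rotate(qi, c(cox$x[j], cox$y[j], cox$z[j]))
      if (cfg$legs_rigid) {
        tars <- rot_about_pivot(leg_points0[[leg]]$tarsus, phi_v[i])
      } else if (!is.null(stance_now)) {
        tg <- stance_now[[leg]]
        f <- min(1, (times[i] - blend_t0) / blend_dur)
        tars <- (1 - f) * blend_from[[leg]] + f * tg
      } else if (leg %in% rownames(stance_tg)) {
        tars <- stance_tg[leg, ]
      } else {
        t_att <- if (phase[i] == "righting") times[i] - t_att_start else 0
        fw <- quat_rotate(qi, c(1, 0, 0)); fw[3] <- 0
        fw <- fw / max(sqrt(sum(fw^2)), 1e-9)
        tars <- .swing_tarsus_spatial(leg, cfg,
                                      s = if (phase[i] == "righting") s else 0,
                                      t_att = t_att, coxa_sp = coxa_sp,
                                      origin = orig, fwd = fw)
        tars[3] <- max(tars[3], 3e-4)   # swing feet do not enter the ground
      }
      bend <- if (phase[i] == "righted" || leg %in% rownames(stance_tg))
        c(0, 0, 1) else quat_rotate(qi, c(0, 0, -1))
      elbow <- if (cfg$legs_rigid)
        rot_about_pivot(leg_points0[[leg]]$femur_tibia, phi_v[i]) else
        .elbow_point(coxa_sp, tars, bend)
      if (!cfg$legs_rigid) elbow[3] <- max(elbow[3], 2.5e-4)
      clean[[paste0("coxa_", leg)]][i, ] <- coxa_sp
      clean[[paste0("femur_tibia_", leg)]][i, ] <- elbow
      clean[[paste0("tarsus_", leg)]][i, ] <- tars
      cur_tarsus[[leg]] <- tars
    }
    last_tarsus <- cur_tarsus
    # energies (noise-free truth)
    bcom <- orig + quat_rotate(qi, body_mp$com)
    pe_body[i] <- m_body * g * bcom[3]
    pl <- 0
    seg_m <- 0
    mom <- m_body * bcom
    for (j in seq_len(nrow(cox))) {
      leg <- cox$leg[j]
      cxp <- clean[[paste0("coxa_", leg)]][i, ]
      el <- clean[[paste0("femur_tibia_", leg)]][i, ]
      tr <- clean[[paste0("tarsus_", leg)]][i, ]
      c2 <- (cxp + el) / 2; c1 <- (el + tr) / 2
      pl <- pl + morph$seg2_mass[j] * g * c2[3] + morph$seg1_mass[j] * g * c1[3]
      mom <- mom + morph$seg2_mass[j] * c2 + morph$seg1_mass[j] * c1
    }
    pe_legs[i] <- pl
    pe_tot[i] <- pe_body[i] + pl
    com_t[i, ] <- mom / cfg$total_mass
  }

  # orbital truth relative to the pivot landmark position (or pivot point)
  pivot_ref <- if (!is.na(geo$pivot_landmark))
    clean[[geo$pivot_landmark]][1, ] else geo$pivot
  rel <- sweep(com_t, 2, pivot_ref)
  d_t <- sqrt(rowSums(rel^2))
  # exact COM velocity of the rigid assembly: omega x r about the axis
  v_t <- numeric(n)
  for (i in seq_len(n)) {
    rr <- com_t[i, ] - geo$pivot
    r_perp <- sqrt(max(0, sum(rr^2) - sum(rr * geo$axis)^2))
    v_t[i] <- abs(om_v[i]) * r_perp
  }
  omega_orb <- ifelse(d_t > 1e-6, v_t / d_t, NA_real_)
  ke_t <- 0.5 * I_dyn * om_v^2

  # observation noise
  set.seed(cfg$seed)
  noisy <- lapply(clean, function(m) {
    m + matrix(stats::rnorm(length(m), sd = cfg$noise_sd), nrow(m), 3)
  })
  trial <- tracked_trial(times = times, landmarks = noisy,
                         frame_rate = cfg$frame_rate,
                         substrate = "synthetic", instar = "synthetic",
                         body_length = 2 * ax[1], mass = cfg$total_mass,
                         metadata = list(mode = cfg$mode, seed = cfg$seed))
  truth <- list(times = times, phase = phase, attempt = att_v, phi = phi_v,
                omega = om_v, omega_vec = outer(om_v, geo$axis), com = com_t,
                v_com = v_t, d = d_t, omega_orbital = omega_orb,
                pe_total = pe_tot, pe_body = pe_body, pe_legs = pe_legs,
                ke = ke_t, tau_applied = tau_v, tau_up = tau_up,
                axis = geo$axis, pivot = geo$pivot,
                pivot_landmark = geo$pivot_landmark,
                pivot_ref = pivot_ref, I_dyn = I_dyn,
                phi_apex = phi_apex, phi_end = phi_end,
                n_attempts = cfg$n_attempts,
                success = final_success, mode = cfg$mode,
                landmarks_clean = clean, body_mesh = mesh,
                m_body = m_body, body_com0 = body_mp$com)
  structure(list(trial = trial, truth = truth, config = cfg),
            class = "synthetic_trial")
}

#' Canonical reference poses of the standard morphology
#'
#' Deterministic landmark sets (no noise) for the stereotypic poses:
#' overturned (flat on the back, legs raised), planted (overturned, feet on
#' the ground dorsally), lifted (mid-stroke), apex (maximum potential
#' energy), and righted (standing).
#'
#' @param cfg a [synthetic_trial_config()] (mode sets the stroke geometry).
#' @return named list of poses; each pose is a named list of landmark
#'   3-vectors plus attributes `Zdv` and `phi`.
#' @export
make_reference_pose_library <- function(cfg = synthetic_trial_config(
                                          mode = "diagonal_rotating",
                                          noise_sd = 0)) {
  ax <- cfg$semi_axes
  geo <- .mode_geometry(cfg)
  bl <- .body_landmarks(ax)
  cox <- .coxa_body(ax)
  flat_R <- rot_x(pi)
  flat_orig <- c(0, 0, ax[3])
  sim <- simulate_trial(synthetic_trial_config(
    mode = cfg$mode, noise_sd = 0, seed = 1, semi_axes = cfg$semi_axes,
    total_mass = cfg$total_mass, morph = cfg$morph))
  tr <- sim$truth
  pose_at <- function(i) {
    lapply(tr$landmarks_clean, function(m) m[i, ])
  }
  overturned <- list()
  for (nm in rownames(bl)) {
    overturned[[nm]] <- flat_orig + as.numeric(flat_R %*% bl[nm, ])
  }
  for (j in seq_len(nrow(cox))) {
    leg <- cox$leg[j]
    coxa_sp <- flat_orig + as.numeric(flat_R %*% c(cox$x[j], cox$y[j], cox$z[j]))
    tars <- flat_orig + as.numeric(flat_R %*% c(cox$x[j],
                                                sign(cox$y[j]) * 2.8e-3,
                                                -3.0e-3))
    overturned[[paste0("coxa_", leg)]] <- coxa_sp
    overturned[[paste0("femur_tibia_", leg)]] <-
      .elbow_point(coxa_sp, tars, c(0, 0, 1))
    overturned[[paste0("tarsus_", leg)]] <- tars
  }
  attr(overturned, "Zdv") <- 1
  attr(overturned, "phi") <- 0
  idx_planted <- which(tr$phase == "righting")[1]
  idx_apex <- which.max(tr$pe_total)
  ri <- which(tr$phase == "righting")
  idx_lift <- ri[which.min(abs(tr$phi[ri] - 0.5 * tr$phi_apex))]
  idx_right <- length(tr$times)
  mk <- function(i) {
    p <- pose_at(i)
    attr(p, "Zdv") <- compute_Zdv(quat_multiply(
      quat_from_axis_angle(tr$axis, tr$phi[i]), geo$q0))
    attr(p, "phi") <- tr$phi[i]
    p
  }
  list(overturned = overturned, planted = mk(idx_planted),
       lifted = mk(idx_lift), apex = mk(idx_apex), righted = mk(idx_right))
}

#' Write a synthetic trial's ground truth as a CSV sidecar
#' @param sim a `synthetic_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  tr <- sim$truth
  df <- data.frame(time_s = tr$times, phase = tr$phase, attempt = tr$attempt,
                   phi_rad = tr$phi, omega_rad_s = tr$omega,
                   com_X = tr$com[, 1], com_Y = tr$com[, 2],
                   com_Z = tr$com[, 3], v_com = tr$v_com, d_m = tr$d,
                   omega_orbital = tr$omega_orbital, PE_total = tr$pe_total,
                   PE_body = tr$pe_body, PE_legs = tr$pe_legs, KE = tr$ke,
                   tau_applied = tr$tau_applied)
  write_metrics(df, path)
}
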
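# End-to-end analysis of a tracked righting trial: smoothing, ground plane,
# attitude, energetics, pendulum-template mechanics, stability margins,
# behavioral segmentation, method classification, and leg coordination.

.body_landmark_names <- function() {
  c("cranial", "caudal", "dorsum_mid", paste0("coxa_", leg_names()))
}

# anatomical body frame from landmark positions: origin at the
# cranial-caudal midpoint, x cranial, z dorsal, y = z x x (left lateral)
.anatomical_frame <- function(lm) {
  origin <- (lm[["cranial"]] + lm[["caudal"]]) / 2
  xhat <- lm[["cranial"]] - lm[["caudal"]]
  xhat <- xhat / sqrt(sum(xhat^2))
  zraw <- lm[["dorsum_mid"]] - origin
  zhat <- zraw - sum(zraw * xhat) * xhat
  zhat <- zhat / sqrt(sum(zhat^2))
  yhat <- cross3(zhat, xhat)
  list(origin = origin, R = cbind(xhat, yhat, zhat))
}

#' Smooth every landmark of a trial
#'
#' Body landmarks (cranial, caudal, dorsum, coxae) use the slow window,
#' femur-tibia joints and tarsi the fast window.
#'
#' @param trial a `tracked_trial`.
#' @param body_window_ms,leg_window_ms windows, ms (defaults 25 and 5).
#' @param robust robust (outlier-excluding) local regression (default TRUE).
#' @return the trial with smoothed landmark coordinates.
#' @export
smooth_trial <- function(trial, body_window_ms = 25, leg_window_ms = 5,
                         robust = TRUE) {
  body_set <- .body_landmark_names()
  for (nm in names(trial$landmarks)) {
    w <- if (nm %in% body_set) body_window_ms else leg_window_ms
    m <- trial$landmarks[[nm]]
    for (k in 1:3) m[, k] <- smooth_series(m[, k], trial$times, w, robust)
    trial$landmarks[[nm]] <- m
  }
  trial
}

#' Estimate the ground plane of a trial from low tarsus samples
#'
#' Collects tarsus samples lying within `band` of the lowest observed
#' tarsus height (a proxy for feet in ground contact) and fits a
#' total-least-squares plane.
#'
#' @param trial a `tracked_trial`.
#' @param band height band above the lowest tarsus sample, m (default 0.6 mm).
#' @param n_trim trimming refits discarding samples beyond 2.5 SD (2).
#' @return a plane (see [fit_ground_plane()]).
#' @export
estimate_ground_plane <- function(trial, band = 6e-4, n_trim = 2) {
  P <- do.call(rbind, trial$landmarks[paste0("tarsus_", leg_names())])
  P <- P[stats::complete.cases(P), , drop = FALSE]
  zlo <- stats::quantile(P[, 3], 0.02)
  P <- P[P[, 3] <= zlo + band, , drop = FALSE]
  plane <- fit_ground_plane(P)
  for (k in seq_len(n_trim)) {
    d <- plane_height(P, plane)
    keep <- abs(d) <= 2.5 * max(stats::sd(d), 1e-5)
    if (sum(keep) < 3 || all(keep)) break
    P <- P[keep, , drop = FALSE]
    plane <- fit_ground_plane(P)
  }
  plane
}

#' Attitude time series of a trial
#'
#' Builds the body-frame reference configuration from the mean geometry of
#' the first `n_ref` valid frames, expressed in the anatomical frame
#' (origin at the cranial-caudal midpoint, x cranial, y left lateral, z
#' dorsal), then solves the absolute-orientation problem frame by frame and
#' enforces quaternion hemisphere continuity.
#'
#' Because the body landmark set is nearly planar, small errors in the
#' reference geometry tilt the recovered dorsoventral axis; averaging over
#' 25 frames (25 ms of the initial quiescent period at 1000 fps) keeps the
#' reference tilt well under a degree at typical tracking noise.
#'
#' @param trial a smoothed `tracked_trial`.
#' @param n_ref number of initial frames averaged for the reference (25).
#' @return list with `Q` (n x 4 quaternions), `origin` (n x 3 anatomical
#'   origin in the spatial frame), `rmsd`, `reference` (body-frame landmark
#'   matrix), and `landmark_names` used.
#' @export
trial_attitude <- function(trial, n_ref = 25) {
  nms <- intersect(.body_landmark_names(), names(trial$landmarks))
  if (length(nms) < 3) stop("need >= 3 body-fixed landmarks for attitude")
  n <- n_frames(trial)
  obs <- function(i) {
    t(vapply(nms, function(nm) trial$landmarks[[nm]][i, ], numeric(3)))
  }
  valid <- vapply(seq_len(n), function(i) !anyNA(obs(i)), logical(1))
  ref_frames <- utils::head(which(valid), n_ref)
  if (length(ref_frames) == 0) stop("no frame has all body landmarks valid")
  mean_lm <- Reduce(`+`, lapply(ref_frames, obs)) / length(ref_frames)
  rownames(mean_lm) <- nms
  fr <- .anatomical_frame(lapply(nms, function(nm) mean_lm[nm, ]) |>
                            stats::setNames(nms))
  reference <- sweep(mean_lm, 2, fr$origin) %*% fr$R
  Q <- matrix(NA_real_, n, 4)
  origin <- matrix(NA_real_, n, 3)
  rmsd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    o <- obs(i)
    ok <- stats::complete.cases(o)
    if (sum(ok) < 3) next
    fit <- tryCatch(estimate_attitude(reference[ok, , drop = FALSE],
                                      o[ok, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    Q[i, ] <- fit$q
    origin[i, ] <- fit$translation
    rmsd[i] <- fit$rmsd
  }
  Q <- quat_continuity(Q)
  list(Q = Q, origin = origin, rmsd = rmsd, reference = reference,
       landmark_names = nms)
}

#' Default body mesh for a trial
#'
#' An ellipsoid stand-in in the anatomical frame with the standard
#' morphology's aspect ratios, scaled to the trial's body length.
#'
#' @param body_length head-caudal length, m.
#' @param n_theta,n_phi tessellation.
#' @return a `body_mesh`.
#' @export
default_body_mesh <- function(body_length = 8.9e-3, n_theta = 24,
                              n_phi = 36) {
  a <- body_length / 2
  ellipsoid_mesh(c(a, a * 1.8 / 4.45, a * 1.1 / 4.45), n_theta, n_phi)
}

#' Analyze a tracked righting trial
#'
#' Runs the full pipeline: landmark smoothing, ground-plane estimation,
#' attitude and angular velocity, whole-insect COM and spin inertia (anchor
#' assembly), pendulum-template mechanics (orbital kinematics, available
#' kinetic energy, reaction torque, force per leg), potential energy and
#' righting number, support-polygon stability margins, attempt
#' segmentation, righting-method classification, and leg coordination.
#'
#' @param trial a `tracked_trial` (raw; smoothing is applied internally).
#' @param mesh body mesh in the anatomical frame (default: ellipsoid
#'   stand-in scaled to the trial's body length).
#' @param morph leg morphometrics (default [default_leg_morphometrics()]).
#' @param mass whole-insect mass, kg (default `trial$mass`).
#' @param body_window_ms,leg_window_ms smoothing windows, ms.
#' @param robust robust smoothing flag.
#' @param contact_tol contact tolerance, m (default `max(2 * plane residual
#'   SD, 0.1 mm)`).
#' @param d_min pivot-distance guard for orbital rates, m.
#' @param gravity_arm `"r_com"` (default) or `"d"`, see
#'   [reaction_torque_and_force()].
#' @param active_frac active-overturning rate threshold fraction.
#' @param standardize if TRUE (default) rescale the trial to the
#'   standardized body length and mass first (when `body_length` is known).
#' @param plane optional pre-fitted (e.g. calibration) ground plane; by
#'   default estimated from low tarsus samples via
#'   [estimate_ground_plane()].
#' @return object of class `righting_analysis`: list with `frames` (per-
#'   frame metric data.frame), `attempts`, `success`, `method`, `events`
#'   (apex/flip/overturning), `pivot`, `plane`, `coordination`, `summary`
#'   (per-trial scalars).
#' @export
analyze_trial <- function(trial, mesh = NULL,
                          morph = default_leg_morphometrics(), mass = NULL,
                          body_window_ms = 25, leg_window_ms = 5,
                          robust = TRUE, contact_tol = NULL, d_min = 1e-3,
                          gravity_arm = c("r_com", "d"), active_frac = 0.5,
                          standardize = TRUE, plane = NULL) {
  gravity_arm <- match.arg(gravity_arm)
  if (standardize && !is.na(trial$body_length)) {
    trial <- scale_to_standard(trial)
  }
  if (is.null(mass)) mass <- trial$mass
  if (is.null(mass) || is.na(mass)) stop("whole-insect mass is required")
  m_legs <- total_leg_mass(morph)
  if (m_legs >= mass) stop("morphometrics leg mass exceeds whole-insect mass")
  m_body <- mass - m_legs
  if (is.null(mesh)) {
    L <- if (!is.na(trial$body_length)) trial$body_length else 8.9e-3
    mesh <- default_body_mesh(L)
  }
  body_mp <- mesh_mass_properties(mesh, m_body)
  sm_trial <- smooth_trial(trial, body_window_ms, leg_window_ms, robust)
  times <- sm_trial$times
  n <- length(times)
  dt <- 1 / sm_trial$frame_rate

  if (is.null(plane)) plane <- estimate_ground_plane(sm_trial)
  if (is.null(contact_tol)) contact_tol <- max(2 * plane$residual_sd, 1e-4)

  att <- trial_attitude(sm_trial)
  Q <- att$Q
  zdv <- compute_Zdv(Q)
  euler <- t(apply(Q, 1, function(q) {
    if (anyNA(q)) c(yaw = NA_real_, pitch = NA_real_, roll = NA_real_)
    else quat_to_euler(q)
  }))
  W <- angular_velocity_series(Q, times)
  omega_mag <- sqrt(rowSums(W^2))
  omega_rp <- vapply(seq_len(n), function(i) {
    spin_rate_rollpitch(W[i, ], Q[i, ])
  }, numeric(1))

  # --- anchor assembly per frame ------------------------------------------
  com_whole <- matrix(NA_real_, n, 3)
  com_body <- matrix(NA_real_, n, 3)
  I_spin <- rep(NA_real_, n); I_body_s <- rep(NA_real_, n)
  I_legs_s <- rep(NA_real_, n)
  pe_legs <- rep(NA_real_, n)
  # rotation axis per frame: unit omega, carried over where rate is tiny
  axis_mat <- matrix(NA_real_, n, 3)
  last_axis <- c(1, 0, 0)
  for (i in seq_len(n)) {
    if (!is.na(omega_mag[i]) && omega_mag[i] > 1) {
      last_axis <- W[i, ] / omega_mag[i]
    }
    axis_mat[i, ] <- last_axis
  }
  leg_pts <- function(i) {
    out <- list()
    for (leg in leg_names()) {
      out[[leg]] <- list(
        coxa = sm_trial$landmarks[[paste0("coxa_", leg)]][i, ],
        femur_tibia = sm_trial$landmarks[[paste0("femur_tibia_", leg)]][i, ],
        tarsus = sm_trial$landmarks[[paste0("tarsus_", leg)]][i, ])
    }
    out
  }
  have_legs <- all(c(paste0("coxa_", leg_names()),
                     paste0("femur_tibia_", leg_names()),
                     paste0("tarsus_", leg_names())) %in%
                     names(sm_trial$landmarks))
  for (i in seq_len(n)) {
    if (anyNA(Q[i, ])) next
    cb <- att$origin[i, ] + quat_rotate(Q[i, ], body_mp$com)
    com_body[i, ] <- cb
    if (!have_legs) { com_whole[i, ] <- cb; next }
    lp <- leg_pts(i)
    an <- assemble_anchor(body_mp, Q[i, ], cb, lp, morph, axis_mat[i, ])
    com_whole[i, ] <- an$com
    I_spin[i] <- an$I_spin; I_body_s[i] <- an$I_body
    I_legs_s[i] <- an$I_legs
    if (!anyNA(an$com)) {
      pe_legs[i] <- sum(vapply(leg_names(), function(leg) {
        l <- lp[[leg]]; j <- match(leg, morph$leg)
        morph$seg2_mass[j] * GRAVITY *
          plane_height((l$coxa + l$femur_tibia) / 2, plane) +
          morph$seg1_mass[j] * GRAVITY *
          plane_height((l$femur_tibia + l$tarsus) / 2, plane)
      }, numeric(1)))
    }
  }

  # --- contacts, stability -------------------------------------------------
  contact_sets <- vector("list", n)
  n_tarsi <- integer(n); body_contact <- logical(n)
  SM <- rep(NA_real_, n); ISM <- rep(NA_real_, n); SMr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pos <- t(vapply(names(sm_trial$landmarks),
                    function(nm) sm_trial$landmarks[[nm]][i, ], numeric(3)))
    cs <- detect_contacts(pos, plane, contact_tol)
    contact_sets[[i]] <- cs
    n_tarsi[i] <- sum(grepl("^tarsus_", cs))
    body_contact[i] <- any(cs %in% c("cranial", "caudal", "dorsum_mid"))
    if (length(cs) > 0 && !anyNA(com_whole[i, ])) {
      cp <- project_to_plane(pos[cs, , drop = FALSE], plane)
      sm <- stability_margin(cp, as.numeric(project_to_plane(com_whole[i, ],
                                                             plane)))
      SM[i] <- sm$SM; ISM[i] <- sm$ISM; SMr[i] <- sm$SM_ratio
    }
  }

  # --- energetics -----------------------------------------------------------
  z_com <- plane_height(com_whole, plane)
  z_body <- plane_height(com_body, plane)
  pe_body <- potential_energy(z_body, m_body)
  pe_total <- ifelse(is.na(pe_legs), pe_body, pe_body + pe_legs)
  v_com <- cbind(derivative_series(com_whole[, 1], times, body_window_ms),
                 derivative_series(com_whole[, 2], times, body_window_ms),
                 derivative_series(com_whole[, 3], times, body_window_ms))
  com_speed <- sqrt(rowSums(v_com^2))

  # --- attempts --------------------------------------------------------------
  # contact count for segmentation uses additionally smoothed tarsus
  # heights (slow window) so noise chatter cannot break the rest criterion
  n_tarsi_seg <- rowSums(vapply(leg_names(), function(leg) {
    h <- plane_height(sm_trial$landmarks[[paste0("tarsus_", leg)]], plane)
    hs <- smooth_series(h, times, body_window_ms, robust = FALSE)
    !is.na(hs) & abs(hs) <= contact_tol
  }, logical(n)))
  seg <- segment_attempts(times, zdv, plane_height(
    sm_trial$landmarks[["dorsum_mid"]], plane), n_tarsi_seg, com_speed,
    contact_tol = contact_tol)

  d_v <- rep(NA_real_, n); v_orb <- rep(NA_real_, n)
  om_orb <- rep(NA_real_, n); al_orb <- rep(NA_real_, n)
  dPE <- rep(NA_real_, n); KE <- rep(NA_real_, n); I_pend <- rep(NA_real_, n)
  RN <- rep(NA_real_, n)
  r_perp_v <- rep(NA_real_, n)
  pivots <- list()
  for (a in seq_len(seg$n_attempts)) {
    idx <- which(times >= seg$attempts$start_s[a] &
                   times <= seg$attempts$end_s[a])
    if (length(idx) < 3) next
    piv <- locate_pivot(sm_trial, contact_sets, idx)
    pivots[[a]] <- piv
    if (!piv$defined) next
    ok <- stats::complete.cases(com_whole)
    orb <- orbital_kinematics(com_whole, times, piv$pivot, body_window_ms,
                              d_min)
    d_v[idx] <- orb$d[idx]; v_orb[idx] <- orb$v_orbital[idx]
    om_orb[idx] <- orb$omega_orbital[idx]; al_orb[idx] <- orb$alpha_orbital[idx]
    pk <- pendulum_inertia_and_ke(I_spin[idx], mass, orb$d[idx],
                                  orb$omega_orbital[idx])
    I_pend[idx] <- pk$I_pendulum; KE[idx] <- pk$KE_avail
    pe_max <- max(pe_total[idx], na.rm = TRUE)
    dPE[idx] <- pmax(0, pe_max - pe_total[idx])
    rn <- righting_number(pmax(0, KE[idx]), dPE[idx])
    RN[idx] <- rn$RN
    for (i in idx) {
      tars_c <- grep("^tarsus_", contact_sets[[i]], value = TRUE)
      if (length(tars_c) > 0) {
        r_perp_v[i] <- mean(vapply(tars_c, function(nm) {
          sqrt(sum((sm_trial$landmarks[[nm]][i, ] - piv$pivot)^2))
        }, numeric(1)))
      }
    }
  }
  rt <- reaction_torque_and_force(
    I_pend, al_orb, mass,
    r_com = {
      if (length(pivots) > 0 && pivots[[length(pivots)]]$defined) {
        pv2 <- as.numeric(project_to_plane(pivots[[length(pivots)]]$pivot,
                                           plane))
        cw2 <- project_to_plane(com_whole, plane)
        sqrt((cw2[, 1] - pv2[1])^2 + (cw2[, 2] - pv2[2])^2)
      } else rep(NA_real_, n)
    },
    r_perp = r_perp_v, n_tarsi = n_tarsi, d = d_v,
    gravity_arm = gravity_arm)

  # --- events on the final attempt ----------------------------------------
  events <- NULL
  method <- "none"
  final_idx <- NULL
  if (seg$n_attempts > 0) {
    a <- seg$n_attempts
    final_idx <- which(times >= seg$attempts$start_s[a] &
                         times <= seg$attempts$end_s[a])
    if (length(final_idx) >= 5) {
      events <- detect_apex_and_overturning(times[final_idx],
                                            pe_total[final_idx],
                                            zdv[final_idx],
                                            frac = active_frac)
      ov_idx <- if (!is.na(events$flip_time)) {
        final_idx[seq(events$overturning_idx[1], events$overturning_idx[2])]
      } else integer(0)
      if (!is.na(events$flip_time) && length(ov_idx) > 0) {
        ax_m <- colMeans(axis_mat[ov_idx, , drop = FALSE], na.rm = TRUE)
        lat <- colMeans(t(vapply(ov_idx, function(i) {
          if (anyNA(Q[i, ])) rep(NA_real_, 3) else
            quat_rotate(Q[i, ], c(0, 1, 0))
        }, numeric(3))), na.rm = TRUE)
        piv_fin <- pivots[[a]]
        caud <- colMeans(sm_trial$landmarks[["caudal"]][ov_idx, ,
                                                        drop = FALSE],
                         na.rm = TRUE)
        method <- classify_method(any(body_contact[ov_idx]), ax_m, lat,
                                  if (piv_fin$defined) piv_fin$pivot else
                                    rep(NA_real_, 3), caud)
      }
    }
  }

  # --- coordination (first analyzed frame to the apex) --------------------
  coordination <- NULL
  if (!is.null(events) && !is.null(final_idx)) {
    apex_global <- final_idx[events$apex_index]
    win <- seq_len(apex_global)
    if (length(win) >= 16) {
      zt <- vapply(leg_names(), function(leg) {
        tarsus_body_z(sm_trial$landmarks[[paste0("tarsus_", leg)]][win, ,
                                                                   drop = FALSE],
                      Q[win, , drop = FALSE],
                      att$origin[win, , drop = FALSE])
      }, numeric(length(win)))
      colnames(zt) <- leg_names()
      coordination <- tryCatch(coordination_summary(zt, dt),
                               error = function(e) NULL)
    }
  }

  frames <- data.frame(
    time_s = times, Zdv = zdv, yaw = euler[, 1], pitch = euler[, 2],
    roll = euler[, 3], omega = omega_mag, omega_spin_rp = omega_rp,
    com_X = com_whole[, 1], com_Y = com_whole[, 2], com_Z = com_whole[, 3],
    com_speed = com_speed, z_com = z_com,
    PE_total = pe_total, PE_body = pe_body, PE_legs = pe_legs,
    dPE = dPE, KE_avail = KE, RN = RN,
    I_spin = I_spin, I_body = I_body_s, I_legs = I_legs_s,
    leg_inertia_fraction = I_legs_s / I_spin,
    d = d_v, v_orbital = v_orb, omega_orbital = om_orb,
    alpha_orbital = al_orb, I_pendulum = I_pend,
    tau_net = rt$tau_net, tau_grav = rt$tau_grav,
    tau_reaction = rt$tau_reaction, F_reaction = rt$F_reaction,
    F_leg = rt$F_leg, F_leg_bw = rt$F_leg_bw,
    r_perp = r_perp_v, n_tarsi = n_tarsi,
    body_contact = body_contact, SM = SM, ISM = ISM, SM_ratio = SMr)

  summary_row <- {
    sel <- if (!is.null(final_idx) && !is.null(events)) {
      final_idx[seq_len(events$apex_index)]      # start to apex
    } else integer(0)
    data.frame(
      success = seg$success, n_attempts = seg$n_attempts, method = method,
      time_to_right_s = seg$time_to_right,
      time_per_attempt_s = seg$time_per_attempt,
      pe_gain_J = if (length(sel)) max(pe_total[sel], na.rm = TRUE) -
        pe_total[sel[1]] else NA_real_,
      leg_inertia_fraction = mean(I_legs_s / I_spin, na.rm = TRUE),
      spin_orbital_ratio = if (length(sel))
        stats::median((omega_rp / om_orb)[sel], na.rm = TRUE) else NA_real_,
      mean_tau_reaction = if (length(sel))
        mean(abs(rt$tau_reaction[sel]), na.rm = TRUE) else NA_real_,
      mean_F_leg_bw = if (length(sel))
        mean(abs(rt$F_leg_bw[sel]), na.rm = TRUE) else NA_real_,
      mean_r_perp_m = if (length(sel))
        mean(r_perp_v[sel], na.rm = TRUE) else NA_real_,
      mean_SM_ratio = if (length(sel))
        mean(SMr[sel], na.rm = TRUE) else NA_real_,
      mean_n_tarsi = if (length(sel)) mean(n_tarsi[sel]) else NA_real_)
  }

  structure(list(frames = frames, attempts = seg$attempts,
                 success = seg$success, n_attempts = seg$n_attempts,
                 method = method, events = events, pivots = pivots,
                 plane = plane, contact_tol = contact_tol,
                 coordination = coordination, attitude = att,
                 summary = summary_row, mass = mass, body_mass = m_body,
                 smoothed = sm_trial),
            class = "righting_analysis")
}

#' @export
print.righting_analysis <- function(x, ...) {
  cat(sprintf("righting_analysis: %d frames, %d attempt(s), success = %s\n",
              nrow(x$frames), x$n_attempts, x$success))
  cat(sprintf("  method: %s\n", x$method))
  if (!is.null(x$events) && !is.na(x$events$flip_time)) {
    cat(sprintf("  flip at %.3f s, apex at %.3f s\n",
                x$events$flip_time, x$events$apex_time))
  }
  invisible(x)
}
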
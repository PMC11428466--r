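# The articulated "anchor" model: the rigid body (mesh mass properties)
# plus six legs, each modelled as two thin rigid rods between tracked
# joints. Composes whole-insect COM and spin moment of inertia about an
# arbitrary axis using the rod formula, the parallel-axis theorem, and the
# quadratic form of the inertia tensor.

#' Moment of inertia of a thin rod about a transverse axis through its COM
#'
#' @param m rod mass, kg (> 0).
#' @param L rod length, m (>= 0).
#' @return `m * L^2 / 12`, kg m^2.
#' @export
rod_inertia <- function(m, L) {
  if (any(m <= 0)) stop("rod mass must be > 0")
  if (any(L < 0)) stop("rod length must be >= 0")
  m * L^2 / 12
}

#' Parallel-axis theorem
#'
#' Moment of inertia about an axis parallel to one through the COM,
#' displaced by distance `d`.
#'
#' @param I_com moment of inertia about the COM axis, kg m^2.
#' @param mass object mass, kg (> 0).
#' @param d perpendicular axis displacement, m (>= 0).
#' @return `I_com + mass * d^2`.
#' @export
parallel_axis <- function(I_com, mass, d) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(d < 0)) stop("axis displacement d must be >= 0")
  I_com + mass * d^2
}

#' Moment of inertia about an arbitrary axis through the COM
#'
#' Quadratic form `r' I r` of the inertia tensor with a unit axis.
#'
#' @param I_tensor symmetric 3x3 inertia tensor about the COM, kg m^2.
#' @param axis unit 3-vector (|axis| = 1 within 1e-9; not silently
#'   normalized).
#' @return scalar moment of inertia, kg m^2.
#' @export
inertia_about_axis <- function(I_tensor, axis) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) {
    stop("axis must be a unit vector (|axis| = 1 within 1e-9)")
  }
  as.numeric(t(axis) %*% I_tensor %*% axis)
}

#' Default leg morphometrics for the standardized nymph
#'
#' Two-segment rod model per leg: segment 1 is the tibia + tarsus (distal),
#' segment 2 the femur + trochanter + coxa (proximal). Values are the
#' package's standard morphology for the 8.9 mm / 28.4 mg standardized
#' nymph: legs carry a large share of body mass, hindlegs (jumping legs)
#' longest and heaviest; editable via [write_leg_morphometrics()] /
#' [read_leg_morphometrics()].
#'
#' @return data.frame with columns `leg`, `seg1_length`, `seg1_mass`,
#'   `seg2_length`, `seg2_mass` (SI units).
#' @export
default_leg_morphometrics <- function() {
  df <- data.frame(
    leg = leg_names(),
    #          L1     L2     L3     R1     R2     R3
    seg1_length = c(3.2, 3.5, 5.0, 3.2, 3.5, 5.0) * 1e-3,
    seg1_mass   = c(0.60, 0.68, 1.00, 0.60, 0.68, 1.00) * 1e-6,
    seg2_length = c(2.8, 3.0, 4.0, 2.8, 3.0, 4.0) * 1e-3,
    seg2_mass   = c(0.90, 1.02, 1.50, 0.90, 1.02, 1.50) * 1e-6
  )
  validate_leg_morphometrics(df)
}

#' Validate a leg morphometrics table
#' @param morph candidate data.frame.
#' @return the validated table (rows ordered L1..R3).
#' @export
validate_leg_morphometrics <- function(morph) {
  need <- c("leg", "seg1_length", "seg1_mass", "seg2_length", "seg2_mass")
  if (!all(need %in% names(morph))) {
    stop("morphometrics must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(morph$leg, leg_names())) stop("exactly six legs L1..R3 required")
  vals <- as.matrix(morph[, need[-1]])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("segment lengths and masses must be finite and > 0")
  }
  morph[match(leg_names(), morph$leg), , drop = FALSE]
}

#' Total leg mass of a morphometrics table
#' @param morph morphometrics data.frame.
#' @return total mass of all 12 segments, kg.
#' @export
total_leg_mass <- function(morph) sum(morph$seg1_mass) + sum(morph$seg2_mass)

# moment of inertia of a rod between p1, p2 about the line (point, axis)
.rod_about_line <- function(p1, p2, m, point, axis) {
  L <- sqrt(sum((p2 - p1)^2))
  xc <- (p1 + p2) / 2
  u_dot <- if (L > 0) sum((p2 - p1) / L * axis) else 0
  I_own <- (m * L^2 / 12) * (1 - u_dot^2)
  r <- xc - point
  d_perp2 <- sum(r^2) - sum(r * axis)^2
  list(I = I_own + m * max(0, d_perp2), com = xc, mass = m)
}

#' Assemble the anchor model for one frame
#'
#' Combines the rigid body (mesh mass properties, rotated to the spatial
#' frame) with 12 leg-segment rods spanning the tracked joint positions, and
#' returns the whole-insect COM and the spin moment of inertia about a given
#' axis through that COM, decomposed into body and leg shares.
#'
#' @param body `mass_properties` of the body (tensor in body axes).
#' @param q attitude quaternion (body -> spatial).
#' @param body_com body COM position in the spatial frame, m.
#' @param legs named list (L1..R3) of lists with spatial positions `coxa`,
#'   `femur_tibia`, `tarsus` (each length-3, may be NA).
#' @param morph leg morphometrics table (see [default_leg_morphometrics()]).
#' @param axis unit spin axis, spatial frame (default body roll axis is not
#'   assumed; pass the measured rotation axis).
#' @return list with `com` (whole-insect, m), `mass`, `I_spin` (kg m^2 about
#'   `axis` through `com`), `I_body`, `I_legs`, `leg_fraction`
#'   (= I_legs / I_spin), and `n_segments_used`. Frames with missing
#'   endpoints for some segment return NA inertia values rather than failing.
#' @export
assemble_anchor <- function(body, q, body_com, legs, morph,
                            axis = c(1, 0, 0)) {
  morph <- validate_leg_morphometrics(morph)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be a unit vector")
  segs <- list()
  for (i in seq_len(nrow(morph))) {
    leg <- morph$leg[i]
    lp <- legs[[leg]]
    if (is.null(lp)) {
      return(list(com = rep(NA_real_, 3), mass = NA_real_, I_spin = NA_real_,
                  I_body = NA_real_, I_legs = NA_real_,
                  leg_fraction = NA_real_, n_segments_used = NA_integer_))
    }
    segs[[paste0(leg, "_seg2")]] <- list(p1 = lp$coxa, p2 = lp$femur_tibia,
                                         m = morph$seg2_mass[i])
    segs[[paste0(leg, "_seg1")]] <- list(p1 = lp$femur_tibia, p2 = lp$tarsus,
                                         m = morph$seg1_mass[i])
  }
  missing <- vapply(segs, function(s) anyNA(c(s$p1, s$p2)), logical(1))
  if (any(missing)) {
    return(list(com = rep(NA_real_, 3), mass = NA_real_, I_spin = NA_real_,
                I_body = NA_real_, I_legs = NA_real_, leg_fraction = NA_real_,
                n_segments_used = sum(!missing)))
  }
  leg_mass <- sum(vapply(segs, function(s) s$m, numeric(1)))
  M <- body$mass + leg_mass
  seg_coms <- t(vapply(segs, function(s) (s$p1 + s$p2) / 2, numeric(3)))
  seg_m <- vapply(segs, function(s) s$m, numeric(1))
  com <- (body$mass * body_com + colSums(seg_coms * seg_m)) / M
  R <- quat_to_matrix(q)
  I_body_spatial <- R %*% body$inertia_tensor %*% t(R)
  rb <- body_com - com
  d2b <- sum(rb^2) - sum(rb * axis)^2
  I_body <- inertia_about_axis((I_body_spatial + t(I_body_spatial)) / 2, axis) +
    body$mass * max(0, d2b)
  I_legs <- sum(vapply(segs, function(s) {
    .rod_about_line(s$p1, s$p2, s$m, com, axis)$I
  }, numeric(1)))
  I_spin <- I_body + I_legs
  list(com = com, mass = M, I_spin = I_spin, I_body = I_body, I_legs = I_legs,
       leg_fraction = I_legs / I_spin, n_segments_used = length(segs))
}

#' Leg share of spin inertia in the reference splayed pose
#'
#' Builds the standardized morphology in a symmetric splayed pose (legs
#' extended at the given elevation from the body plane, as when overturned
#' and reaching) and computes the fraction of the whole-insect spin moment
#' of inertia contributed by the 12 leg segments, about each body principal
#' axis through the whole-insect COM and as their mean.
#'
#' @param morph leg morphometrics (default [default_leg_morphometrics()]).
#' @param elevation_deg leg elevation above the body plane, degrees (45).
#' @param total_mass whole-insect mass, kg (default 28.4 mg).
#' @param semi_axes body ellipsoid semi-axes, m.
#' @return list with `per_axis` (named roll/pitch/yaw fractions) and `mean`.
#' @export
splayed_leg_inertia_share <- function(morph = default_leg_morphometrics(),
                                      elevation_deg = 45,
                                      total_mass = 28.4e-6,
                                      semi_axes = c(4.45e-3, 1.8e-3, 1.1e-3)) {
  morph <- validate_leg_morphometrics(morph)
  mesh <- ellipsoid_mesh(semi_axes)
  m_body <- total_mass - total_leg_mass(morph)
  if (m_body <= 0) stop("leg mass exceeds total mass")
  bmp <- mesh_mass_properties(mesh, m_body)
  cox <- .coxa_body(semi_axes)
  el <- elevation_deg * pi / 180
  legs <- list()
  for (i in seq_len(nrow(cox))) {
    side <- sign(cox$y[i])
    coxa <- c(cox$x[i], cox$y[i], cox$z[i])
    dir <- c(0.15, side * 0.95 * cos(el), 0.95 * sin(el))
    dir <- dir / sqrt(sum(dir^2))
    elbow <- coxa + dir * morph$seg2_length[i]
    tars <- elbow + dir * morph$seg1_length[i]
    legs[[cox$leg[i]]] <- list(coxa = coxa, femur_tibia = elbow,
                               tarsus = tars)
  }
  per <- vapply(list(roll = c(1, 0, 0), pitch = c(0, 1, 0),
                     yaw = c(0, 0, 1)), function(axv) {
    assemble_anchor(bmp, c(1, 0, 0, 0), c(0, 0, 0), legs, morph,
                    axv)$leg_fraction
  }, numeric(1))
  list(per_axis = per, mean = mean(per))
}
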
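# Energetics of righting: gravitational potential energy, the remaining
# barrier Delta-PE, the dimensionless righting number, apex / flipping /
# active-overturning detection, and the pitch-roll potential energy
# landscape of the body resting on one contact point.

#' Gravitational potential energy
#'
#' `PE = M g Z` with `Z` the COM height above the fitted ground plane.
#'
#' @param Z COM height, m (vectorized).
#' @param M mass, kg.
#' @param g gravitational acceleration, m s^-2.
#' @return potential energy, J.
#' @export
potential_energy <- function(Z, M, g = GRAVITY) {
  if (M <= 0) stop("mass must be > 0")
  M * g * Z
}

#' Righting number
#'
#' `RN(t) = KE_avail(t) / DeltaPE(t)`: the fraction of the remaining
#' potential-energy barrier covered by available kinetic energy. RN >= 1
#' permits purely dynamic righting; RN << 1 is quasistatic. Frames with
#' `DeltaPE` below `eps` are reported as NA with `saturated = TRUE` rather
#' than infinity.
#'
#' @param KE_avail available kinetic energy, J (>= 0, vectorized).
#' @param dPE remaining potential-energy increase to the apex, J (>= 0).
#' @param eps saturation threshold for `dPE`, J (default 1e-10).
#' @return data.frame with `RN` and logical `saturated`.
#' @export
righting_number <- function(KE_avail, dPE, eps = 1e-10) {
  if (any(KE_avail < 0, na.rm = TRUE)) stop("KE_avail must be >= 0")
  if (any(dPE < -sqrt(.Machine$double.eps), na.rm = TRUE)) {
    stop("dPE must be >= 0")
  }
  saturated <- !is.na(dPE) & dPE < eps
  RN <- ifelse(saturated, NA_real_, KE_avail / dPE)
  data.frame(RN = RN, saturated = saturated)
}

#' Detect the apex, flipping point, and active-overturning interval
#'
#' The apex is the time of maximum total potential energy; the flipping
#' point is the first downward crossing of `Z_dv = 0`; active overturning is
#' the maximal contiguous interval containing the flipping point in which
#' the dorsoventral reorientation rate `|dZ_dv/dt|` is at least `frac` of
#' its trial maximum.
#'
#' @param times sample times, s.
#' @param pe_total smoothed total potential energy, J.
#' @param zdv smoothed Z_dv series.
#' @param frac active-overturning rate threshold as a fraction of the
#'   maximum rate (default 0.5).
#' @param window_ms derivative window for the Z_dv rate, ms.
#' @return list with `apex_time`, `apex_index`, `flip_time` (NA if Z_dv
#'   never crosses 0 downward: a failed attempt), `flip_index`,
#'   `overturning` (length-2 times or NA), `overturning_idx`, `righted`.
#' @export
detect_apex_and_overturning <- function(times, pe_total, zdv, frac = 0.5,
                                        window_ms = 25) {
  ok <- which(is.finite(pe_total))
  if (length(ok) == 0) stop("no finite potential energy samples")
  apex_index <- ok[which.max(pe_total[ok])]
  cross <- which(zdv[-length(zdv)] > 0 & zdv[-1] <= 0)
  if (length(cross) == 0) {
    return(list(apex_time = times[apex_index], apex_index = apex_index,
                flip_time = NA_real_, flip_index = NA_integer_,
                overturning = c(NA_real_, NA_real_),
                overturning_idx = c(NA_integer_, NA_integer_),
                righted = FALSE))
  }
  i <- cross[1]
  # linear interpolation of the crossing time
  z0 <- zdv[i]; z1 <- zdv[i + 1]
  flip_time <- times[i] + (times[i + 1] - times[i]) * z0 / (z0 - z1)
  flip_index <- if (abs(z1) < abs(z0)) i + 1L else i
  rate <- abs(derivative_series(zdv, times, window_ms))
  thr <- frac * max(rate, na.rm = TRUE)
  fast <- !is.na(rate) & rate >= thr
  lo <- flip_index
  while (lo > 1 && fast[lo - 1]) lo <- lo - 1
  hi <- flip_index
  while (hi < length(times) && fast[hi + 1]) hi <- hi + 1
  list(apex_time = times[apex_index], apex_index = apex_index,
       flip_time = flip_time, flip_index = flip_index,
       overturning = c(times[lo], times[hi]),
       overturning_idx = c(lo, hi), righted = TRUE)
}

#' Pitch-roll potential energy landscape of the body
#'
#' For each (pitch, roll) pair with yaw fixed at 0 (yaw does not change COM
#' height for a point contact), the body mesh is rotated by the Tait-Bryan
#' rotation, translated so its lowest vertex touches the ground, and the
#' body PE `M_body g Z_com` recorded.
#'
#' @param mesh body `body_mesh` (vertices in body axes, m).
#' @param M_body body mass, kg.
#' @param pitch,roll grid vectors, rad (default 1 degree spacing over
#'   `[-pi, pi)`).
#' @param g gravitational acceleration, m s^-2.
#' @return list of class `pe_landscape` with `pitch`, `roll`, and `PE`
#'   (length(pitch) x length(roll) matrix, J).
#' @export
pe_landscape <- function(mesh, M_body,
                         pitch = seq(-pi, pi - pi / 180, by = pi / 180),
                         roll = seq(-pi, pi - pi / 180, by = pi / 180),
                         g = GRAVITY) {
  mesh <- mesh_validate(mesh)
  com <- mesh_mass_properties(mesh, M_body)$com
  V <- mesh$vertices
  PE <- matrix(NA_real_, length(pitch), length(roll))
  for (i in seq_along(pitch)) {
    Rp <- rot_y(pitch[i])
    for (j in seq_along(roll)) {
      R <- Rp %*% rot_x(roll[j])
      z <- V %*% R[3, ]                 # Z-coordinates of rotated vertices
      zc <- sum(R[3, ] * com)
      PE[i, j] <- M_body * g * (zc - min(z))
    }
  }
  structure(list(pitch = pitch, roll = roll, PE = PE), class = "pe_landscape")
}

#' Write a PE landscape as a dense long-format CSV grid
#' @param landscape a `pe_landscape`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pe_landscape <- function(landscape, path) {
  df <- data.frame(
    pitch_rad = rep(landscape$pitch, times = length(landscape$roll)),
    roll_rad = rep(landscape$roll, each = length(landscape$pitch)),
    PE_J = as.numeric(landscape$PE))
  write_metrics(df, path)
}
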
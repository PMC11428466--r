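# Behavioral (ethogram) summary: attempt segmentation, righting-method
# classification, behavior frequencies, and the inclined-plane friction
# conversion.

#' Segment a trial into self-righting attempts
#'
#' An attempt starts when the dorsum leaves contact tolerance while the
#' insect is overturned (Z_dv > `zdv_overturned`). It ends in success when
#' the insect first comes to rest stably upright: all six tarsi in contact,
#' Z_dv < 0, and COM speed below `v_rest` sustained for at least `rest_ms`.
#' It ends in failure when the dorsum recontacts the ground overturned.
#'
#' @param times sample times, s.
#' @param zdv smoothed Z_dv series.
#' @param dorsum_height signed height of the dorsum landmark above the
#'   ground plane, m.
#' @param tarsi_in_contact integer count of tarsi in ground contact per
#'   frame.
#' @param com_speed COM speed, m/s.
#' @param contact_tol contact tolerance, m (default 0.5 mm).
#' @param v_rest rest-speed threshold, m/s (default 5 mm/s).
#' @param rest_ms minimum sustained rest duration, ms (default 100).
#' @param zdv_overturned Z_dv above which the insect counts as overturned
#'   (default 0.9).
#' @param max_trial_s give-up horizon, s (default 30): no success by then is
#'   a failed trial.
#' @return list with `attempts` (data.frame: start_s, end_s, outcome),
#'   `n_attempts`, `success`, `time_to_right` (s from first attempt start
#'   to success; NA on failure), `time_per_attempt` (total attempting time /
#'   attempts).
#' @export
segment_attempts <- function(times, zdv, dorsum_height, tarsi_in_contact,
                             com_speed, contact_tol = 5e-4, v_rest = 5e-3,
                             rest_ms = 100, zdv_overturned = 0.9,
                             max_trial_s = 30) {
  n <- length(times)
  stopifnot(length(zdv) == n, length(dorsum_height) == n,
            length(tarsi_in_contact) == n, length(com_speed) == n)
  dt <- stats::median(diff(times))
  rest_n <- max(1L, round((rest_ms / 1000) / dt))
  dorsum_up <- !is.na(dorsum_height) & dorsum_height > contact_tol
  overturned <- !is.na(zdv) & zdv > zdv_overturned
  resting <- !is.na(com_speed) & com_speed < v_rest &
    !is.na(tarsi_in_contact) & tarsi_in_contact >= 6 &
    !is.na(zdv) & zdv < 0
  # run-length lookahead: frame i starts a sustained rest of >= rest_n frames
  runlen <- integer(n)
  acc <- 0L
  for (i in n:1) {
    acc <- if (resting[i]) acc + 1L else 0L
    runlen[i] <- acc
  }
  attempts <- list()
  i <- 1L
  success <- FALSE
  horizon <- times[1] + max_trial_s
  while (i <= n && times[i] <= horizon) {
    # wait for an attempt start: overturned with the dorsum lifting off
    if (!(overturned[i] && dorsum_up[i]) ||
        (i > 1 && dorsum_up[i - 1] && overturned[i - 1])) {
      i <- i + 1L
      next
    }
    start <- i
    j <- i + 1L
    end <- NA_integer_
    outcome <- "censored"
    while (j <= n) {
      if (runlen[j] >= rest_n) { end <- j; outcome <- "success"; break }
      if (!dorsum_up[j] && overturned[j]) { end <- j; outcome <- "failure"; break }
      j <- j + 1L
    }
    if (is.na(end)) end <- n
    attempts[[length(attempts) + 1]] <-
      data.frame(start_s = times[start], end_s = times[end], outcome = outcome)
    if (outcome == "success") { success <- TRUE; break }
    i <- end + 1L
  }
  att <- if (length(attempts)) do.call(rbind, attempts) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               outcome = character(0))
  n_att <- nrow(att)
  t_right <- if (success) att$end_s[n_att] - att$start_s[1] else NA_real_
  t_per <- if (n_att > 0) sum(att$end_s - att$start_s) / n_att else NA_real_
  list(attempts = att, n_attempts = n_att, success = success,
       time_to_right = t_right, time_per_attempt = t_per)
}

#' Classify the righting method of an attempt
#'
#' Lifted rotating if no body (non-leg) part touches the ground during
#' active overturning; otherwise pitching if the mean rotation axis lies
#' within `cone_deg` of the body lateral (pitch) axis AND the pivot sits at
#' the caudal end; otherwise diagonal rotating.
#'
#' @param body_in_contact logical: was any body (non-leg) landmark in ground
#'   contact during active overturning?
#' @param rotation_axis mean unit rotation axis during active overturning,
#'   spatial frame.
#' @param lateral_axis mean body lateral (pitch) axis, spatial frame.
#' @param pivot_point pivot location, m (may be NA).
#' @param caudal_point mean caudal landmark position during the attempt, m.
#' @param cone_deg pitch-axis cone half-angle, degrees (default 30).
#' @param pivot_tol max pivot-caudal distance to call the pivot caudal, m
#'   (default 1.5 mm).
#' @return one of `"diagonal_rotating"`, `"lifted_rotating"`, `"pitching"`,
#'   `"none"`.
#' @export
classify_method <- function(body_in_contact, rotation_axis, lateral_axis,
                            pivot_point, caudal_point, cone_deg = 30,
                            pivot_tol = 1.5e-3) {
  if (is.na(body_in_contact) || anyNA(rotation_axis) || anyNA(lateral_axis)) {
    return("none")
  }
  if (!body_in_contact) return("lifted_rotating")
  u <- rotation_axis / sqrt(sum(rotation_axis^2))
  v <- lateral_axis / sqrt(sum(lateral_axis^2))
  ang <- acos(min(1, abs(sum(u * v)))) * 180 / pi
  caudal_pivot <- !anyNA(pivot_point) && !anyNA(caudal_point) &&
    sqrt(sum((pivot_point - caudal_point)^2)) <= pivot_tol
  if (ang <= cone_deg && caudal_pivot) "pitching" else "diagonal_rotating"
}

#' Behavior frequencies from classification counts
#'
#' @param counts named integer vector of per-method trial counts.
#' @return named numeric percentages (100 * count / total), rounded to one
#'   decimal.
#' @export
behavior_frequencies <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("total count must be > 0")
  round(100 * counts / total, 1)
}

#' Static friction coefficient from an inclined-plane sliding angle
#'
#' `mu_s = tan(psi)` with `psi` the minimum tilt at which sliding begins.
#'
#' @param psi tilt angle, rad, in `[0, pi/2)`. Angles at or beyond pi/2
#'   (specimen rolled instead of sliding) are a parameter error: only a
#'   lower bound exists in that case.
#' @return coefficient of static friction.
#' @export
friction_from_tilt <- function(psi) {
  if (any(psi < 0) || any(psi >= pi / 2)) {
    stop("psi must lie in [0, pi/2): at pi/2 the specimen rolls, giving only a lower bound")
  }
  tan(psi)
}
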
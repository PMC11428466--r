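# The TrackedTrial container: time-indexed named-landmark 3D coordinates
# with acquisition metadata, as produced by multi-camera DLT reconstruction
# (or by the package's synthetic-trial generator).

#' Leg names used throughout the package
#' @return character vector `c("L1","L2","L3","R1","R2","R3")`.
#' @export
leg_names <- function() c("L1", "L2", "L3", "R1", "R2", "R3")

#' Canonical landmark schema
#'
#' Cranial and caudal body points, a dorsal midline point, and per-leg
#' coxa / femur-tibia joint / tarsus points: 21 names covering the 16-18
#' anatomical landmarks typically tracked, with room for omissions.
#'
#' @return character vector of 21 landmark names.
#' @export
landmark_schema <- function() {
  c("cranial", "caudal", "dorsum_mid",
    paste0("coxa_", leg_names()),
    paste0("femur_tibia_", leg_names()),
    paste0("tarsus_", leg_names()))
}

#' Minimal landmark schema required for analysis
#' @return character vector: cranial, caudal, dorsum_mid and the 6 tarsi.
#' @export
landmark_schema_minimal <- function() {
  c("cranial", "caudal", "dorsum_mid", paste0("tarsus_", leg_names()))
}

#' Construct a TrackedTrial
#'
#' @param times sample times, s; strictly increasing, uniformly spaced to
#'   within 1e-9 s.
#' @param landmarks named list of n x 3 matrices (m, spatial frame, Z up);
#'   NA marks missing samples.
#' @param frame_rate frames per second (default inferred from `times`).
#' @param substrate,instar free-text labels.
#' @param body_length head-caudal body length, m (NA if unknown).
#' @param mass whole-insect mass, kg (NA if unknown).
#' @param metadata list of extra metadata.
#' @return object of class `tracked_trial`.
#' @export
tracked_trial <- function(times, landmarks, frame_rate = NULL,
                          substrate = NA_character_, instar = NA_character_,
                          body_length = NA_real_, mass = NA_real_,
                          metadata = list()) {
  times <- as.numeric(times)
  n <- length(times)
  if (n >= 2) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-9) {
      stop("times must be uniformly spaced to within 1e-9 s")
    }
  }
  if (is.null(frame_rate)) {
    frame_rate <- if (n >= 2) 1 / stats::median(diff(times)) else NA_real_
  }
  if (is.null(names(landmarks)) || any(!nzchar(names(landmarks)))) {
    stop("landmarks must be a named list")
  }
  landmarks <- lapply(landmarks, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3 || nrow(m) != n) {
      stop("each landmark must be an n x 3 matrix sharing the trial time base")
    }
    colnames(m) <- c("X", "Y", "Z")
    m
  })
  structure(list(times = times, frame_rate = frame_rate,
                 landmarks = landmarks, substrate = substrate,
                 instar = instar, body_length = body_length, mass = mass,
                 metadata = metadata),
            class = "tracked_trial")
}

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("tracked_trial: %d frames @ %g fps, %d landmarks\n",
              length(x$times), x$frame_rate, length(x$landmarks)))
  cat(sprintf("  body length %s, mass %s, substrate %s, instar %s\n",
              ifelse(is.na(x$body_length), "NA",
                     sprintf("%.2f mm", 1e3 * x$body_length)),
              ifelse(is.na(x$mass), "NA", sprintf("%.2f mg", 1e6 * x$mass)),
              x$substrate, x$instar))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a `tracked_trial`.
#' @return integer frame count.
#' @export
n_frames <- function(trial) length(trial$times)

#' Rescale a trial to the standardized body length and mass
#'
#' Growth of these nymphs is isometric, so tracked coordinates for different
#' specimens are made comparable by uniform scaling: every coordinate is
#' multiplied by `L_std / body_length` and the mass set to the standardized
#' value. Applying the scaling twice is a no-op after the first application.
#'
#' @param trial a `tracked_trial` with a known `body_length`.
#' @param L_std standardized body length, m (default 8.9 mm).
#' @param M_std standardized whole-insect mass, kg (default 28.4 mg).
#' @return the rescaled trial; the scale factor is stored in
#'   `metadata$scale_factor`.
#' @export
scale_to_standard <- function(trial, L_std = 8.9e-3, M_std = 28.4e-6) {
  if (is.na(trial$body_length) || trial$body_length <= 0) {
    stop("trial body_length must be known and positive to standardize")
  }
  f <- L_std / trial$body_length
  trial$landmarks <- lapply(trial$landmarks, function(m) m * f)
  trial$body_length <- L_std
  trial$mass <- M_std
  trial$metadata$scale_factor <- f *
    if (is.null(trial$metadata$scale_factor)) 1 else trial$metadata$scale_factor
  trial
}
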
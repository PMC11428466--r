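# On-disk formats: landmark trajectory tables (CSV, the flat per-landmark
# XYZ dialect exported by DLT-based trackers), per-frame metric tables, and
# leg morphometrics (YAML). All internal computation is SI (m, kg, s, J,
# N m); unit conversion happens only at this boundary.

.meta_header <- function(trial) {
  m <- c(units = "m",
         frame_rate = format(trial$frame_rate, digits = 17),
         substrate = as.character(trial$substrate),
         instar = as.character(trial$instar),
         body_length = format(trial$body_length, digits = 17),
         mass = format(trial$mass, digits = 17))
  sprintf("# %s: %s", names(m), m)
}

.parse_meta <- function(lines) {
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Read a landmark trajectory table
#'
#' Expects a CSV with columns `frame`, `time_s`, and `<name>_X`, `<name>_Y`,
#' `<name>_Z` for each landmark, optionally preceded by `# key: value`
#' comment lines carrying units and trial metadata. Missing cells become NA
#' (never silently zero).
#'
#' @param path CSV file path.
#' @param schema landmark names that must be present (default: the minimal
#'   schema, [landmark_schema_minimal()]); any further `<name>_X/Y/Z` column
#'   triples found are read as well.
#' @param units `"auto"` (use the `# units:` header, defaulting to m),
#'   `"m"`, or `"mm"`.
#' @return a [tracked_trial()] in SI units.
#' @export
read_landmark_table <- function(path, schema = landmark_schema_minimal(),
                                units = c("auto", "m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("landmark table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_meta(lines)
  df <- utils::read.csv(text = lines, comment.char = "#",
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("frame", "time_s") %in% names(df))) {
    stop("landmark table must have 'frame' and 'time_s' columns")
  }
  if (units == "auto") {
    units <- if (!is.null(meta$units)) meta$units else "m"
  }
  if (!units %in% c("m", "mm")) stop("unsupported units: ", units)
  fac <- if (units == "mm") 1e-3 else 1
  coord_cols <- grep("_(X|Y|Z)$", names(df), value = TRUE)
  found <- unique(sub("_(X|Y|Z)$", "", coord_cols))
  for (nm in schema) {
    missing_cols <- setdiff(paste0(nm, "_", c("X", "Y", "Z")), names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("landmark '%s' missing from table (no column %s)",
                   nm, paste(missing_cols, collapse = ", ")))
    }
  }
  times <- as.numeric(df$time_s)
  dts <- diff(times)
  if (length(dts) > 0 && (any(dts <= 0) || max(dts) - min(dts) > 1e-9)) {
    stop("non-uniform or non-increasing timestamps in landmark table")
  }
  landmarks <- lapply(found, function(nm) {
    m <- as.matrix(df[, paste0(nm, "_", c("X", "Y", "Z"))]) * fac
    storage.mode(m) <- "double"
    m
  })
  names(landmarks) <- found
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tracked_trial(times = times, landmarks = landmarks,
                frame_rate = if (!is.null(meta$frame_rate))
                  as.numeric(meta$frame_rate) else NULL,
                substrate = if (!is.null(meta$substrate)) meta$substrate
                  else NA_character_,
                instar = if (!is.null(meta$instar)) meta$instar
                  else NA_character_,
                body_length = num_or_na(meta$body_length),
                mass = num_or_na(meta$mass))
}

#' Write a trial as a landmark trajectory table
#'
#' Inverse of [read_landmark_table()]; coordinates written in m at full
#' float precision with metadata comment headers.
#'
#' @param trial a `tracked_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(trial, path) {
  cols <- list(frame = seq_along(trial$times), time_s = trial$times)
  for (nm in names(trial$landmarks)) {
    m <- trial$landmarks[[nm]]
    cols[[paste0(nm, "_X")]] <- m[, 1]
    cols[[paste0(nm, "_Y")]] <- m[, 2]
    cols[[paste0(nm, "_Z")]] <- m[, 3]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(trial), con)
  .write_full_precision(df, con)
  invisible(path)
}

.write_full_precision <- function(df, con) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- sprintf("%.17g", col)
      out[!is.finite(col) & !is.nan(col)] <- ""
      out[is.na(col)] <- ""
      out
    } else {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    }
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    writeLines(apply(fmt, 1, paste, collapse = ","), con)
  }
}

#' Write a per-frame metric table as CSV
#'
#' Plain-text CSV, one row per frame, deterministic column order (as given),
#' full float precision; NA/NaN cells are written empty and read back as NA.
#'
#' @param series data.frame of per-frame metrics.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(series, path) {
  stopifnot(is.data.frame(series))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write metrics to: ", path))
  on.exit(close(con))
  .write_full_precision(series, con)
  invisible(path)
}

#' Read a per-frame metric table written by [write_metrics()]
#' @param path CSV path.
#' @return data.frame with NA for empty cells.
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read leg morphometrics from a YAML file
#'
#' The file maps each leg name (L1..L3, R1..R3) to `seg1_length_mm`,
#' `seg1_mass_mg` (tibia + tarsus) and `seg2_length_mm`, `seg2_mass_mg`
#' (femur + trochanter + coxa).
#'
#' @param path YAML file path.
#' @return morphometrics data.frame in SI units (see
#'   [default_leg_morphometrics()]).
#' @export
read_leg_morphometrics <- function(path) {
  y <- yaml::read_yaml(path)
  legs <- leg_names()
  if (!all(legs %in% names(y))) {
    stop("morphometrics must define all six legs: ",
         paste(setdiff(legs, names(y)), collapse = ", "))
  }
  df <- do.call(rbind, lapply(legs, function(l) {
    e <- y[[l]]
    data.frame(leg = l,
               seg1_length = e$seg1_length_mm * 1e-3,
               seg1_mass = e$seg1_mass_mg * 1e-6,
               seg2_length = e$seg2_length_mm * 1e-3,
               seg2_mass = e$seg2_mass_mg * 1e-6)
  }))
  validate_leg_morphometrics(df)
}

#' Write leg morphometrics to YAML
#' @param morph morphometrics data.frame (SI units).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_leg_morphometrics <- function(morph, path) {
  morph <- validate_leg_morphometrics(morph)
  y <- lapply(seq_len(nrow(morph)), function(i) {
    list(seg1_length_mm = morph$seg1_length[i] * 1e3,
         seg1_mass_mg = morph$seg1_mass[i] * 1e6,
         seg2_length_mm = morph$seg2_length[i] * 1e3,
         seg2_mass_mg = morph$seg2_mass[i] * 1e6)
  })
  names(y) <- morph$leg
  yaml::write_yaml(y, path)
  invisible(path)
}
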
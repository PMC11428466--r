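# Leg coordination: tarsus height in the body frame and normalized
# discrete-time auto/cross-correlation of leg motions.

#' Tarsus position along the body dorsoventral axis
#'
#' Transforms spatial tarsus positions into the body frame and reports the
#' coordinate along the dorsal -> ventral axis (the body-frame -z
#' direction): a tarsus raised dorsally above the body origin has negative
#' z_tarsus.
#'
#' @param tarsus n x 3 matrix of tarsus positions, spatial frame, m.
#' @param Q n x 4 matrix of attitude quaternions (body -> spatial).
#' @param origin n x 3 matrix of body origin positions, spatial frame, m.
#' @return numeric z_tarsus series, m (NA where attitude or position is
#'   missing).
#' @export
tarsus_body_z <- function(tarsus, Q, origin) {
  n <- nrow(tarsus)
  stopifnot(nrow(Q) == n, nrow(origin) == n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(tarsus[i, ]) || anyNA(Q[i, ]) || anyNA(origin[i, ])) next
    R <- quat_to_matrix(Q[i, ])
    p_body <- as.numeric(t(R) %*% (tarsus[i, ] - origin[i, ]))
    out[i] <- -p_body[3]
  }
  out
}

.local_max_peaks <- function(lags, values, exclude_zero) {
  n <- length(values)
  if (n < 3) return(integer(0))
  d <- diff(values)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (exclude_zero) idx <- idx[lags[idx] != 0]
  idx
}

#' Normalized discrete-time cross-correlation of two leg-height series
#'
#' Both series are standardized to zero mean; the correlation at each lag is
#' `sum(z_j(t_i) z_k(t_i + lag)) / (n * rms_j * rms_k)` (biased, 1/n
#' normalization), so any series' autocorrelation is exactly 1 at zero lag.
#' Peak similarity is the maximum signed value at any lag for cross-pairs,
#' and the maximum absolute value at nonzero lag for autocorrelations; ties
#' break toward smaller `|lag|`.
#'
#' @param z_j,z_k equal-length numeric series (n >= 8), m.
#' @param dt sample interval, s.
#' @param max_lag_s maximum lag to sweep, s (default half the window).
#' @param type `"cross"` or `"auto"` (controls peak-similarity convention).
#' @return list of class `leg_xcorr` with `lags` (s), `values`,
#'   `peak_similarity`, `peak_lag` (s), and `defined` (FALSE for
#'   zero-variance input, in which case values are NA).
#' @export
normalized_xcorr <- function(z_j, z_k, dt, max_lag_s = NULL,
                             type = c("cross", "auto")) {
  type <- match.arg(type)
  n <- length(z_j)
  if (length(z_k) != n) stop("series must have equal length")
  if (n < 8) stop("need at least 8 samples")
  max_lag <- if (is.null(max_lag_s)) floor(n / 2) else
    min(n - 1, round(max_lag_s / dt))
  zj <- z_j - mean(z_j, na.rm = TRUE)
  zk <- z_k - mean(z_k, na.rm = TRUE)
  rms_j <- sqrt(mean(zj^2, na.rm = TRUE))
  rms_k <- sqrt(mean(zk^2, na.rm = TRUE))
  lags_samp <- -max_lag:max_lag
  if (!is.finite(rms_j) || !is.finite(rms_k) || rms_j == 0 || rms_k == 0) {
    return(structure(list(lags = lags_samp * dt,
                          values = rep(NA_real_, length(lags_samp)),
                          peak_similarity = NA_real_, peak_lag = NA_real_,
                          defined = FALSE), class = "leg_xcorr"))
  }
  zj[is.na(zj)] <- 0
  zk[is.na(zk)] <- 0
  vals <- vapply(lags_samp, function(l) {
    if (l >= 0) {
      i <- seq_len(n - l)
      sum(zj[i] * zk[i + l])
    } else {
      i <- seq_len(n + l)
      sum(zj[i - l] * zk[i])
    }
  }, numeric(1)) / (n * rms_j * rms_k)
  score <- if (type == "auto") abs(vals) else vals
  peaks <- .local_max_peaks(lags_samp, score, exclude_zero = (type == "auto"))
  if (length(peaks) == 0) {
    # fall back to the global max over admissible lags
    adm <- if (type == "auto") which(lags_samp != 0) else seq_along(lags_samp)
    peaks <- adm
  }
  best_val <- max(score[peaks])
  cand <- peaks[score[peaks] >= best_val - 1e-12]
  best <- cand[which.min(abs(lags_samp[cand]))]
  structure(list(lags = lags_samp * dt, values = vals,
                 peak_similarity = if (type == "auto") abs(vals[best])
                   else vals[best],
                 peak_lag = lags_samp[best] * dt, defined = TRUE),
            class = "leg_xcorr")
}

#' Pairwise leg-coordination summary
#'
#' Cross-correlation peak similarity and lag for every pair among the
#' requested legs (default forelegs + midlegs; hindlegs are excluded
#' because they serve mostly static roles), plus each leg's autocorrelation
#' nonzero-lag peak.
#'
#' @param z_mat n x m matrix of z_tarsus series, columns named by leg.
#' @param dt sample interval, s.
#' @param legs legs to analyze (default `c("L1","R1","L2","R2")`).
#' @param max_lag_s maximum lag, s (default half the window).
#' @return list with data.frames `pairs` (leg_j, leg_k, peak_similarity,
#'   peak_lag_s) and `auto` (leg, peak_similarity, peak_lag_s).
#' @export
coordination_summary <- function(z_mat, dt, legs = c("L1", "R1", "L2", "R2"),
                                 max_lag_s = NULL) {
  legs <- intersect(legs, colnames(z_mat))
  if (length(legs) < 2) stop("need >= 2 legs with valid series")
  pr <- utils::combn(legs, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(pr)), function(i) {
    cc <- normalized_xcorr(z_mat[, pr[1, i]], z_mat[, pr[2, i]], dt,
                           max_lag_s, type = "cross")
    data.frame(leg_j = pr[1, i], leg_k = pr[2, i],
               peak_similarity = cc$peak_similarity,
               peak_lag_s = cc$peak_lag)
  }))
  auto <- do.call(rbind, lapply(legs, function(l) {
    ac <- normalized_xcorr(z_mat[, l], z_mat[, l], dt, max_lag_s,
                           type = "auto")
    data.frame(leg = l, peak_similarity = ac$peak_similarity,
               peak_lag_s = ac$peak_lag)
  }))
  list(pairs = pairs, auto = auto)
}
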
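# Local quadratic (Savitzky-Golay-type) smoothing and differentiation of
# tracked coordinate series, and total-least-squares ground-plane fitting.
#
# Smoothing fits a quadratic polynomial by (optionally robust) least squares
# over a moving time window; the fitted value at the window centre is the
# smoothed sample and the fitted slope is the derivative. Quadratics are a
# fixed point of the smoother and are differentiated exactly. Endpoints use
# one-sided windows. Robust weighting excludes samples lying more than 6
# median absolute deviations from the local fit (bisquare weights inside the
# cutoff, two reweighting iterations).

.local_quad <- function(x, times, window_ms, robust, slope) {
  n <- length(x)
  stopifnot(length(times) == n)
  dt <- stats::median(diff(times))
  w_samp <- max(3, round((window_ms / 1000) / dt))
  if ((window_ms / 1000) / dt < 3 - 1e-9) {
    stop("window must span at least 3 samples at this frame rate")
  }
  h <- floor(w_samp / 2)
  out <- rep(NA_real_, n)
  # fast path: complete data, non-robust -> interior windows share one set
  # of least-squares coefficients (a Savitzky-Golay convolution)
  if (!robust && !anyNA(x) && n >= 2 * h + 1) {
    tt0 <- (-h:h) * dt
    X0 <- cbind(1, tt0, tt0^2)
    A0 <- solve(crossprod(X0))
    cf0 <- as.numeric(X0 %*% A0[, if (slope) 2 else 1])
    interior <- (h + 1):(n - h)
    acc <- numeric(length(interior))
    for (j in -h:h) acc <- acc + cf0[j + h + 1] * x[interior + j]
    out[interior] <- acc
    edge_idx <- c(seq_len(h), (n - h + 1):n)
  } else {
    edge_idx <- seq_len(n)
  }
  for (i in edge_idx) {
    j <- max(1L, i - h):min(n, i + h)
    tt <- times[j] - times[i]
    yy <- x[j]
    ok <- is.finite(yy)
    if (sum(ok) < 3) next
    tt <- tt[ok]; yy <- yy[ok]
    X <- cbind(1, tt, tt^2)
    w <- rep(1, length(yy))
    fit_coef <- function(w) {
      Xw <- X * w
      A <- crossprod(Xw, X)
      b <- crossprod(Xw, yy)
      # guard near-singular windows (e.g. < 3 distinct times)
      out <- tryCatch(solve(A, b), error = function(e) NULL)
      out
    }
    cf <- fit_coef(w)
    if (is.null(cf)) next
    if (robust) {
      for (iter in 1:2) {
        r <- yy - as.numeric(X %*% cf)
        s <- stats::median(abs(r))
        if (s < .Machine$double.eps^0.5 * max(abs(yy), 1)) break
        u <- r / (6 * s)
        w <- ifelse(abs(u) >= 1, 0, (1 - u^2)^2)
        if (sum(w > 0) < 3) break
        cf2 <- fit_coef(w)
        if (is.null(cf2)) break
        cf <- cf2
      }
    }
    out[i] <- if (slope) cf[2] else cf[1]
  }
  out
}

#' Smooth a time series by local robust quadratic regression
#'
#' @param x numeric series; NA marks missing samples (ignored in each window).
#' @param times sample times, s (uniformly spaced).
#' @param window_ms moving-window length in milliseconds (default 25, the
#'   body-landmark window; use 5 for fast-moving leg landmarks).
#' @param robust logical; if TRUE, samples more than 6 MAD from the local fit
#'   get zero weight (bisquare inside), with two reweighting iterations.
#' @return smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, times, window_ms = 25, robust = TRUE) {
  .local_quad(x, times, window_ms, robust, slope = FALSE)
}

#' Differentiate a time series by local quadratic regression
#'
#' Slope of the local quadratic fit at each sample; exact for polynomials of
#' degree <= 2.
#'
#' @inheritParams smooth_series
#' @return derivative series, units of x per second.
#' @export
derivative_series <- function(x, times, window_ms = 25, robust = FALSE) {
  .local_quad(x, times, window_ms, robust, slope = TRUE)
}

#' Fit the ground plane to foot-contact points
#'
#' Total-least-squares plane through a cloud of 3D points (smallest principal
#' component of the centred cloud), with the normal oriented along +Z.
#'
#' @param points n x 3 matrix of 3D points (m), n >= 3, non-collinear.
#' @return list with unit `normal` (positive Z component), `offset` (plane is
#'   `normal . p = offset`), `residual_sd` (m, SD of signed point-plane
#'   distances), and `centroid`.
#' @export
fit_ground_plane <- function(points) {
  points <- as.matrix(points)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 3) stop("ground-plane fit needs >= 3 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (e$values[2] < 1e-20 + 1e-9 * e$values[1]) {
    stop("ground-plane fit: points are collinear")
  }
  normal <- e$vectors[, 3]
  if (normal[3] < 0) normal <- -normal
  d <- as.numeric(X %*% normal)
  list(normal = normal,
       offset = sum(normal * ctr),
       residual_sd = if (length(d) > 1) stats::sd(d) else 0,
       centroid = ctr)
}

#' The canonical horizontal ground plane Z = 0
#' @param residual_sd nominal measurement SD to attach, m (default 0.25 mm,
#'   a typical plane-calibration uncertainty).
#' @return a plane object as returned by [fit_ground_plane()].
#' @export
horizontal_ground_plane <- function(residual_sd = 2.5e-4) {
  list(normal = c(0, 0, 1), offset = 0, residual_sd = residual_sd,
       centroid = c(0, 0, 0))
}

#' Signed height of points above a fitted plane
#' @param points length-3 vector or n x 3 matrix.
#' @param plane result of [fit_ground_plane()].
#' @return signed distances, m (positive above the plane).
#' @export
plane_height <- function(points, plane) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  as.numeric(points %*% plane$normal - plane$offset)
}
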
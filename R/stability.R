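# Static stability: ground-contact detection, support polygon (convex hull
# of ground contacts), signed stability margin SM, ideal stability margin
# ISM, and their ratio. Sign semantics: SM > 0 iff the COM ground
# projection lies strictly inside the support polygon; degenerate supports
# (a point or segment) can never enclose the COM, so their SM is never
# positive. Contacts that pull (adhesion, claws) can stabilize any SM; SM
# here assumes pushing contacts only.

#' Detect landmarks in ground contact
#'
#' A landmark is in contact if its unsigned distance to the ground plane is
#' at most the tolerance (default: twice the plane-fit residual SD, i.e.
#' about twice the tracking uncertainty).
#'
#' @param positions named list or matrix (rows named) of landmark positions
#'   for one frame, m.
#' @param plane fitted ground plane from [fit_ground_plane()].
#' @param tolerance contact tolerance, m (> 0); default `2 * residual_sd`.
#' @return character vector of in-contact landmark names.
#' @export
detect_contacts <- function(positions, plane,
                            tolerance = 2 * plane$residual_sd) {
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("contact tolerance must be > 0")
  }
  if (is.list(positions)) {
    positions <- do.call(rbind, positions)
  }
  h <- abs(plane_height(positions, plane))
  rownames(positions)[!is.na(h) & h <= tolerance]
}

#' In-plane orthonormal basis of a ground plane
#' @param plane fitted plane.
#' @return 3 x 2 matrix whose columns span the plane.
#' @keywords internal
plane_basis <- function(plane) {
  n <- plane$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  cbind(e1, e2)
}

#' Project 3D points into ground-plane coordinates
#' @param points length-3 vector or n x 3 matrix.
#' @param plane fitted plane.
#' @return n x 2 matrix of in-plane coordinates, m.
#' @export
project_to_plane <- function(points, plane) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  B <- plane_basis(plane)
  sweep(points, 2, plane$centroid) %*% B
}

.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((p - (a + t * ab))^2))
}

.polygon_area_centroid <- function(P) {
  # P: k x 2 CCW vertices
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-300) return(list(area = 0, centroid = colMeans(P)))
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  list(area = abs(A), centroid = c(cx, cy))
}

.dist_to_polygon_boundary <- function(p, P) {
  k <- nrow(P)
  min(vapply(seq_len(k), function(i) {
    .point_segment_distance(p, P[i, ], P[if (i == k) 1 else i + 1, ])
  }, numeric(1)))
}

.inside_convex <- function(p, P) {
  # P CCW; strictly inside iff all edge cross products > 0
  k <- nrow(P)
  all(vapply(seq_len(k), function(i) {
    a <- P[i, ]; b <- P[if (i == k) 1 else i + 1, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) > 0
  }, logical(1)))
}

#' Stability margin from contact points and the COM projection
#'
#' Builds the support polygon (2D convex hull of contact points in
#' ground-plane coordinates) and returns the signed stability margin: plus
#' the minimum distance from the COM projection to the hull boundary when
#' inside, minus the distance to the hull when outside. The ideal stability
#' margin ISM is the boundary distance from the polygon's area centroid; the
#' ratio SM/ISM (%) measures closeness to optimal static stability.
#'
#' @param contacts k x 2 matrix of contact points in ground-plane
#'   coordinates, m (k >= 1).
#' @param com_proj length-2 COM projection in the same coordinates, m.
#' @return list with `SM` (m, signed), `ISM` (m; 0 for degenerate hulls),
#'   `SM_ratio` (percent; NA for degenerate hulls), `polygon` (hull
#'   vertices, CCW), and `n_contacts`.
#' @export
stability_margin <- function(contacts, com_proj) {
  contacts <- as.matrix(contacts)
  contacts <- contacts[stats::complete.cases(contacts), , drop = FALSE]
  if (nrow(contacts) == 0) {
    return(list(SM = NA_real_, ISM = NA_real_, SM_ratio = NA_real_,
                polygon = NULL, n_contacts = 0L))
  }
  hull_idx <- grDevices::chull(contacts[, 1], contacts[, 2])
  P <- contacts[rev(hull_idx), , drop = FALSE]   # chull returns CW; make CCW
  k <- nrow(P)
  if (k == 1) {
    sm <- -sqrt(sum((com_proj - P[1, ])^2))
    return(list(SM = sm, ISM = 0, SM_ratio = NA_real_, polygon = P,
                n_contacts = nrow(contacts)))
  }
  if (k == 2) {
    sm <- -.point_segment_distance(com_proj, P[1, ], P[2, ])
    return(list(SM = sm, ISM = 0, SM_ratio = NA_real_, polygon = P,
                n_contacts = nrow(contacts)))
  }
  ac <- .polygon_area_centroid(P)
  if (ac$area <= 0) {
    sm <- -.dist_to_polygon_boundary(com_proj, P)
    return(list(SM = sm, ISM = 0, SM_ratio = NA_real_, polygon = P,
                n_contacts = nrow(contacts)))
  }
  bd <- .dist_to_polygon_boundary(com_proj, P)
  SM <- if (.inside_convex(com_proj, P)) bd else -bd
  ISM <- .dist_to_polygon_boundary(ac$centroid, P)
  list(SM = SM, ISM = ISM, SM_ratio = 100 * SM / ISM, polygon = P,
       n_contacts = nrow(contacts))
}
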
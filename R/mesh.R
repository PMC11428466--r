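# Triangle-mesh handling: STL reading/writing, watertightness and
# orientation checks, uniform-density mass properties by exact polyhedral
# volume integrals, and primitive meshes (box, ellipsoid) used for
# verification and as body stand-ins.
#
# A mesh is a list with `vertices` (n x 3 numeric, m) and `faces`
# (m x 3 integer, 1-based, counter-clockwise seen from outside).

new_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices,
                 faces = matrix(as.integer(faces), ncol = 3)),
            class = "body_mesh")
}

#' @export
print.body_mesh <- function(x, ...) {
  cat(sprintf("body_mesh: %d vertices, %d faces, volume %.4g m^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

.mesh_edge_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Count open (boundary) edges of a mesh
#'
#' An edge of a watertight mesh is shared by exactly two faces.
#'
#' @param mesh a `body_mesh`.
#' @return number of undirected edges not shared by exactly two faces.
#' @export
mesh_open_edges <- function(mesh) {
  sum(.mesh_edge_counts(mesh) != 2L)
}

#' Signed volume of a triangle mesh
#'
#' Positive when faces are consistently oriented outward.
#'
#' @param mesh a `body_mesh`.
#' @return signed volume, m^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  detj <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(detj) / 6
}

#' Validate a mesh and fix global orientation
#'
#' Errors (reporting the open-edge count) if the mesh is not watertight;
#' flips all faces if the signed volume is negative so faces point outward.
#'
#' @param mesh a `body_mesh`.
#' @return the validated, outward-oriented mesh.
#' @export
mesh_validate <- function(mesh) {
  open_edges <- mesh_open_edges(mesh)
  if (open_edges > 0) {
    stop(sprintf("mesh is not watertight: %d open edge(s)", open_edges))
  }
  vol <- mesh_volume(mesh)
  if (abs(vol) < 1e-300) stop("mesh has zero volume")
  if (vol < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Rigidly transform a mesh
#' @param mesh a `body_mesh`.
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation (default zero).
#' @return transformed mesh.
#' @export
mesh_transform <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(R) +
    matrix(t, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# ---- STL I/O ---------------------------------------------------------------

.merge_vertices <- function(V, digits = 10) {
  key <- apply(signif(V, digits), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  list(vertices = V[first, , drop = FALSE], index = idx)
}

#' Read a triangle mesh from an STL file
#'
#' Handles both ASCII and binary STL. Duplicate vertices are merged, the mesh
#' is checked for watertightness, and face orientation is fixed so the signed
#' volume is positive.
#'
#' @param path STL file path.
#' @param units `"m"` or `"mm"`; mm coordinates are divided by exactly 1000.
#' @return a watertight, outward-oriented `body_mesh` with vertices in m.
#' @export
read_body_mesh <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("STL file not found: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- grepl("^\\s*solid", rawToChar(head[head != as.raw(0)]))
  # a binary STL can also start with "solid"; verify by size bookkeeping
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      is_ascii <- FALSE
    } else {
      V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
        as.numeric(p[2:4])
      }))
    }
  }
  if (!is_ascii) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n_tri <- readBin(con, "integer", 1, size = 4, endian = "little")
    dat <- readBin(con, "numeric", n_tri * 12, size = 4, endian = "little")
    M <- matrix(dat, ncol = 12, byrow = TRUE)   # normal + 3 vertices
    # 2-byte attribute counts are interleaved in real files; re-read properly
    close(con); on.exit()
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n_tri <- readBin(con, "integer", 1, size = 4, endian = "little")
    V <- matrix(NA_real_, n_tri * 3, 3)
    for (i in seq_len(n_tri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      V[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (anyNA(V)) stop("malformed STL file: ", path)
  merged <- .merge_vertices(V)
  faces <- matrix(merged$index, ncol = 3, byrow = TRUE)
  mesh <- new_mesh(merged$vertices, faces)
  if (units == "mm") mesh$vertices <- mesh$vertices / 1000
  mesh_validate(mesh)
}

#' Write a mesh as ASCII STL
#' @param mesh a `body_mesh`.
#' @param path output path.
#' @param units `"m"` or `"mm"` for the written coordinates.
#' @return `path`, invisibly.
#' @export
write_body_mesh <- function(mesh, path, units = c("m", "mm")) {
  units <- match.arg(units)
  V <- mesh$vertices * if (units == "mm") 1000 else 1
  f <- mesh$faces
  lines <- character(2 + 7 * nrow(f))
  lines[1] <- "solid mesh"
  k <- 2
  for (i in seq_len(nrow(f))) {
    a <- V[f[i, 1], ]; b <- V[f[i, 2], ]; c_ <- V[f[i, 3], ]
    n <- cross3(b - a, c_ - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    lines[k:(k + 6)] <- c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
      sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
      sprintf("      vertex %.17g %.17g %.17g", c_[1], c_[2], c_[3]),
      "    endloop",
      "  endfacet")
    k <- k + 7
  }
  lines[k] <- "endsolid mesh"
  writeLines(lines, path)
  invisible(path)
}

# ---- primitive meshes ------------------------------------------------------

#' Axis-aligned box mesh
#' @param size length-3 edge lengths, m (default unit cube).
#' @param center length-3 center position.
#' @return a `body_mesh` (12 faces, outward-oriented).
#' @export
box_mesh <- function(size = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- size / 2
  V <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  V <- V + matrix(center, 8, 3, byrow = TRUE)
  # vertex order from expand.grid: x fastest
  quads <- rbind(
    c(1, 2, 4, 3),  # z = -h (bottom, seen from below must be CW from above)
    c(5, 7, 8, 6),  # z = +h
    c(1, 5, 6, 2),  # y = -h
    c(3, 4, 8, 7),  # y = +h
    c(1, 3, 7, 5),  # x = -h
    c(2, 6, 8, 4)   # x = +h
  )
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  mesh_validate(new_mesh(V, faces))
}

#' Triangulated ellipsoid mesh
#'
#' Latitude-longitude tessellation of an ellipsoid with semi-axes
#' `(a, b, c)` along x, y, z.
#'
#' @param semi_axes length-3 semi-axes, m.
#' @param n_theta number of latitude bands (>= 8).
#' @param n_phi number of longitude slices (>= 8).
#' @param center length-3 center position.
#' @return a watertight `body_mesh`.
#' @export
ellipsoid_mesh <- function(semi_axes = c(4.45e-3, 1.8e-3, 1.1e-3),
                           n_theta = 40, n_phi = 60, center = c(0, 0, 0)) {
  stopifnot(n_theta >= 8, n_phi >= 8, all(semi_axes > 0))
  theta <- seq(0, pi, length.out = n_theta + 1)       # colatitude
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  # interior rings
  rings <- lapply(theta[2:n_theta], function(th) {
    cbind(semi_axes[1] * sin(th) * cos(phi),
          semi_axes[2] * sin(th) * sin(phi),
          semi_axes[3] * cos(th))
  })
  V <- rbind(c(0, 0, semi_axes[3]), do.call(rbind, rings), c(0, 0, -semi_axes[3]))
  n_rings <- n_theta - 1
  ring_idx <- function(r) 1 + (r - 1) * n_phi + seq_len(n_phi)
  top <- 1L
  bottom <- nrow(V)
  faces <- list()
  r1 <- ring_idx(1)
  faces[[1]] <- cbind(top, r1, r1[c(2:n_phi, 1)])
  for (r in seq_len(n_rings - 1)) {
    ia <- ring_idx(r); ib <- ring_idx(r + 1)
    ia2 <- ia[c(2:n_phi, 1)]; ib2 <- ib[c(2:n_phi, 1)]
    faces[[length(faces) + 1]] <- rbind(cbind(ia, ib, ib2), cbind(ia, ib2, ia2))
  }
  rl <- ring_idx(n_rings)
  faces[[length(faces) + 1]] <- cbind(bottom, rl[c(2:n_phi, 1)], rl)
  mesh <- new_mesh(V + matrix(center, nrow(V), 3, byrow = TRUE),
                   do.call(rbind, faces))
  mesh_validate(mesh)
}

# ---- mass properties -------------------------------------------------------

#' Uniform-density mass properties of a watertight mesh
#'
#' Exact polyhedral volume integrals (signed tetrahedra against the origin),
#' not surface sampling: volume, center of mass, and the inertia tensor about
#' the COM in mesh axes, scaled to the given total mass.
#'
#' @param mesh a watertight `body_mesh` (validated/oriented internally).
#' @param total_mass total mass, kg (> 0).
#' @return object of class `mass_properties`: list with `mass`, `volume`,
#'   `com` (m), `inertia_tensor` (3x3 kg m^2 about the COM, mesh axes),
#'   `principal_moments` (ascending) and `principal_axes` (columns).
#' @export
mesh_mass_properties <- function(mesh, total_mass) {
  if (!is.numeric(total_mass) || total_mass <= 0) stop("total_mass must be > 0")
  mesh <- mesh_validate(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  detj <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(detj) / 6
  s <- a + b + c_
  com <- colSums(detj * s) / 24 / vol
  # second moments about the origin: P[i,j] = integral of x_i x_j dV
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    P[i, j] <- P[j, i] <- sum(detj / 120 *
      (s[, i] * s[, j] + a[, i] * a[, j] + b[, i] * b[, j] + c_[, i] * c_[, j]))
  }
  rho <- total_mass / vol
  I_origin <- rho * (diag(3) * sum(diag(P)) - P)
  r <- com
  I_com <- I_origin - total_mass * (diag(3) * sum(r^2) - outer(r, r))
  I_com <- (I_com + t(I_com)) / 2
  e <- eigen(I_com, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(mass = total_mass, volume = vol, com = com,
                 inertia_tensor = I_com,
                 principal_moments = e$values[ord],
                 principal_axes = e$vectors[, ord, drop = FALSE]),
            class = "mass_properties")
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("mass_properties: m = %.4g kg, V = %.4g m^3\n", x$mass, x$volume))
  cat("  COM (m): ", paste(sprintf("%.4g", x$com), collapse = ", "), "\n")
  cat("  principal moments (kg m^2): ",
      paste(sprintf("%.4g", x$principal_moments), collapse = ", "), "\n")
  invisible(x)
}
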
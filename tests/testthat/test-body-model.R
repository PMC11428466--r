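# Mesh mass properties, rod/parallel-axis/arbitrary-axis inertia, anchor
# assembly, and standardized scaling.

test_that("cube inertia matches the closed form", {
  mp <- mesh_mass_properties(box_mesh(), total_mass = 2)
  expect_equal(mp$volume, 1, tolerance = 1e-12)
  expect_equal(mp$com, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(mp$inertia_tensor, diag(2 / 6, 3), tolerance = 1e-9)
})

test_that("ellipsoid inertia matches the analytic values within 0.5%", {
  a <- 6e-3; b <- 2e-3; c_ <- 1.5e-3; m <- 1e-3
  mp <- mesh_mass_properties(ellipsoid_mesh(c(a, b, c_), 80, 120), m)
  exact <- sort(c(m * (b^2 + c_^2) / 5, m * (a^2 + c_^2) / 5,
                  m * (a^2 + b^2) / 5))
  expect_lt(max(abs(mp$principal_moments - exact) / exact), 0.005)
  expect_equal(mp$volume, 4 / 3 * pi * a * b * c_, tolerance = 0.005)
})

test_that("mesh inertia is translation invariant and rotates tensorially", {
  set.seed(31)
  mesh <- ellipsoid_mesh(c(4e-3, 2e-3, 1e-3), 24, 36)
  mp <- mesh_mass_properties(mesh, 1e-5)
  mp_t <- mesh_mass_properties(mesh_transform(mesh, t = c(0.02, -0.01, 0.015)),
                               1e-5)
  expect_lt(max(abs(mp_t$inertia_tensor - mp$inertia_tensor)) /
              max(abs(mp$inertia_tensor)), 1e-8)
  for (i in 1:5) {
    R <- quat_to_matrix(random_quat())
    mp_r <- mesh_mass_properties(mesh_transform(mesh, R = R), 1e-5)
    expect_lt(max(abs(mp_r$inertia_tensor - R %*% mp$inertia_tensor %*% t(R))) /
                max(abs(mp$inertia_tensor)), 1e-9)
  }
})

test_that("eigendecomposition reproduces the tensor and satisfies triangle inequalities", {
  mp <- mesh_mass_properties(ellipsoid_mesh(), 28.4e-6)
  V <- mp$principal_axes
  rebuilt <- V %*% diag(mp$principal_moments) %*% t(V)
  expect_lt(max(abs(rebuilt - mp$inertia_tensor)) / max(abs(mp$inertia_tensor)),
            1e-12)
  pm <- mp$principal_moments
  expect_gte(pm[1] + pm[2], pm[3] * (1 - 1e-12))
})

test_that("rod inertia matches closed form and a point-mass discretization", {
  expect_equal(rod_inertia(0.012, 1), 0.001)
  expect_equal(rod_inertia(1, 0), 0)
  expect_error(rod_inertia(-1, 1), "> 0")
  # brute force: 1e5 point masses along the rod
  m <- 3.7e-6; L <- 5.2e-3
  x <- (seq_len(1e5) - 0.5) / 1e5 * L - L / 2
  expect_lt(abs(sum(m / 1e5 * x^2) - rod_inertia(m, L)) / rod_inertia(m, L),
            1e-6)
})

test_that("parallel axis theorem: identity, point mass, end-pivoted rod", {
  expect_equal(parallel_axis(0.37, 2, 0), 0.37)
  expect_equal(parallel_axis(0, 2, 0.3), 2 * 0.09)
  m <- 1.3; L <- 0.7
  expect_equal(parallel_axis(rod_inertia(m, L), m, L / 2), m * L^2 / 3,
               tolerance = 1e-12)
  expect_error(parallel_axis(1, 1, -0.1), ">= 0")
})

test_that("inertia about an arbitrary axis matches a point-cloud brute force", {
  set.seed(12)
  pts <- matrix(stats::rnorm(300, sd = 3e-3), 100, 3)
  mass <- stats::runif(100, 1e-8, 1e-6)
  com <- colSums(pts * mass) / sum(mass)
  pts <- sweep(pts, 2, com)
  I_tensor <- matrix(0, 3, 3)
  for (i in 1:100) {
    r <- pts[i, ]
    I_tensor <- I_tensor + mass[i] * (diag(3) * sum(r^2) - outer(r, r))
  }
  for (k in 1:20) {
    ax <- runit()
    brute <- sum(mass * (rowSums(pts^2) - as.numeric(pts %*% ax)^2))
    expect_lt(abs(inertia_about_axis(I_tensor, ax) - brute) / brute, 1e-6)
    expect_equal(inertia_about_axis(I_tensor, ax),
                 inertia_about_axis(I_tensor, -ax))
  }
  expect_error(inertia_about_axis(I_tensor, c(1, 1, 0)), "unit")
})

test_that("anchor assembly: degenerate legs, symmetry, brute-force closure", {
  mesh <- ellipsoid_mesh()
  morph <- default_leg_morphometrics()
  body <- mesh_mass_properties(mesh, 17e-6)
  # legs with negligible mass: whole-insect inertia collapses to the body's
  tiny <- morph
  tiny$seg1_mass[] <- 1e-18; tiny$seg2_mass[] <- 1e-18
  legs <- list()
  for (i in 1:6) {
    leg <- morph$leg[i]
    side <- if (grepl("^L", leg)) 1 else -1
    legs[[leg]] <- list(coxa = c(0, side * 1.5e-3, 0),
                        femur_tibia = c(0, side * 4e-3, 1e-3),
                        tarsus = c(0, side * 7e-3, 0))
  }
  an0 <- assemble_anchor(body, c(1, 0, 0, 0), c(0, 0, 0), legs, tiny,
                         axis = c(1, 0, 0))
  expect_equal(an0$I_spin,
               inertia_about_axis(body$inertia_tensor, c(1, 0, 0)),
               tolerance = 1e-9)
  # bilaterally symmetric pose: whole-insect COM on the sagittal plane
  an1 <- assemble_anchor(body, c(1, 0, 0, 0), c(0, 0, 0), legs, morph,
                         axis = c(1, 0, 0))
  expect_lt(abs(an1$com[2]), 1e-12)
  expect_equal(an1$mass, 17e-6 + total_leg_mass(morph), tolerance = 1e-12)
  # brute force: mesh volume cells + dense rod sampling, within 1%
  axp <- runit()
  an2 <- assemble_anchor(body, c(1, 0, 0, 0), c(0, 0, 0), legs, morph, axp)
  I_brute <- inertia_about_axis(body$inertia_tensor, axp) +
    body$mass * (sum((body$com - an2$com)^2) -
                   sum((body$com - an2$com) * axp)^2)
  for (i in 1:6) {
    leg <- morph$leg[i]
    for (seg in 1:2) {
      p1 <- if (seg == 2) legs[[leg]]$coxa else legs[[leg]]$femur_tibia
      p2 <- if (seg == 2) legs[[leg]]$femur_tibia else legs[[leg]]$tarsus
      m_seg <- if (seg == 2) morph$seg2_mass[i] else morph$seg1_mass[i]
      u <- seq(0.5 / 1e4, 1 - 0.5 / 1e4, length.out = 1e4)
      pts <- outer(1 - u, p1) + outer(u, p2)
      rel <- sweep(pts, 2, an2$com)
      I_brute <- I_brute + sum(m_seg / 1e4 *
                                 (rowSums(rel^2) - as.numeric(rel %*% axp)^2))
    }
  }
  expect_lt(abs(an2$I_spin - I_brute) / I_brute, 0.01)
})

test_that("splayed reference pose puts the legs' inertia share in the reported band", {
  share <- splayed_leg_inertia_share()
  expect_gte(share$mean, 0.65)
  expect_lte(share$mean, 0.72)
})

test_that("COM-axis inertia is minimal over parallel axes", {
  mp <- mesh_mass_properties(ellipsoid_mesh(), 28.4e-6)
  ax <- c(0, 0, 1)
  I0 <- inertia_about_axis(mp$inertia_tensor, ax)
  set.seed(2)
  for (i in 1:20) {
    d <- stats::runif(1, 1e-4, 5e-3)
    expect_gt(parallel_axis(I0, mp$mass, d), I0)
  }
})

test_that("standardized scaling is unit-preserving, correct, and idempotent", {
  sim <- sim_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  tr <- sim$trial                       # body length 8.9 mm already
  sc <- scale_to_standard(tr)
  expect_equal(sc$metadata$scale_factor, 1, tolerance = 1e-12)
  expect_equal(sc$landmarks$cranial, tr$landmarks$cranial, tolerance = 1e-12)

  tr2 <- tr; tr2$body_length <- 11.7e-3   # 4th-instar mean
  sc2 <- scale_to_standard(tr2)
  expect_equal(sc2$metadata$scale_factor, 8.9 / 11.7, tolerance = 1e-9)
  expect_equal(sc2$landmarks$caudal, tr$landmarks$caudal * 8.9 / 11.7,
               tolerance = 1e-12)
  expect_equal(sc2$mass, 28.4e-6)
  sc3 <- scale_to_standard(sc2)           # fixed point
  expect_equal(sc3$landmarks$caudal, sc2$landmarks$caudal, tolerance = 1e-12)
  tr3 <- tr; tr3$body_length <- NA_real_
  expect_error(scale_to_standard(tr3), "body_length")
})
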
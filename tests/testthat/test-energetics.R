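# Potential energy, righting number, apex/flip detection, PE landscapes.

test_that("potential energy arithmetic and decomposition", {
  expect_equal(potential_energy(1e-3, 28.4e-6), 2.786e-7, tolerance = 1e-3)
  expect_equal(potential_energy(0, 28.4e-6), 0)
  expect_error(potential_energy(1, -1), "> 0")
  # simulator truth: whole-insect PE equals body + leg components
  sim <- sim_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  expect_equal(sim$truth$pe_total, sim$truth$pe_body + sim$truth$pe_legs,
               tolerance = 1e-12)
})

test_that("pipeline PE gain matches the generator's programmed gain within a few %", {
  sim <- sim_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  an <- analysis_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  tr <- sim$truth
  fi <- which(an$frames$time_s >= an$attempts$start_s[1] &
                an$frames$time_s <= an$attempts$end_s[1])
  # compare over the same window the pipeline segmented
  gain_true <- max(tr$pe_total[fi]) - tr$pe_total[fi[1]]
  gain_est <- max(an$frames$PE_total[fi], na.rm = TRUE) -
    an$frames$PE_total[fi[1]]
  expect_lt(abs(gain_est - gain_true) / gain_true, 0.01)
})

test_that("righting number: threshold values, saturation, monotonicity", {
  expect_equal(righting_number(2e-7, 2e-7)$RN, 1)       # dynamic threshold
  expect_equal(righting_number(0, 1e-7)$RN, 0)          # purely quasistatic
  expect_equal(righting_number(0.25 * 3e-7, 3e-7)$RN, 0.25)  # paper cutoff
  rs <- righting_number(1e-8, 1e-12)
  expect_true(rs$saturated && is.na(rs$RN))
  expect_error(righting_number(-1e-9, 1e-9), ">= 0")
  dpe <- seq(1e-9, 1e-7, length.out = 50)
  rn <- righting_number(rep(2e-8, 50), dpe)$RN
  expect_true(all(diff(rn) < 0))
})

test_that("RN crosses 1 exactly when remaining barrier equals current KE", {
  # rigid tip-over: compare against the integrator's own energy ledger
  sim <- sim_mode("pitching", noise_sd = 0, seed = 2, legs_rigid = TRUE)
  tr <- sim$truth
  ri <- which(tr$phase == "righting")
  pe_max <- max(tr$pe_total[ri])
  dpe <- pmax(0, pe_max - tr$pe_total[ri])
  ke <- tr$ke[ri]
  ok <- dpe > 1e-10
  rn <- righting_number(ke[ok], dpe[ok])$RN
  cross <- which(rn[-1] >= 1 & rn[-length(rn)] < 1)[1]
  expect_false(is.na(cross))
  # interpolate the sub-frame crossing instant: there KE must equal dPE
  f <- (1 - rn[cross]) / (rn[cross + 1] - rn[cross])
  ke_c <- ke[ok][cross] + f * (ke[ok][cross + 1] - ke[ok][cross])
  dpe_c <- dpe[ok][cross] + f * (dpe[ok][cross + 1] - dpe[ok][cross])
  expect_lt(abs(ke_c / dpe_c - 1), 0.02)
})

test_that("apex/flip detection on constructed and simulated series", {
  t <- seq(0, 1, by = 0.001)
  zdv <- 1 - 2 * t                      # monotone ramp, crosses 0 at 0.5 s
  pe <- -(t - 0.4)^2
  ev <- detect_apex_and_overturning(t, pe, zdv)
  expect_equal(ev$flip_time, 0.5, tolerance = 1e-6)
  expect_equal(ev$apex_time, 0.4, tolerance = 1e-3)
  # a constant ramp's rate is everywhere at its maximum: the interval is
  # (nearly) the whole ramp
  expect_lt(ev$overturning[1], 0.05)
  expect_gt(ev$overturning[2], 0.95)

  # constant Z_dv: no flipping, failure flagged
  ev0 <- detect_apex_and_overturning(t, pe, rep(1, length(t)))
  expect_false(ev0$righted)
  expect_true(is.na(ev0$flip_time))

  # simulated diagonal rotation: apex strictly after the flip,
  # and the active-overturning window brackets the flip
  an <- analysis_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  ev2 <- an$events
  expect_gt(ev2$apex_time, ev2$flip_time)
  expect_lte(ev2$overturning[1], ev2$flip_time)
  expect_gte(ev2$overturning[2], ev2$flip_time)
})

test_that("PE landscape: symmetry oracles and basin structure", {
  # sphere: constant over the whole grid to facet tolerance
  sph <- ellipsoid_mesh(c(2e-3, 2e-3, 2e-3), 28, 40)
  g <- seq(-pi, pi, length.out = 17)
  L <- pe_landscape(sph, 1e-5, pitch = g, roll = g)
  expect_lt((max(L$PE) - min(L$PE)) / mean(L$PE), 0.01)

  # triaxial ellipsoid: resting flat is the global minimum; on the side is
  # higher; the landscape is symmetric under roll -> -roll
  ell <- ellipsoid_mesh(c(4.45e-3, 1.8e-3, 1.1e-3), 48, 72)
  gp <- seq(-pi, pi - pi / 18, by = pi / 18)
  L2 <- pe_landscape(ell, 1.7e-5, pitch = gp, roll = gp)
  i0 <- which.min(abs(gp)); i90 <- which.min(abs(gp - pi / 2))
  expect_lt(L2$PE[i0, i0], L2$PE[i0, i90])
  expect_equal(L2$PE[i0, i0], min(L2$PE), tolerance = 0.02)
  roll_sym <- vapply(seq_along(gp), function(j) {
    jm <- which.min(abs(gp + gp[j]))
    abs(L2$PE[i0, j] - L2$PE[i0, jm]) / mean(L2$PE)
  }, numeric(1))
  expect_lt(max(roll_sym), 0.01)

  # landscape values are bounded below by the minimum support height
  expect_true(all(L2$PE > 0))
})

test_that("PE landscape writes a dense long-format grid", {
  ell <- ellipsoid_mesh(n_theta = 12, n_phi = 18)
  g <- seq(-pi / 2, pi / 2, length.out = 5)
  L <- pe_landscape(ell, 1e-5, pitch = g, roll = g)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pe_landscape(L, tmp)
  back <- read_metrics(tmp)
  expect_equal(nrow(back), 25)
  expect_equal(back$PE_J[1], L$PE[1, 1], tolerance = 1e-12)
})
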
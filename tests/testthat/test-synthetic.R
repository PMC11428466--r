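# The synthetic-trial generator: determinism, dynamics, pose library.

test_that("identical configs and seeds give identical trials", {
  s1 <- simulate_trial(synthetic_trial_config(mode = "diagonal_rotating",
                                              noise_sd = 2e-4, seed = 42))
  s2 <- simulate_trial(synthetic_trial_config(mode = "diagonal_rotating",
                                              noise_sd = 2e-4, seed = 42))
  expect_identical(s1$trial$landmarks, s2$trial$landmarks)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(s1$trial, f1)
  write_landmark_table(s2$trial, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_trial(synthetic_trial_config(mode = "diagonal_rotating",
                                              noise_sd = 2e-4, seed = 43))
  expect_false(identical(s1$trial$landmarks, s3$trial$landmarks))
})

test_that("a balanced inverted pendulum stays at its apex", {
  # point mass exactly above the pivot: unstable equilibrium is a fixed
  # point of the integrator
  M <- 1e-3; d <- 5e-3; I <- M * d^2
  tau_g <- function(phi) M * 9.81 * d * sin(phi)   # phi from vertical
  tt <- seq(0, 0.2, by = 1e-3)
  tr <- integrate_pivoted_rotation(I, tau_g, function(t) 0, 0, 0, tt)
  expect_lt(max(abs(tr$phi)), 1e-12)
})

test_that("a pendulum released just past vertical conserves energy to 0.1%", {
  M <- 1e-3; d <- 5e-3; I <- M * d^2
  tau_g <- function(phi) M * 9.81 * d * sin(phi)
  tt <- seq(0, 0.12, by = 1e-3)
  tr <- integrate_pivoted_rotation(I, tau_g, function(t) 0, pi / 180, 0, tt)
  expect_gt(max(tr$phi), 1)                        # it tips over
  E <- M * 9.81 * d * cos(tr$phi) + 0.5 * I * tr$omega^2
  expect_lt((max(E) - min(E)) / (M * 9.81 * d), 1e-3)
})

test_that("constant torque from rest arrives in sqrt(2 theta I / tau)", {
  I <- 1.8e-9; tau <- 8e-7; theta <- pi / 2
  tt <- seq(0, 0.1, by = 1e-3)
  tr <- integrate_pivoted_rotation(I, function(p) 0, function(t) tau, 0, 0, tt)
  t_arr <- stats::approx(tr$phi, tr$t, xout = theta)$y
  expect_lt(abs(t_arr - sqrt(2 * theta * I / tau)) /
              sqrt(2 * theta * I / tau), 0.01)
})

test_that("rigid trials conserve mechanical energy in the torque-free coast", {
  sim <- sim_mode("pitching", noise_sd = 0, seed = 2, legs_rigid = TRUE)
  tr <- sim$truth
  coast <- which(tr$phase == "righting" & tr$tau_applied == 0 &
                   abs(tr$omega) > 0)
  coast <- coast[-length(coast)]           # drop the clamped landing frame
  E <- tr$pe_total[coast] + tr$ke[coast]
  expect_gt(length(coast), 10)
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-3)
})

test_that("unstable torque programs are rejected", {
  cfg <- synthetic_trial_config(mode = "pitching", noise_sd = 0,
                                applied_torque = 5e-3)
  expect_error(simulate_trial(cfg), "unstable")
})

test_that("the reference pose library has the advertised geometry", {
  lib <- make_reference_pose_library()
  expect_identical(attr(lib$overturned, "Zdv"), 1)
  expect_lt(attr(lib$righted, "Zdv"), 0)
  # righted: all six tarsi on the ground plane
  tarsi_z <- vapply(leg_names(), function(l) {
    lib$righted[[paste0("tarsus_", l)]][3]
  }, numeric(1))
  expect_lt(max(abs(tarsi_z)), 1e-4)
  # apex pose has the maximal COM height among library poses
  morph <- default_leg_morphometrics()
  com_z <- vapply(lib, function(pose) {
    pts <- do.call(rbind, pose[grepl("^(coxa|femur|tarsus|cranial|caudal|dorsum)",
                                     names(pose))])
    mean(pts[, 3])
  }, numeric(1))
  expect_equal(names(which.max(com_z)), "apex")
})

test_that("lifted-mode bodies stay airborne until righted", {
  sim <- sim_mode("lifted_rotating", noise_sd = 0, seed = 7)
  tr <- sim$truth
  ri <- which(tr$phase == "righting")
  body_z <- vapply(ri, function(i) {
    min(tr$landmarks_clean$cranial[i, 3], tr$landmarks_clean$caudal[i, 3],
        tr$landmarks_clean$dorsum_mid[i, 3])
  }, numeric(1))
  expect_gt(min(body_z), 2e-4)
})
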
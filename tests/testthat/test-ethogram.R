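# Attempt segmentation, method classification, behavior frequencies,
# friction conversion.

test_that("a single clean tip-over yields one successful attempt", {
  an <- analysis_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  expect_true(an$success)
  expect_equal(an$n_attempts, 1)
  expect_equal(an$attempts$outcome, "success")
  expect_gt(an$summary$time_per_attempt_s, 0)
})

test_that("programmed rock-and-fall-back attempts are counted exactly", {
  an4 <- fixture("an diag 4 attempts", function() {
    sim <- sim_mode("diagonal_rotating", noise_sd = 0, seed = 5,
                    n_attempts = 4)
    analyze_trial(sim$trial, robust = FALSE)
  })
  expect_equal(an4$n_attempts, 4)
  expect_true(an4$success)
  expect_equal(an4$attempts$outcome, c(rep("failure", 3), "success"))

  # at tracking noise the count stays within +-1 (two seeds)
  for (sd in c(11, 12)) {
    an_n <- fixture(paste("an diag 3 attempts noisy", sd), function() {
      sim <- sim_mode("diagonal_rotating", noise_sd = 2e-4, seed = sd,
                      n_attempts = 3)
      analyze_trial(sim$trial, robust = TRUE)
    })
    expect_lte(abs(an_n$n_attempts - 3), 1)
    expect_true(an_n$success)
  }
})

test_that("a flat-lined overturned trial reports failure", {
  t <- seq(0, 2, by = 0.001)
  n <- length(t)
  seg <- segment_attempts(t, zdv = rep(0.99, n), dorsum_height = rep(0, n),
                          tarsi_in_contact = rep(0L, n),
                          com_speed = rep(0, n))
  expect_false(seg$success)
  expect_equal(seg$n_attempts, 0)
  # the failed synthetic mode also never rights
  an_f <- fixture("an failed", function() {
    sim <- sim_mode("failed", noise_sd = 0, seed = 4, n_attempts = 2)
    analyze_trial(sim$trial, robust = FALSE)
  })
  expect_false(an_f$success)
  expect_equal(an_f$n_attempts, 2)
})

test_that("method classification matches the programmed mode", {
  expect_equal(analysis_mode("diagonal_rotating", 0, 1)$method,
               "diagonal_rotating")
  expect_equal(analysis_mode("lifted_rotating", 0, 7)$method,
               "lifted_rotating")
  expect_equal(analysis_mode("pitching", 0, 7)$method, "pitching")
})

test_that("classification is accurate across randomized noisy trials", {
  modes <- rep(c("diagonal_rotating", "lifted_rotating", "pitching"), each = 4)
  seeds <- rep(c(21, 22, 23, 24), times = 3)
  hits <- mapply(function(md, sd) {
    an <- fixture(paste("cls", md, sd), function() {
      sim <- sim_mode(md, noise_sd = 2e-4, seed = sd)
      analyze_trial(sim$trial, robust = TRUE)
    })
    an$method == md
  }, modes, seeds)
  expect_gte(mean(hits), 0.95)
})

test_that("classifier primitives follow the decision rule", {
  lat <- c(0, 1, 0)
  expect_equal(classify_method(FALSE, c(0, 1, 0), lat, c(0, 0, 0), c(0, 0, 0)),
               "lifted_rotating")
  expect_equal(classify_method(TRUE, c(0, 1, 0), lat, c(-4e-3, 0, 0),
                               c(-4e-3, 0, 0)), "pitching")
  # axis oblique to the lateral axis -> diagonal even with a caudal pivot
  ax45 <- c(sin(45 * pi / 180), cos(45 * pi / 180), 0)
  expect_equal(classify_method(TRUE, ax45, lat, c(-4e-3, 0, 0),
                               c(-4e-3, 0, 0)), "diagonal_rotating")
  # pitch-like axis but a non-caudal pivot -> diagonal
  expect_equal(classify_method(TRUE, c(0, 1, 0), lat, c(0, 0, 0),
                               c(-4e-3, 0, 0)), "diagonal_rotating")
  expect_equal(classify_method(NA, c(0, 1, 0), lat, c(0, 0, 0), c(0, 0, 0)),
               "none")
})

test_that("behavior frequencies reproduce the printed percentages", {
  freq <- behavior_frequencies(c(diagonal = 289, lifted = 9, pitching = 1))
  expect_equal(unname(freq), c(96.7, 3.0, 0.3))
  expect_equal(unname(behavior_frequencies(c(a = 0, b = 10))), c(0, 100))
  expect_error(behavior_frequencies(c(a = 0, b = 0)), "> 0")
})

test_that("friction coefficients follow mu = tan(psi)", {
  expect_equal(friction_from_tilt(pi / 4), 1)
  expect_equal(friction_from_tilt(0), 0)
  expect_equal(friction_from_tilt(atan(0.36)), 0.36)
  expect_error(friction_from_tilt(pi / 2), "lower bound")
})
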
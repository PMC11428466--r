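# Contact detection, support polygon, stability margins.

test_that("contact detection respects the tolerance and is monotone in it", {
  plane <- fit_ground_plane(cbind(stats::runif(10), stats::runif(10), 0))
  pos <- rbind(low = c(0.1, 0.1, 1e-4), high = c(0.2, 0.2, 5e-3))
  expect_equal(detect_contacts(pos, plane, 5e-4), "low")
  expect_equal(length(detect_contacts(pos, plane, 1e-5)), 0)
  expect_error(detect_contacts(pos, plane, 0), "> 0")
  # sweep: contact count nondecreasing in tolerance on a noisy pose
  set.seed(9)
  pose <- cbind(stats::runif(12), stats::runif(12),
                abs(stats::rnorm(12, 0, 5e-4)))
  rownames(pose) <- paste0("p", 1:12)
  counts <- vapply(seq(1e-5, 2e-3, length.out = 30), function(tol) {
    length(detect_contacts(pose, plane, tol))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("stability margin: unit square closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- stability_margin(sq, c(0.5, 0.5))
  expect_equal(r$SM, 0.5)
  expect_equal(r$ISM, 0.5)
  expect_equal(r$SM_ratio, 100)
  r2 <- stability_margin(sq, c(2, 0.5))
  expect_equal(r2$SM, -1)
})

test_that("stability margin agrees with a brute-force edge oracle on random hulls", {
  set.seed(77)
  for (rep in 1:40) {
    pts <- matrix(stats::rnorm(12), 6, 2)
    p <- stats::rnorm(2, sd = 1.5)
    r <- stability_margin(pts, p)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    k <- nrow(hull)
    # oracle: min point-segment distance over edges; inside via sign
    # consistency of all edge cross-products
    dists <- vapply(seq_len(k), function(i) {
      a <- hull[i, ]; b <- hull[if (i == k) 1 else i + 1, ]
      ab <- b - a; t0 <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((p - a - t0 * ab)^2))
    }, numeric(1))
    crosses <- vapply(seq_len(k), function(i) {
      a <- hull[i, ]; b <- hull[if (i == k) 1 else i + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    }, numeric(1))
    inside <- all(crosses > 0) || all(crosses < 0)
    sm_oracle <- if (inside) min(dists) else -min(dists)
    expect_equal(r$SM, sm_oracle, tolerance = 1e-12)
    expect_lte(r$SM, r$ISM + 1e-12)
  }
})

test_that("degenerate supports never report positive margins", {
  r1 <- stability_margin(rbind(c(1, 1)), c(0, 0))
  expect_equal(r1$SM, -sqrt(2))
  expect_equal(r1$ISM, 0)
  expect_true(is.na(r1$SM_ratio))
  r2 <- stability_margin(rbind(c(0, 0), c(2, 0)), c(1, 1))
  expect_equal(r2$SM, -1)
  r3 <- stability_margin(rbind(c(0, 0), c(1, 0), c(2, 0)), c(1, 0.5))
  expect_lte(r3$SM, 0)
})

test_that("margins are invariant to rigid translation and grow with added contacts", {
  set.seed(13)
  pts <- matrix(stats::rnorm(10), 5, 2)
  p <- c(0.1, -0.2)
  r <- stability_margin(pts, p)
  shift <- c(3.7, -1.2)
  r_sh <- stability_margin(sweep(pts, 2, -shift), p + shift)
  expect_equal(r$SM, r_sh$SM, tolerance = 1e-12)
  expect_equal(r$ISM, r_sh$ISM, tolerance = 1e-12)
  for (i in 1:20) {
    extra <- rbind(pts, stats::rnorm(2, sd = 2))
    expect_gte(stability_margin(extra, p)$SM, r$SM - 1e-12)
  }
})

test_that("simulated righting modes reproduce the reported margin signs", {
  # diagonal rotating: body pivot plus planted feet -> statically stable
  # (SM > 0) throughout the stroke
  an_d <- analysis_mode("diagonal_rotating", noise_sd = 0, seed = 1)
  ev <- an_d$events
  fi <- which(an_d$frames$time_s >= an_d$attempts$start_s[an_d$n_attempts] &
                an_d$frames$time_s <= an_d$attempts$end_s[an_d$n_attempts])
  pre <- fi[an_d$frames$time_s[fi] < ev$flip_time]
  expect_true(all(an_d$frames$SM[pre] > 0, na.rm = TRUE))

  # lifted rotating and pitching: unstable (SM < 0) before flipping; for a
  # caudal-pivot pitch the COM projection reaches the support boundary at
  # the flipping point itself, so the last few ms are excluded
  for (mode in c("lifted_rotating", "pitching")) {
    an <- analysis_mode(mode, noise_sd = 0,
                        seed = if (mode == "pitching") 7 else 7)
    ev <- an$events
    fi <- which(an$frames$time_s >= an$attempts$start_s[an$n_attempts] &
                  an$frames$time_s <= an$attempts$end_s[an$n_attempts])
    pre <- fi[an$frames$time_s[fi] < ev$flip_time - 0.005]
    sm_pre <- an$frames$SM[pre]
    expect_true(all(sm_pre < 0, na.rm = TRUE))
    all_pre <- an$frames$SM[fi[an$frames$time_s[fi] < ev$flip_time]]
    expect_gte(mean(all_pre < 0, na.rm = TRUE), 0.95)
  }
})
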
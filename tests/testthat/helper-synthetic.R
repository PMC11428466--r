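# Shared lazily-built fixtures: synthetic trials and their full analyses
# are expensive, so each is simulated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

sim_mode <- function(mode, noise_sd = 0, seed = 1, ...) {
  key <- paste("sim", mode, noise_sd, seed, ...)
  fixture(key, function() {
    simulate_trial(synthetic_trial_config(mode = mode, noise_sd = noise_sd,
                                          seed = seed, ...))
  })
}

analysis_mode <- function(mode, noise_sd = 0, seed = 1, ...) {
  key <- paste("an", mode, noise_sd, seed, ...)
  fixture(key, function() {
    sim <- sim_mode(mode, noise_sd, seed, ...)
    analyze_trial(sim$trial, robust = noise_sd > 0)
  })
}

# truth Z_dv series of a simulated trial (exact, from the programmed angle)
truth_zdv <- function(sim) {
  tr <- sim$truth
  q0 <- righting:::.mode_geometry(sim$config)$q0
  vapply(tr$phi, function(p) {
    compute_Zdv(quat_multiply(quat_from_axis_angle(tr$axis, p), q0))
  }, numeric(1))
}

# random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_quat <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) -q else q
}
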
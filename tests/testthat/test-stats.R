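grid512 <- function(period = 24) seq(0, period, length.out = 513)[1:512]

test_that("rhythm statistics of an analytic sinusoid are exact to grid error", {
  g <- grid512()
  st <- compute_rhythm_stats(5 + 2 * cos(2 * pi * g / 24), period = 24)
  expect_equal(st$mesor, 5, tolerance = 1e-6)
  expect_equal(st$peak, 7, tolerance = 1e-4)
  expect_equal(st$peak_phase, 0)
  expect_equal(st$trough, 3, tolerance = 1e-4)
  expect_equal(st$trough_phase, 12)
  expect_equal(st$ptr_amp, 4, tolerance = 1e-3)
  expect_equal(st$rms_amp, 2 / sqrt(2), tolerance = 1e-3)
  expect_false(st$degenerate)
})

test_that("constant curves are flagged degenerate with phases 0", {
  st <- compute_rhythm_stats(rep(1.5, 512), period = 24)
  expect_equal(st$ptr_amp, 0)
  expect_equal(st$rms_amp, 0)
  expect_equal(st$peak_phase, 0)
  expect_equal(st$trough_phase, 0)
  expect_true(st$degenerate)
})

test_that("RMS amplitude never exceeds peak-to-trough amplitude", {
  set.seed(20)
  for (i in 1:20) {
    v <- as.numeric(stats::filter(rnorm(512), rep(1 / 30, 30), circular = TRUE))
    st <- compute_rhythm_stats(v, 24)
    expect_lte(st$rms_amp, st$ptr_amp)
  }
})

test_that("curve evaluation averages the shifted models", {
  sim <- simulate_rhythm_data(n_genes = 5, seed = 21, frac_rhythmic = 1)
  fit <- rhythmfit(sim$experiment, shrink = FALSE, backend = "plain")
  V <- evaluate_curves(fit, type = "raw", grid_size = 128)
  g <- attr(V, "time")
  # oracle: evaluate each shifted model separately and average
  oracle <- 0
  for (k in 1:3) {
    Xk <- cbind(1, periodic_spline_basis(g, 24, 3, shift = fit$raw$shifts[k]))
    ck <- fit$raw$fits[[k]]$coef
    oracle <- oracle + (ck %*% t(Xk)) / 3
  }
  expect_equal(unname(V), unname(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  # m = 1: curve equals the single model's fit
  fit1 <- rhythmfit(sim$experiment, n_shifts = 1, shrink = FALSE,
                    backend = "plain")
  V1 <- evaluate_curves(fit1, type = "raw", grid_size = 128)
  X1 <- cbind(1, periodic_spline_basis(g, 24, 3))
  expect_equal(unname(V1), unname(fit1$raw$fits[[1]]$coef %*% t(X1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # zero time coefficients: flat curve at the intercept
  flat <- rhythm_experiment(matrix(2.5, 1, 24), time = seq(0, 46, by = 2))
  ff <- rhythmfit(flat, shrink = FALSE, backend = "plain")
  Vf <- evaluate_curves(ff, type = "raw")
  expect_equal(as.numeric(Vf), rep(2.5, 512), tolerance = 1e-9)
})

test_that("identical draws give identical per-draw statistics, in draw order", {
  g <- grid512()
  curves <- matrix(rep(3 + cos(2 * pi * g / 24), 4), nrow = 4, byrow = TRUE)
  st <- compute_rhythm_stats(curves, 24)
  expect_equal(nrow(st), 4)
  for (col in names(st)) expect_length(unique(st[[col]]), 1)
})

test_that("the amplitude sign-flip rule follows the circular mean phase", {
  # all draws at one phase: nothing flips
  s <- signed_amplitude(c(2, 2, 2), c(5, 5, 5), period = 24)
  expect_equal(as.numeric(s), c(2, 2, 2))
  expect_equal(attr(s, "reference_phase"), 5, tolerance = 1e-10)
  # phases 0, 0, 12 with equal amplitudes: reference 0, third draw negated
  s2 <- signed_amplitude(c(1, 1, 1), c(0, 0, 12), period = 24)
  expect_equal(as.numeric(s2), c(1, 1, -1))
  # uniform phases: about half flip (binomial 3 sigma)
  set.seed(22)
  ph <- runif(2000, 0, 24)
  s3 <- signed_amplitude(rep(1, 2000), ph, 24)
  n_flip <- sum(s3 < 0)
  expect_lt(abs(n_flip - 1000), 3 * sqrt(2000 * 0.25))
  # all-zero amplitudes: degenerate, unflipped
  s4 <- signed_amplitude(c(0, 0), c(1, 13), 24)
  expect_true(attr(s4, "degenerate"))
  expect_equal(as.numeric(s4), c(0, 0))
})

test_that("credible intervals follow the quantile and HDI rules", {
  ci <- credible_interval(1:100, 0.90, "equal_tailed")
  expect_equal(ci$lower, as.numeric(quantile(1:100, 0.05)))
  expect_equal(ci$upper, as.numeric(quantile(1:100, 0.95)))
  expect_equal(ci$lower, 5.95, tolerance = 1e-12)
  expect_equal(ci$upper, 95.05, tolerance = 1e-12)
  cc <- credible_interval(rep(3, 10), 0.9, "hdi")
  expect_equal(c(cc$lower, cc$upper), c(3, 3))
  ce <- credible_interval(rep(3, 10), 0.9, "equal_tailed")
  expect_equal(c(ce$lower, ce$upper), c(3, 3))
  expect_error(credible_interval(1:10, mass = 1.2), "mass")
  # HDI width never exceeds equal-tailed width
  set.seed(23)
  for (i in 1:30) {
    x <- switch(1 + i %% 3, rnorm(150), rexp(150), c(rnorm(80), rnorm(70, 8)))
    hdi <- credible_interval(x, 0.9, "hdi")
    et <- credible_interval(x, 0.9, "equal_tailed")
    expect_lte(hdi$upper - hdi$lower, et$upper - et$lower + 1e-12)
  }
})

test_that("adding a constant shifts levels but not amplitudes or phases", {
  sim <- simulate_rhythm_data(n_genes = 6, seed = 24, frac_rhythmic = 1)
  ex <- sim$experiment
  fit0 <- rhythmfit(ex, shrink = FALSE, backend = "plain")
  ex$measurements <- ex$measurements + 2.5
  fit1 <- rhythmfit(ex, shrink = FALSE, backend = "plain")
  s0 <- rhythm_stats(fit0, type = "raw")
  s1 <- rhythm_stats(fit1, type = "raw")
  expect_equal(s1$mesor, s0$mesor + 2.5, tolerance = 1e-8)
  expect_equal(s1$peak, s0$peak + 2.5, tolerance = 1e-8)
  expect_equal(s1$trough, s0$trough + 2.5, tolerance = 1e-8)
  expect_equal(s1$ptr_amp, s0$ptr_amp, tolerance = 1e-8)
  expect_equal(s1$rms_amp, s0$rms_amp, tolerance = 1e-8)
  expect_equal(s1$peak_phase, s0$peak_phase)
})

test_that("translating sample times rotates phases and preserves amplitudes", {
  sim <- simulate_rhythm_data(n_genes = 6, seed = 25, frac_rhythmic = 1)
  ex <- sim$experiment
  # a multiple of the knot-shift spacing maps each shifted model space onto
  # itself, making the equivariance exact rather than approximate
  delta <- 6
  fit0 <- rhythmfit(ex, shrink = FALSE, backend = "plain")
  ex2 <- rhythm_experiment(ex$measurements, time = ex$time + delta)
  fit1 <- rhythmfit(ex2, shrink = FALSE, backend = "plain")
  s0 <- rhythm_stats(fit0, type = "raw")
  s1 <- rhythm_stats(fit1, type = "raw")
  expect_equal(s1$ptr_amp, s0$ptr_amp, tolerance = 1e-6)
  expect_equal(s1$rms_amp, s0$rms_amp, tolerance = 1e-6)
  circ_diff <- (s1$peak_phase - s0$peak_phase - delta) %% 24
  circ_diff <- pmin(circ_diff, 24 - circ_diff)
  expect_true(all(circ_diff < 24 / 512 + 1e-9))
})

test_that("interval coverage for peak-to-trough amplitude is calibrated", {
  # sinusoidal truth lies (near) the spline model space, so coverage error
  # reflects the interval construction rather than waveform misspecification
  sim <- simulate_rhythm_data(n_genes = 300, seed = 26, frac_rhythmic = 1,
                              waveforms = "sinusoid", noise_coupling = 0)
  fit <- rhythmfit(sim$experiment)
  iv <- rhythm_intervals(fit, n_draws = 100, seed = 27)
  covered <- iv$ptr_amp_lower <= sim$truth$amplitude &
    sim$truth$amplitude <= iv$ptr_amp_upper
  expect_gte(mean(covered), 0.80)
  expect_lte(mean(covered), 0.97)
})
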
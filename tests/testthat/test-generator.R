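test_that("trial configs validate and map pellet grades", {
  cfg <- trial_config(pellet = "2#")
  expect_equal(cfg$pellet_mm, 3)
  expect_equal(trial_config(pellet = "6#")$pellet_mm, 7)
  expect_equal(trial_config(pellet = 4.2)$pellet_mm, 4.2)
  expect_error(trial_config(pellet = "9#"), "unknown pellet")
  expect_error(trial_config(size_g = -5), "positive")
})

test_that("generation is bit-reproducible for a fixed config and seed", {
  cfg <- trial_config(seed = 314)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$z, b$z)
  c <- generate_trial(trial_config(seed = 315))
  expect_false(identical(a$x, c$x))
})

test_that("the noiseless envelope rises to a single calibrated peak", {
  # modulation off: the per-sample sum is exactly the scaled envelope
  p <- noiseless_params(modulation_depth = 0)
  cfg <- trial_config(size_g = 300, density = 30, feed_rate = 1, seed = 2)
  tr <- generate_trial(cfg, p)
  s <- triaxial_sum(tr)
  expect_equal(s[1], 0)                     # A(0) = 0
  ipk <- which.max(s)
  expect_equal(tr$time[ipk], 35, tolerance = 0.11)  # envelope peak at t_peak
  expect_true(all(diff(s[1:ipk]) > -1e-12))         # monotone rise
  expect_true(all(diff(s[ipk:length(s)]) < 1e-12))  # monotone decay
})

test_that("noiseless peak window sums recover the calibrated group means", {
  profiles <- default_profiles()
  peaks <- vapply(c(50, 150, 300), function(S) {
    cfg <- trial_config(size_g = S, density = 30, feed_rate = 1, seed = S)
    ws <- window_sums(triaxial_sum(generate_trial(cfg, noiseless_params())))
    peak_displacement(ws)$peak
  }, numeric(1))
  expect_equal(peaks, profiles$size$means, tolerance = 1e-9)
  # OLS recovery: refitting the noiseless peaks returns the published line
  fit <- fit_line(c(50, 150, 300), peaks)
  expect_equal(fit$slope, 1.7316, tolerance = 1e-6)
  expect_equal(fit$intercept, 236.41, tolerance = 1e-6)
})

test_that("noiseless 2# trials oscillate at the base frequency", {
  f <- vapply(1:4, function(sd) {
    tr <- generate_trial(trial_config(pellet = "2#", seed = sd),
                         noiseless_params())
    fluctuation_frequency(triaxial_sum(tr))
  }, numeric(1))
  expect_true(all(abs(f - 2.0) / 2.0 < 0.05))
})

test_that("raw-series correlations hit the published targets", {
  tr <- generate_trial(trial_config(duration_s = 600, seed = 42))
  rho <- interaxis_correlation(tr)
  expect_lt(abs(rho$rho_xy - 0.93), 0.03)
  expect_lt(abs(rho$rho_xz - 0.88), 0.03)
  expect_lt(abs(rho$rho_yz - 0.91), 0.03)
  # the calibration also holds at the default 120-s duration
  rho2 <- interaxis_correlation(generate_trial(trial_config(seed = 9)))
  expect_lt(abs(rho2$rho_xy - 0.93), 0.03)
  expect_lt(abs(rho2$rho_xz - 0.88), 0.03)
  expect_lt(abs(rho2$rho_yz - 0.91), 0.03)
})

test_that("frequency reduction follows the factor table", {
  p <- generator_params()
  expect_equal(frequency_reduction(p, "2#", "4#"), 42)
  expect_equal(frequency_reduction(p, "4#", "4#"), 0)
  p2 <- generator_params(osc_freq_factors = c("3" = 1.0, "5" = 0.5,
                                              "7" = 0.75))
  expect_equal(frequency_reduction(p2, "2#", "4#"), 50)
  expect_error(frequency_reduction(p, 12, "4#"), "unknown pellet")
})

test_that("the default design expands to the published trial count", {
  d <- default_design()
  expect_equal(nrow(d), 12)
  expect_equal(sum(d$replicates), 408)
  small <- generate_dataset(default_design(replicates = 1), master_seed = 3)
  expect_equal(nrow(small$manifest), 12)
  expect_length(small$traces, 12)
  # same master seed -> identical manifest (and seeds)
  small2 <- generate_dataset(default_design(replicates = 1), master_seed = 3)
  expect_identical(small$manifest, small2$manifest)
  expect_identical(small$traces[[1]]$x, small2$traces[[1]]$x)
})

test_that("trials shorter than one analysis window are rejected", {
  expect_error(generate_trial(trial_config(duration_s = 3, seed = 1)),
               "duration too short")
})

test_that("generator parameter validation catches bad values", {
  expect_error(generator_params(osc_freq_base = 6), "fs/2")
  expect_error(generator_params(modulation_depth = 1), "\\[0, 1\\)")
  expect_error(generator_params(ar_coef = 1), "\\(-1, 1\\)")
})
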
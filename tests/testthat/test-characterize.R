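test_that("peak extraction takes the earliest maximal window", {
  ws <- window_sums(rep(c(1, 5, 3), each = 50), 50)
  pk <- peak_displacement(ws)
  expect_equal(pk$peak, 250)
  expect_equal(pk$index, 2)
  expect_equal(peak_time(ws), 7.5)

  flat <- window_sums(rep(2, 150), 50)
  expect_equal(peak_displacement(flat)$index, 1)   # tie -> earliest

  single <- window_sums(rep(1, 50), 50)
  expect_equal(peak_time(single), 2.5)             # single-window midpoint

  expect_warning(empty <- window_sums(1:3, 50))
  expect_error(peak_displacement(empty), "empty")
})

test_that("OLS fit matches lm and respects affine invariances", {
  set.seed(11)
  x <- c(50, 150, 300, 50, 150, 300)
  y <- 2 * x + 30 + rnorm(6, sd = 20)
  fit <- fit_line(x, y)
  ref <- stats::lm(y ~ x)
  expect_equal(fit$slope, unname(coef(ref)[2]))
  expect_equal(fit$intercept, unname(coef(ref)[1]))
  expect_equal(fit$r_squared, summary(ref)$r.squared)

  shifted <- fit_line(x, y + 100)
  expect_equal(shifted$slope, fit$slope)
  expect_equal(shifted$intercept, fit$intercept + 100)
  scaled <- fit_line(x, 3 * y)
  expect_equal(scaled$slope, 3 * fit$slope)
  expect_equal(scaled$r_squared, fit$r_squared)

  collinear <- fit_line(1:4, 2 * (1:4) + 1)
  expect_equal(collinear$r_squared, 1)
  expect_error(fit_line(rep(1, 3), 1:3), "identical")
})

test_that("percent increase is a simple relative contrast", {
  expect_equal(percent_increase(100, 200), 100)
  for (a in c(0.5, 3, 120)) expect_equal(percent_increase(a, a), 0)
  expect_error(percent_increase(0, 5), "> 0")
})

test_that("mean-crossing frequency matches analytic cases and is scale-free", {
  t <- seq(0, 10 - 0.1, by = 0.1)
  s <- sin(2 * pi * 2 * t)
  expect_equal(zero_crossing_frequency(s, 10), 2.0, tolerance = 0.05)
  expect_equal(zero_crossing_frequency(rep(4, 20), 10), 0)
  expect_equal(zero_crossing_frequency(5 * s, 10),
               zero_crossing_frequency(s, 10))
  expect_error(zero_crossing_frequency(1, 10), "at least 2")
})

test_that("pellet palatability shifts the burst frequency by the factor table", {
  f2 <- fluctuation_frequency(triaxial_sum(generate_trial(
    trial_config(pellet = "2#", seed = 21), noiseless_params())))
  f4 <- fluctuation_frequency(triaxial_sum(generate_trial(
    trial_config(pellet = "4#", seed = 21), noiseless_params())))
  expect_equal(f4 / f2, 0.58, tolerance = 0.05)
})

test_that("the simulated size experiment recovers the published slope", {
  chr <- characterize_experiment("size", replicates = 6, seed = 400)
  expect_equal(chr$fit$slope, 1.7316, tolerance = 0.05 * 1.7316)
  expect_equal(chr$percent_increase_top_vs_bottom, 109.7, tolerance = 12)
  expect_equal(chr$summary$n, rep(6, 3))
})

test_that("rate and pellet experiments report timing and frequency shifts", {
  rate <- characterize_experiment("rate", replicates = 2, seed = 41)
  expect_true(all(diff(rate$summary$mean_peak_time_s) < 0))
  pellet <- characterize_experiment("pellet", replicates = 2, seed = 42)
  expect_lt(pellet$summary$mean_freq_hz[2],
            pellet$summary$mean_freq_hz[1])
})
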
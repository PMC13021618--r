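test_that("group-mean calibration solves the line + ratio system", {
  # independent oracle: lm() refit of the solved means must return the
  # published coefficients, and the ratio constraint must hold exactly
  mu <- calibrate_group_means(c(50, 150, 300), 1.7316, 236.41, 2.097)
  expect_equal(unname(mu), c(377.9282, 404.5863, 792.5155), tolerance = 1e-6)
  refit <- stats::lm(mu ~ l, data.frame(l = c(50, 150, 300)))
  expect_equal(unname(coef(refit)), c(236.41, 1.7316), tolerance = 1e-9)
  expect_equal(mu[[3]] / mu[[1]], 2.097, tolerance = 1e-12)

  mu2 <- calibrate_group_means(c(20, 40, 60), 5.4250, 47.11, 2.419)
  expect_equal(unname(mu2), c(152.9246, 269.4808, 369.9246), tolerance = 1e-6)
  refit2 <- stats::lm(mu2 ~ l, data.frame(l = c(20, 40, 60)))
  expect_equal(unname(coef(refit2)), c(47.11, 5.4250), tolerance = 1e-9)
})

test_that("a line-consistent ratio puts the means exactly on the line", {
  lv <- c(10, 20, 30)
  slope <- 2; intercept <- 5
  ratio <- (intercept + slope * 30) / (intercept + slope * 10)
  mu <- calibrate_group_means(lv, slope, intercept, ratio)
  expect_equal(unname(mu), intercept + slope * lv, tolerance = 1e-10)
})

test_that("calibration rejects malformed systems", {
  expect_error(calibrate_group_means(c(1, 1, 2), 1, 0, 2), "distinct")
  expect_error(calibrate_group_means(c(1, 2, 3), 1, 0, -2), "> 0")
})

test_that("one-factor loadings reproduce their correlation targets", {
  w <- factor_loadings(0.93, 0.88, 0.91)
  expect_equal(unname(w), c(0.94834, 0.98066, 0.92795), tolerance = 1e-4)
  expect_equal(w[["w_y"]] * w[["w_z"]], 0.91, tolerance = 1e-12)
  expect_equal(unname(factor_loadings(1, 1, 1)), c(1, 1, 1))
  expect_equal(unname(factor_loadings(0.81, 0.81, 0.81)), rep(0.9, 3))
  expect_error(factor_loadings(0.9, 0.2, 0.9), "exceeds 1")
  expect_error(factor_loadings(0, 0.5, 0.5), "\\(0, 1\\]")
})

test_that("peak time declines linearly with feed rate and clamps", {
  expect_equal(peak_time_model(3), 20)
  expect_equal(peak_time_model(1), 35)
  expect_equal(peak_time_model(2), 27.5)
  expect_equal(peak_time_model(10), 5)              # lower clamp
  expect_equal(peak_time_model(0.1, duration_s = 40), 35)  # upper clamp
  expect_error(peak_time_model(0), "> 0")
})

test_that("expected peaks honor per-experiment profiles and combine otherwise", {
  expect_equal(mean_peak(trial_config(size_g = 300, density = 30,
                                      feed_rate = 1)),
               792.5155, tolerance = 1e-4)
  expect_equal(mean_peak(trial_config(size_g = 50, density = 60,
                                      feed_rate = 1)),
               369.9246, tolerance = 1e-4)
  expect_equal(mean_peak(trial_config(size_g = 50, density = 30,
                                      feed_rate = 1)),
               377.9282, tolerance = 1e-4)
  # feed rate does not move the expected amplitude
  expect_equal(mean_peak(trial_config(size_g = 300, density = 30,
                                      feed_rate = 3)),
               mean_peak(trial_config(size_g = 300, density = 30,
                                      feed_rate = 1)))
  expect_warning(mean_peak(trial_config(size_g = 1000, density = 30,
                                        feed_rate = 2)),
                 "clamped")
})
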
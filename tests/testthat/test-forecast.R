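test_that("supervised window counts follow the sliding contract", {
  mk <- function(n) {
    tr <- generate_trial(trial_config(duration_s = n / 10, seed = 1),
                         noiseless_params())
    tr
  }
  expect_equal(dim(build_supervised(mk(600), stride = 1, seed = 1)$x)[1], 501)
  expect_equal(dim(build_supervised(mk(100), stride = 1, seed = 1)$x)[1], 1)
  expect_equal(dim(build_supervised(mk(600), stride = 50, seed = 1)$x)[1], 11)
  expect_warning(
    expect_error(build_supervised(mk(50), stride = 1, seed = 1), "no trial"),
    "skipped")
})

test_that("targets follow the context with no gap", {
  tr <- generate_trial(trial_config(seed = 4), noiseless_params())
  s <- triaxial_sum(tr, synthetic_filter_threshold())  # same gate as below
  sup <- build_supervised(tr, stride = 37, seed = 1)
  expect_equal(sup$y[1], sum(s[51:100]))
  expect_equal(sup$x[1, , "s"], unname(s[1:50]))
  traj <- build_supervised(tr, stride = 37, mode = "trajectory", seed = 1)
  expect_equal(traj$y[1, ], unname(s[51:100]))
  expect_equal(ncol(traj$y), 50)
})

test_that("normalization statistics come from the training split only", {
  tr <- lapply(1:2, function(i) generate_trial(trial_config(seed = i)))
  sup <- build_supervised(tr, stride = 20, seed = 3)
  flat_train <- matrix(sup$x[sup$is_train, , , drop = FALSE], ncol = 6)
  expect_equal(unname(sup$feature_stats$mean[1]), mean(flat_train[, 1]))
  flat_all <- matrix(sup$x, ncol = 6)
  expect_false(isTRUE(all.equal(unname(sup$feature_stats$mean[1]),
                                mean(flat_all[, 1]))))
})

test_that("a small LSTM overfits one noiseless trial", {
  tr <- generate_trial(trial_config(seed = 3), noiseless_params())
  sup <- build_supervised(tr, stride = 6, seed = 1)
  fit <- train_forecaster(sup, model_config("lstm", units = 16,
                                            dense_units = 8, dropout = 0),
                          train_config(max_epochs = 40, patience = 40,
                                       seed = 1))
  m <- evaluate_forecaster(fit, sup, "train")
  # final train MSE below 1% of the target variance
  expect_gt(m$r_squared, 0.99)
})

test_that("training is deterministic and early stopping engages", {
  tr <- generate_trial(trial_config(seed = 6), noiseless_params())
  sup <- build_supervised(tr, stride = 15, seed = 2)
  cfg <- model_config("gru", units = 6, dense_units = 4)
  one <- suppressWarnings(
    train_forecaster(sup, cfg, train_config(max_epochs = 2, seed = 7)))
  two <- suppressWarnings(
    train_forecaster(sup, cfg, train_config(max_epochs = 2, seed = 7)))
  expect_identical(one$history, two$history)
  expect_identical(one$net$params, two$net$params)

  stopped <- suppressWarnings(
    train_forecaster(sup, cfg, train_config(max_epochs = 100, patience = 3,
                                            seed = 7)))
  expect_lt(nrow(stopped$history), 100)
  expect_equal(min(stopped$history$val_mse),
               stopped$history$val_mse[stopped$best_epoch])
})

test_that("prediction is batch-invariant and shape-checked", {
  tr <- generate_trial(trial_config(seed = 8), noiseless_params())
  sup <- build_supervised(tr, stride = 25, seed = 2)
  fit <- suppressWarnings(
    train_forecaster(sup, model_config("lstm", units = 4, dense_units = 3),
                     train_config(max_epochs = 1, seed = 1)))
  batched <- predict(fit, sup$x)
  single <- vapply(seq_len(dim(sup$x)[1]), function(i) {
    predict(fit, sup$x[i, , ])
  }, numeric(1))
  expect_equal(batched, single)
  expect_error(predict(fit, sup$x[, 1:10, ]), "shape mismatch")
})

test_that("metric formulas match the closed-form example and rmse >= mae", {
  m <- vibrofeed:::.forecast_metrics(c(1, 2, 4), c(1, 2, 3))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-6)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-6)
  expect_equal(m$r_squared, 0.5)
  expect_error(vibrofeed:::.forecast_metrics(1:3, rep(2, 3)),
               "zero target variance")
  set.seed(31)
  for (i in 1:20) {
    mm <- vibrofeed:::.forecast_metrics(rnorm(30), rnorm(30))
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("perfect and mean-constant predictors bound the metrics", {
  y <- c(1, 5, 3, 8)
  perfect <- vibrofeed:::.forecast_metrics(y, y)
  expect_equal(c(perfect$rmse, perfect$mae, perfect$r_squared), c(0, 0, 1))
  const <- vibrofeed:::.forecast_metrics(rep(mean(y), 4), y)
  expect_equal(const$r_squared, 0)
})

test_that("architecture comparison shares data and reports one row per run", {
  tr <- generate_trial(trial_config(seed = 10), noiseless_params())
  sup <- build_supervised(tr, stride = 30, seed = 5)
  tab <- suppressWarnings(compare_architectures(sup, seeds = c(1, 2),
                               model_args = list(units = 4, dense_units = 3,
                                                 d_model = 6, ff_dim = 8),
                               train_cfg = train_config(max_epochs = 1)))
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$arch), c("lstm", "gru", "transformer"))
  expect_named(tab, c("arch", "seed", "rmse_um", "mae_um", "r2"))
})
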
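# Shared fixtures. Heavy objects (datasets, trained forecasters) are built
# once per test run and memoised here so the acceptance-level tests can
# share them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small deterministic trace for unit tests
tiny_trace <- function(n = 200, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / 10
  triaxial_trace(x = sin(t) + rnorm(n, sd = 0.1),
                 y = sin(t) + rnorm(n, sd = 0.1),
                 z = 0.5 * sin(t) + rnorm(n, sd = 0.1))
}

# the default 408-trial synthetic dataset (shared by forecaster and
# control acceptance tests)
default_dataset <- function() {
  fixture("dataset408", function() generate_dataset(master_seed = 7))
}

# scaled-down scalar-mode forecaster trained on the default dataset;
# problem sizes chosen to keep the suite runnable while preserving the
# reference architecture and optimizer configuration
scalar_forecaster <- function() {
  fixture("scalar_fc", function() {
    sup <- build_supervised(default_dataset(), stride = 10, seed = 7,
                            max_samples = 2500)
    fit <- train_forecaster(sup, model_config("lstm"),
                            train_config(max_epochs = 6, patience = 6,
                                         seed = 101))
    list(sup = sup, fit = fit)
  })
}

# trajectory-mode forecaster for the closed-loop tests
trajectory_forecaster <- function() {
  fixture("traj_fc", function() {
    sup <- build_supervised(default_dataset(), stride = 25,
                            mode = "trajectory", seed = 7,
                            max_samples = 1500)
    fit <- train_forecaster(sup, model_config("lstm"),
                            train_config(max_epochs = 24, patience = 24,
                                         seed = 202))
    list(sup = sup, fit = fit)
  })
}

# mock forecasters with scripted trajectory predictions, for controller
# cadence tests that must not depend on training
mock_forecaster <- function(traj) {
  structure(list(mode = "trajectory", context_len = 50L, traj = traj),
            class = c("mock_forecaster", "feed_forecaster"))
}

predict.mock_forecaster <- function(object, newdata, ...) {
  matrix(object$traj, nrow = 1)
}
registerS3method("predict", "mock_forecaster", predict.mock_forecaster)
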
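test_that("decline detection follows the strict half-mean rule", {
  expect_true(detect_decline(c(rep(100, 25), rep(89, 25))))
  expect_false(detect_decline(c(rep(100, 25), rep(90, 25))))  # boundary
  expect_false(detect_decline(rep(0, 50)))                    # 0 < 0 false
  expect_true(detect_decline(seq(100, 2, length.out = 50)))
  expect_false(detect_decline(seq(2, 100, length.out = 50)))
  expect_error(detect_decline(rep(1, 49)), "exactly 50")
})

test_that("the stop logic counts consecutive declines and resets", {
  cfg <- controller_config()
  down <- c(rep(100, 25), rep(50, 25))
  up <- c(rep(50, 25), rep(100, 25))
  st <- controller_init(cfg)

  r1 <- controller_step(st, down, cfg)
  expect_equal(r1$state$decline_count, 1)
  expect_equal(r1$command, "maintain")
  r2 <- controller_step(r1$state, down, cfg)
  expect_equal(r2$command, "stop")
  expect_true(r2$state$stopped)

  # decline, recovery, decline: count resets, still maintaining
  s <- controller_init(cfg)
  for (pred in list(down, up, down)) s <- controller_step(s, pred, cfg)$state
  expect_false(s$stopped)
  expect_equal(s$decline_count, 1)

  fresh <- controller_step(controller_init(cfg), up, cfg)
  expect_equal(fresh$command, "maintain")
  expect_equal(fresh$state$feeder_speed, 2.0)

  expect_warning(controller_step(r2$state, down, cfg), "already stopped")
})

test_that("exhaustive two-cycle decision table", {
  cfg <- controller_config()
  down <- c(rep(10, 25), rep(8, 25))
  up <- c(rep(10, 25), rep(10, 25))
  outcomes <- expand.grid(first = c(TRUE, FALSE), second = c(TRUE, FALSE))
  for (i in seq_len(nrow(outcomes))) {
    s <- controller_init(cfg)
    s <- controller_step(s, if (outcomes$first[i]) down else up, cfg)$state
    res <- controller_step(s, if (outcomes$second[i]) down else up, cfg)
    expect_equal(res$command == "stop",
                 outcomes$first[i] && outcomes$second[i])
  }
})

test_that("a stricter decline ratio never stops earlier", {
  set.seed(77)
  for (rep in 1:25) {
    preds <- lapply(1:8, function(i) abs(rnorm(50, mean = 5, sd = 3)))
    stop_at <- function(ratio) {
      cfg <- controller_config(decline_ratio = ratio)
      s <- controller_init(cfg)
      for (i in seq_along(preds)) {
        r <- controller_step(s, preds[[i]], cfg)
        s <- r$state
        if (r$command == "stop") return(i)
      }
      Inf
    }
    expect_gte(stop_at(0.8), stop_at(0.95))
  }
})

test_that("monotonically increasing prediction streams never stop", {
  cfg <- controller_config()
  s <- controller_init(cfg)
  for (i in 1:20) {
    r <- controller_step(s, seq(i, i + 5, length.out = 50), cfg)
    s <- r$state
    expect_equal(r$command, "maintain")
  }
})

test_that("proportional output clamps, scales and rounds half up", {
  expect_equal(proportional_output(800, 800), 255L)
  expect_equal(proportional_output(0, 800), 0L)
  expect_equal(proportional_output(400, 800, 255L), 128L)
  expect_equal(proportional_output(1000, 800), 255L)
  expect_error(proportional_output(10, 0), "> 0")
})

test_that("residual feed rate matches hand arithmetic", {
  expect_equal(rfr(0, 50), 0)
  expect_equal(rfr(1, 100), 1)
  expect_equal(rfr(4.25, 64.6), 6.58, tolerance = 1e-3)
  expect_error(rfr(1, 0), "> 0")
  expect_error(rfr(-1, 10), ">= 0")
})

test_that("the tank surrogate conserves feed mass", {
  set.seed(9)
  tank <- tank_model(300, 30)
  delivered_total <- 0
  for (i in 1:300) {
    d <- runif(1, 0, 0.3)
    delivered_total <- delivered_total + d
    tank <- tank_step(tank, d, 0.1)
    expect_equal(tank$consumed + tank$pending, delivered_total,
                 tolerance = 1e-10)
    expect_gte(tank$appetite, 0)
    expect_lte(tank$appetite, 1)
  }
})

test_that("satiated and hungry limits behave as expected", {
  sated <- tank_model(capacity = 10, max_intake_rate = 5)
  sated$consumed <- 10; sated$appetite <- 0
  sated <- tank_step(sated, 2, 0.1)
  expect_equal(sated$pending, 2)      # nothing eaten

  hungry <- tank_model(capacity = 1e9, max_intake_rate = 5)
  for (i in 1:50) hungry <- tank_step(hungry, 0.2, 0.1)
  expect_equal(hungry$pending, 0)     # intake keeps pace with delivery
})

test_that("a steadily declining mock forecast stops after two cycles", {
  mock <- mock_forecaster(seq(100, 2, length.out = 50))
  ses <- simulate_session(mock, seed = 1, max_duration = 30)
  expect_equal(ses$stop_time, 9.9, tolerance = 0.2)   # two 5-s cycles
  expect_equal(ses$total_fed, 20, tolerance = 0.5)    # 2 g/s for ~10 s
  expect_equal(ses$total_fed, ses$tank$consumed + ses$tank$pending,
               tolerance = 1e-9)
})

test_that("a never-declining mock forecast times out with a warning", {
  mock <- mock_forecaster(seq(2, 100, length.out = 50))
  expect_warning(ses <- simulate_session(mock, seed = 2, max_duration = 20),
                 "max duration")
  expect_true(is.na(ses$stop_time))
})

test_that("cadence mismatches are rejected", {
  mock <- mock_forecaster(rep(1, 50))
  expect_error(
    simulate_session(mock, ctrl_cfg = controller_config(buffer_len = 40),
                     seed = 1),
    "cadence mismatch")
})
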
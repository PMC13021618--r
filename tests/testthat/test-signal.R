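test_that("amplitude filter zeroes sub-threshold samples and nothing else", {
  expect_equal(amplitude_filter(c(-300, 700, -900, 200), 500),
               c(0, 700, -900, 0))
  expect_equal(amplitude_filter(rep(0, 5), 500), rep(0, 5))
  x <- c(-2, 0.4, 3, -0.1)
  expect_equal(amplitude_filter(x, 0), x)
  expect_error(amplitude_filter(c(1, NA, 2), 10), "signal-quality")
  expect_error(amplitude_filter(c(1, Inf), 10), "signal-quality")
})

test_that("filter is idempotent and monotone in the threshold", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(100, sd = 500)
    thr <- runif(1, 0, 800)
    once <- amplitude_filter(x, thr)
    expect_identical(amplitude_filter(once, thr), once)
    higher <- amplitude_filter(x, thr + runif(1, 0, 500))
    expect_true(all(abs(higher) <= abs(once)))
  }
})

test_that("triaxial sum filters per axis before summing magnitudes", {
  tr <- triaxial_trace(x = 1, y = -2, z = 3)
  expect_equal(triaxial_sum(tr, 0), 6)
  expect_equal(triaxial_sum(triaxial_trace(0, 0, 0), 0), 0)
  tr2 <- triaxial_trace(x = 600, y = -300, z = 0)
  expect_equal(triaxial_sum(tr2, 500), 600)
  expect_error(triaxial_trace(1:3, 1:2, 1:3), "structural")
})

test_that("window sums follow the non-overlapping floor-division contract", {
  ws <- window_sums(rep(1, 100), 50)
  expect_equal(ws$d_sum, c(50, 50))
  expect_equal(ws$h_max, c(1, 1))
  expect_equal(ws$window_start_times, c(0, 5))

  expect_length(window_sums(rep(1, 120), 50)$d_sum, 2)

  spike <- c(rep(0, 49), 10)
  ws3 <- window_sums(spike, 50)
  expect_equal(ws3$d_sum, 10)
  expect_equal(ws3$h_max, 10)

  expect_warning(empty <- window_sums(rep(1, 10), 50), "shorter")
  expect_length(empty$d_sum, 0)
})

test_that("window sums conserve mass against a brute-force oracle", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(50:400, 1)
    len <- sample(c(1L, 10L, 50L), 1)
    s <- abs(rnorm(n))
    ws <- window_sums(s, len)
    k <- n %/% len
    # brute force: per-window loop
    oracle <- vapply(seq_len(k), function(j) {
      sum(s[((j - 1) * len + 1):(j * len)])
    }, numeric(1))
    expect_equal(ws$d_sum, oracle)
    expect_equal(sum(ws$d_sum), sum(s[seq_len(k * len)]))
    expect_true(all(ws$d_sum >= ws$h_max - 1e-12))
    expect_true(all(ws$h_max >= 0))
  }
})

test_that("unit windows reduce to the identity", {
  s <- abs(rnorm(30))
  ws <- window_sums(s, 1)
  expect_equal(ws$d_sum, s)
  expect_equal(ws$h_max, s)
})

test_that("inter-axis correlation handles exact, null and degenerate cases", {
  x <- rnorm(50)
  tr <- triaxial_trace(x, x, rnorm(50))
  expect_equal(interaxis_correlation(tr)$rho_xy, 1.0)

  # Monte-Carlo oracle: independent white noise decorrelates at n = 1e5
  set.seed(123)
  big <- triaxial_trace(rnorm(1e5), rnorm(1e5), rnorm(1e5))
  rho <- interaxis_correlation(big)
  expect_lt(abs(rho$rho_xy), 0.02)
  expect_lt(abs(rho$rho_xz), 0.02)

  expect_error(interaxis_correlation(triaxial_trace(rep(1, 10), rnorm(10),
                                                    rnorm(10))),
               "zero-variance")
  expect_error(interaxis_correlation(triaxial_trace(1:2, 1:2, 1:2)),
               "at least 3")
})

test_that("trace constructor validates time spacing", {
  expect_error(triaxial_trace(1:5, 1:5, 1:5, time = c(0, 1, 2, 3, 3.5)),
               "spacing")
  tr <- triaxial_trace(1:5, 1:5, 1:5, time = (0:4) / 10)
  expect_equal(tr$time, c(0, 0.1, 0.2, 0.3, 0.4))
})
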
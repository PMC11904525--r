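# Cleaning chain: reliability rule, interpolation, resampling, detrending.

test_that("reliability rule: flags dominate, threshold is inclusive", {
  raw <- make_raw(c(0, 0.1, 0.2, 0.3), 100,
                  confidence = c(0.79, 0.95, 0.8, 0.81),
                  blink = c(0L, 1L, 0L, 0L), artifact = c(0L, 0L, 0L, 1L))
  m <- mask_unreliable(raw)
  expect_identical(m$reliable, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("interpolation bridges gaps at the midpoint and extends edges", {
  raw <- make_raw(0:4, c(50, 100, 999, 102, 70),
                  confidence = c(0.2, 1, 0.3, 1, 0.5))
  f <- interpolate_gaps(mask_unreliable(raw))
  expect_equal(f$diameter, c(100, 100, 101, 102, 102))  # midpoint + constant ends
  expect_identical(f$interp, c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("interpolation is the identity on fully reliable input", {
  raw <- make_raw(seq(0, 2, by = 0.1), rnorm(21, 100))
  f <- interpolate_gaps(mask_unreliable(raw))
  expect_identical(f$diameter, raw$diameter)
  expect_false(any(f$interp))
})

test_that("interpolation reconstructs a linear ramp exactly", {
  withr::local_seed(42)
  t <- seq(0, 10, by = 0.016)
  ramp <- 90 + 1.7 * t
  conf <- rep(1, length(t))
  drop <- sample(2:(length(t) - 1), 150)
  conf[drop] <- 0.1
  raw <- make_raw(t, ramp + ifelse(conf < 0.8, 50, 0), confidence = conf)
  f <- interpolate_gaps(mask_unreliable(raw))
  expect_equal(f$diameter, ramp, tolerance = 1e-9)
})

test_that("fewer than two reliable samples is a hard error", {
  raw <- make_raw(0:3, 100, confidence = c(1, 0.1, 0.1, 0.1))
  expect_error(interpolate_gaps(mask_unreliable(raw)), "2 reliable")
})

test_that("resampling: constant input, grid length, and mask propagation", {
  withr::local_seed(1)
  t <- cumsum(runif(300, 0.012, 0.020))
  raw <- make_raw(t, 100)
  cs <- resample_50hz(interpolate_gaps(mask_unreliable(raw)))
  expect_equal(cs$rate, 50)
  expect_true(all(abs(cs$values - 100) < 1e-12))
  expect_identical(length(cs$values), as.integer(floor((t[300] - t[1]) * 50) + 1))

  conf <- rep(1, 300); conf[100:110] <- 0.2
  raw2 <- make_raw(t, 100, confidence = conf)
  cs2 <- resample_50hz(interpolate_gaps(mask_unreliable(raw2)))
  grid_t <- cs2$t0 + (seq_along(cs2$values) - 1) / 50
  # every grid point with a masked flanking source sample is masked
  covered <- grid_t >= t[99] & grid_t <= t[111]
  expect_true(all(cs2$interp_mask[covered]))
  expect_false(any(cs2$interp_mask[grid_t < t[98] | grid_t > t[112]]))
})

test_that("resampling error stays below the linear-interpolation bound for a sine", {
  withr::local_seed(2)
  t <- cumsum(runif(600, 0.012, 0.020))
  f <- 1.3  # Hz
  raw <- make_raw(t, 100 + 5 * sin(2 * pi * f * t))
  cs <- resample_50hz(interpolate_gaps(mask_unreliable(raw)))
  grid_t <- cs$t0 + (seq_along(cs$values) - 1) / 50
  truth <- 100 + 5 * sin(2 * pi * f * grid_t)
  bound <- max(diff(t))^2 * 5 * (2 * pi * f)^2 / 8
  expect_lt(max(abs(cs$values - truth)), bound + 1e-12)
})

test_that("detrending removes a pure line and preserves the mean", {
  n <- 1000
  v <- 7 + 0.03 * (seq_len(n) - 1) / 50
  cs <- clean_series(0, 50, v, logical(n))
  d <- detrend_preserve_mean(cs)
  expect_equal(d$values, rep(mean(v), n), tolerance = 1e-9)

  # trend-free input is unchanged; OLS oracle confirms zero residual slope
  sine <- sin(2 * pi * (seq_len(n) - 1) / 50 / 7)
  cs2 <- detrend_preserve_mean(clean_series(0, 50, 100 + sine + 0.05 * (seq_len(n) - 1) / 50,
                                            logical(n)))
  tt <- (seq_len(n) - 1) / 50
  fit <- lm(cs2$values ~ tt)
  expect_lt(abs(coef(fit)[2]), 1e-9)
  expect_equal(detrend_preserve_mean(cs2)$values, cs2$values, tolerance = 1e-9)
})

test_that("preprocessing its own output is the identity", {
  sub <- simulate_session(fast_config(seed = 6), "baseline")
  cs <- clean_pupil(sub$left)
  again <- make_raw(cs$t0 + (seq_along(cs$values) - 1) / 50, cs$values,
                    condition = "baseline")
  cs2 <- clean_pupil(again)
  expect_equal(cs2$values, cs$values, tolerance = 1e-9)
  expect_false(any(cs2$interp_mask))
})

test_that("mask fraction tracks the unreliable time share of the input", {
  s <- simulate_session(fast_config(seed = 13), "baseline")
  m <- interpolate_gaps(mask_unreliable(s$left))
  cs <- resample_50hz(m)
  # OR-propagation makes the grid mask conservative: at least the input
  # unreliable share, inflated by at most ~one grid sample per masked run
  expect_gte(mean(cs$interp_mask), mean(m$interp) - 1e-9)
  expect_lt(mean(cs$interp_mask) - mean(m$interp), 0.05)
})

test_that("the mask/interpolate stages are not interchangeable with resampling", {
  # resampling before interpolation lets unreliable values leak into the
  # grid; the canonical order does not
  t <- seq(0, 2, by = 1 / 62)
  conf <- rep(1, length(t)); conf[40:50] <- 0.1
  v <- rep(100, length(t)); v[40:50] <- 30  # blink-like dip
  raw <- make_raw(t, v, confidence = conf)
  canonical <- resample_50hz(interpolate_gaps(mask_unreliable(raw)))
  leaky <- make_raw(t, v)  # same values, mask ignored
  wrong <- resample_50hz(interpolate_gaps(mask_unreliable(leaky)))
  expect_gt(max(abs(canonical$values - wrong$values)), 1)
  expect_true(all(abs(canonical$values - 100) < 1e-9))
})
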
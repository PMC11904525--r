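# Pre-stimulus size regression: trial points, baseline control selection,
# centering, OLS and the two comparison tests.

pct_set <- function(m, pre_mean = NULL, ...) {
  frame_set(m, norm_mode = "percent", pre_mean = pre_mean %||% 100, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trial points are in-window means relative to 100 %", {
  m <- matrix(100, 2, 150)
  m[2, ] <- 102
  fs <- pct_set(m, pre_mean = c(90, 95))
  pts <- trial_points(fs)
  expect_equal(pts$pdr_pct, c(0, 2))
  expect_equal(pts$pre_px, c(90, 95))
  # brute-force window mean (samples with 1.0 <= k/50 < 1.5, 0-based)
  withr::local_seed(40)
  mr <- matrix(rnorm(4 * 150, 100, 3), 4, 150)
  oracle <- rowMeans(mr[, 51:75]) - 100
  expect_equal(trial_points(pct_set(mr))$pdr_pct, oracle, tolerance = 1e-12)
  expect_error(trial_points(frame_set(mr)), "percent")
})

test_that("baseline control selection is seeded, equally spaced, and bounded", {
  withr::local_seed(41)
  fs <- pct_set(matrix(rnorm(50 * 150, 100, 2), 50, 150))
  p1 <- baseline_control_points(fs, 20, seed = 7)
  p2 <- baseline_control_points(fs, 20, seed = 7)
  expect_identical(p1, p2)
  idx <- attr(p1, "indices")
  expect_identical(length(idx), 20L)
  expect_identical(anyDuplicated(idx), 0L)
  # arithmetic progression modulo pool: steps take at most two values,
  # the nominal spacing and one wrap-around
  steps <- diff(sort(idx))
  expect_lte(length(unique(steps)), 2L)
  expect_identical(as.integer(sort(table(steps), decreasing = TRUE)[1]) >= 17L, TRUE)
  expect_identical(p1$condition, rep("baseline_control", 20))

  expect_warning(all_pts <- baseline_control_points(fs, 60, seed = 1), "taking all")
  expect_identical(nrow(all_pts), 50L)
  full <- baseline_control_points(fs, 50, seed = 2)
  expect_identical(nrow(full), 50L)
})

test_that("subject centering zeroes pooled and per-subject means", {
  withr::local_seed(42)
  pts <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), times = c(10, 15, 5)),
    condition = "audio",
    pre_px = rnorm(30, 100, 10), pdr_pct = rnorm(30, 1, 0.5)
  )
  cc <- center_by_subject(pts)
  for (s in c("a", "b", "c")) {
    expect_equal(mean(cc$pre_px[cc$subject_id == s]), 0, tolerance = 1e-12)
    expect_equal(mean(cc$pdr_pct[cc$subject_id == s]), 0, tolerance = 1e-12)
  }
  expect_equal(mean(cc$pre_px), 0, tolerance = 1e-12)
  expect_equal(center_by_subject(cc), cc, tolerance = 1e-12)
})

test_that("OLS matches the normal-equation oracle", {
  withr::local_seed(43)
  x <- rnorm(60, 100, 8)
  y <- 2 - 0.04 * x + rnorm(60, 0, 0.4)
  pts <- tibble::tibble(subject_id = "a", condition = "audio",
                        pre_px = x, pdr_pct = y)
  fit <- ols_fit(pts)
  # normal equations by hand
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (60 - 2)
  expect_equal(fit$residual_var, s2, tolerance = 1e-10)
  expect_equal(fit$slope_se, sqrt(s2 / sum((x - mean(x))^2)), tolerance = 1e-10)
  expect_equal(fit$r, cor(x, y), tolerance = 1e-12)
})

test_that("OLS handles collinear and degenerate inputs", {
  pts <- tibble::tibble(subject_id = "a", condition = "audio",
                        pre_px = c(1, 2, 3, 4), pdr_pct = c(2, 4, 6, 8))
  fit <- suppressWarnings(ols_fit(pts))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(abs(fit$r), 1, tolerance = 1e-12)
  flat <- tibble::tibble(subject_id = "a", condition = "audio",
                         pre_px = c(1, 2, 3), pdr_pct = c(5, 5, 5))
  ffit <- suppressWarnings(ols_fit(flat))
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r, 0)
  expect_error(ols_fit(flat[1:2, ]), "at least 3")
  expect_error(ols_fit(tibble::tibble(subject_id = "a", condition = "audio",
                                      pre_px = c(1, 1, 1), pdr_pct = 1:3)),
               "variance")
})

test_that("slope-equality test equals the interaction-model oracle", {
  withr::local_seed(44)
  for (rep in 1:5) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    x1 <- rnorm(n1, 0, 2); y1 <- -0.3 * x1 + rnorm(n1, 0, 0.8)
    x2 <- rnorm(n2, 0, 2); y2 <- -0.1 * x2 + rnorm(n2, 0, 0.8)
    f1 <- ols_fit(tibble::tibble(subject_id = "a", condition = "audio",
                                 pre_px = x1, pdr_pct = y1))
    f2 <- ols_fit(tibble::tibble(subject_id = "a", condition = "b",
                                 pre_px = x2, pdr_pct = y2))
    cmp <- compare_slopes(f1, f2)
    joint <- lm(y ~ x * g,
                data = data.frame(x = c(x1, x2), y = c(y1, y2),
                                  g = rep(c(0, 1), c(n1, n2))))
    sj <- summary(joint)$coefficients["x:g", ]
    expect_equal(cmp$t, -unname(sj["t value"]), tolerance = 1e-10)
    expect_equal(cmp$p, unname(sj["Pr(>|t|)"]), tolerance = 1e-10)
    expect_identical(cmp$df, n1 + n2 - 4L)
    # antisymmetry in group order
    expect_equal(compare_slopes(f2, f1)$t, -cmp$t, tolerance = 1e-12)
  }
})

test_that("identical fits give a null slope comparison", {
  withr::local_seed(45)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30, 0, 0.2)
  f <- ols_fit(tibble::tibble(subject_id = "a", condition = "audio",
                              pre_px = x, pdr_pct = y))
  cmp <- compare_slopes(f, f)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
})

test_that("Fisher r-to-z comparison matches the closed form", {
  same <- compare_correlations(0.4, 50, 0.4, 80)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  cmp <- compare_correlations(0.5, 100, 0.0, 100)
  z_oracle <- (atanh(0.5) - atanh(0)) / sqrt(1 / 97 + 1 / 97)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-12)
  expect_lt(cmp$p, 0.001)
  flip <- compare_correlations(0.0, 100, 0.5, 100)
  expect_equal(flip$z, -cmp$z, tolerance = 1e-12)
  expect_error(compare_correlations(1, 10, 0.5, 10), "\\|r\\| < 1")
  expect_error(compare_correlations(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("the full regression wrapper recovers a negative audio slope in low noise", {
  cfg <- sim_config(seed = 46, noise_sd_px = 0.05)
  sub <- pdr_simulate_subject(cfg)
  reg <- suppressWarnings(regress_prestim(sub$audio, sub$baseline, seed = 3))
  expect_lt(reg$fit_audio$slope, 0)
  expect_lt(reg$fit_audio$slope, reg$fit_baseline$slope)
  expect_identical(reg$slope_test$df, reg$fit_audio$n + reg$fit_baseline$n - 4L)
  # centered points: pooled means are zero
  expect_equal(mean(reg$points$pre_px[reg$points$condition == "audio"]), 0,
               tolerance = 1e-9)
})
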
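# Signed areas, pooled t-test, subject detection, grand averages and the
# pre-stimulus diameter comparison.

pct_frames <- function(m, ...) {
  frame_set(m, norm_mode = "percent", pre_mean = 100, ...)
}

test_that("signed areas of constant traces are exact", {
  m <- matrix(100, 1, 150)
  fs <- pct_frames(m)
  expect_identical(signed_area(fs, c(0.5, 2.0)), 0)
  m2 <- matrix(102, 1, 150)
  expect_equal(signed_area(pct_frames(m2), c(0.5, 1.0)), 1.0, tolerance = 1e-12)
  m3 <- matrix(98, 1, 150)  # dips below reference count negatively
  expect_equal(signed_area(pct_frames(m3), c(0.5, 1.0)), -1.0, tolerance = 1e-12)
  expect_error(signed_area(fs, c(2.5, 3.5)), "outside")
  expect_error(signed_area(frame_set(m), c(0.5, 1)), "normalized")
})

test_that("signed area equals the brute-force half-open sample sum", {
  withr::local_seed(8)
  m <- matrix(rnorm(6 * 150, 100, 3), 6, 150)
  fs <- pct_frames(m)
  for (iv in list(c(0.5, 1), c(1, 1.5), c(1.5, 2), c(0.5, 2), c(0, 3))) {
    oracle <- apply(m, 1, function(v) {
      s <- 0
      for (k in 0:149) {
        if (k / 50 >= iv[1] && k / 50 < iv[2]) s <- s + (v[k + 1] - 100) / 50
      }
      s
    })
    expect_equal(signed_area(fs, iv), oracle, tolerance = 1e-12)
  }
})

test_that("full-window area is the exact sum of its three partitions", {
  withr::local_seed(9)
  fs <- pct_frames(matrix(rnorm(10 * 150, 100, 5), 10, 150))
  total <- signed_area(fs, c(0.5, 2))
  parts <- signed_area(fs, c(0.5, 1)) + signed_area(fs, c(1, 1.5)) +
    signed_area(fs, c(1.5, 2))
  expect_equal(total, parts, tolerance = 1e-12)
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  withr::local_seed(10)
  a <- rnorm(40, 0.3, 1.2); b <- rnorm(55, 0, 0.9)
  res <- pooled_t_test(a, b)
  # textbook pooled-variance arithmetic
  sp2 <- ((40 - 1) * var(a) + (55 - 1) * var(b)) / (40 + 55 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 40 + 1 / 55))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_identical(res$df, 93L)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("pooled t-test handles degenerate and separated samples", {
  expect_equal(pooled_t_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")], list(t = 0, p = 1))
  res <- pooled_t_test(1:5, 11:15)
  expect_lt(res$p, 1e-4)
  same <- pooled_t_test(rep(5, 4), rep(5, 6))
  expect_equal(same$p, 1)
  expect_warning(degen <- pooled_t_test(rep(5, 4), rep(6, 4)), "zero pooled variance")
  expect_equal(degen$p, 0)
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("a strong evoked response is detected over ~100 trials", {
  cfg <- sim_config(seed = 14, duration_s = 410, n_stimuli = 100L,
                    pdr_amp_pct = 3, noise_sd_px = 0.2,
                    adaptation_factors = c(1, 1, 1))
  sub <- pdr_simulate_subject(cfg)
  res <- detect_subject(sub$audio, sub$baseline)
  expect_true(res$any_significant)
  expect_identical(res$results$df, res$results$n_audio + res$results$n_baseline - 2L)
  full <- res$results[res$results$start_s == 0.5 & res$results$end_s == 2, ]
  expect_lt(full$p, 0.001)
  expect_gt(full$area_audio, full$area_baseline)
})

test_that("detection is invariant to frame order and eye relabeling", {
  withr::local_seed(15)
  a <- pct_frames(matrix(rnorm(30 * 150, 100.5, 2), 30, 150))
  b <- pct_frames(matrix(rnorm(30 * 150, 100, 2), 30, 150))
  r1 <- detect_subject(a, b)
  perm <- sample(30)
  a2 <- a; a2$values <- a$values[perm, ]; a2$info <- a$info[perm, ]
  a2$info$eye <- rep(c("right", "left"), 15)
  r2 <- detect_subject(a2, b)
  expect_equal(r1$results, r2$results, tolerance = 1e-12)
})

test_that("percent and difference modes give identical t when pre-means agree", {
  withr::local_seed(16)
  raw_a <- frame_set(matrix(rnorm(20 * 150, 80, 1.5), 20, 150))
  raw_b <- frame_set(matrix(rnorm(25 * 150, 80, 1.5), 25, 150))
  # force equal pre-stimulus means across all frames
  raw_a$values <- raw_a$values - (raw_a$info$pre_mean - 80)
  raw_a$info$pre_mean <- rep(80, 20)
  raw_b$values <- raw_b$values - (raw_b$info$pre_mean - 80)
  raw_b$info$pre_mean <- rep(80, 25)
  r_pct <- detect_subject(normalize_frames(raw_a, "percent"),
                          normalize_frames(raw_b, "percent"))
  r_dif <- detect_subject(normalize_frames(raw_a, "difference"),
                          normalize_frames(raw_b, "difference"))
  expect_equal(r_pct$results$t, r_dif$results$t, tolerance = 1e-9)
  expect_equal(r_pct$results$p, r_dif$results$p, tolerance = 1e-9)
})

test_that("percent and difference decisions agree on most null subjects", {
  agree <- numeric(40)
  for (k in 1:40) {
    cfg <- fast_config(seed = 1000 + k, pdr_amp_pct = 0)
    sa <- simulate_session(cfg, "audio")
    sb <- simulate_session(cfg, "baseline")
    mk <- function(sess, sched) {
      sets <- lapply(list(sess$left, sess$right), function(raw) {
        baseline_frames(clean_pupil(raw), sched)
      })
      qc_filter(pool_frames(sets))
    }
    fa <- mk(sa, sa$schedule); fb <- mk(sb, sb$schedule)
    dp <- detect_subject(normalize_frames(fa, "percent"),
                         normalize_frames(fb, "percent"))$results$significant
    dd <- detect_subject(normalize_frames(fa, "difference"),
                         normalize_frames(fb, "difference"))$results$significant
    agree[k] <- mean(dp == dd)  # per-interval decision agreement
  }
  expect_gte(mean(agree), 0.95)
})

test_that("grand averages pool frames with exact mean bookkeeping", {
  withr::local_seed(17)
  m1 <- matrix(rnorm(8 * 150, 101, 2), 8, 150)
  m2 <- matrix(rnorm(12 * 150, 100, 2), 12, 150)
  b1 <- matrix(rnorm(9 * 150, 100, 2), 9, 150)
  ga <- grand_average(list(pct_frames(m1), pct_frames(m2)),
                      pct_frames(b1))
  expect_identical(ga$n_audio, 20L)
  expect_identical(ga$n_baseline, 9L)
  # pooled mean equals the frame-count-weighted mean of per-set means
  expect_equal(ga$trace$mean_audio,
               (8 * colMeans(m1) + 12 * colMeans(m2)) / 20, tolerance = 1e-12)
  one <- suppressWarnings(grand_average(pct_frames(m1[1, , drop = FALSE]),
                                        pct_frames(b1)))
  expect_equal(one$trace$mean_audio, m1[1, ], tolerance = 1e-12)
  expect_true(all(one$trace$se_audio == 0))
  expect_error(grand_average(list(), pct_frames(b1)), "no frame sets")
})

test_that("paired pre-stimulus diameter comparison matches the paired-t oracle", {
  tbl <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    luminance = rep(c("LL", "HL"), 4),
    pre_px = c(98, 70, 110, 75, 95, 62, 101, 68)
  )
  res <- prestim_diameter_compare(tbl)
  ll <- tbl$pre_px[tbl$luminance == "LL"]; hl <- tbl$pre_px[tbl$luminance == "HL"]
  d <- ll - hl
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_identical(res$df, 3)
  expect_equal(res$mean_ll, mean(ll))
  same <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
                         luminance = rep(c("LL", "HL"), 2),
                         pre_px = c(90, 90, 80, 80))
  expect_equal(prestim_diameter_compare(same)$p, 1)
  expect_error(prestim_diameter_compare(tbl[1:2, ]), "at least 2")
})
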
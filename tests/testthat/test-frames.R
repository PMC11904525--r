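# Frame segmentation, QC, normalization and block labels.

test_that("frame windows start at the grid sample at or before onset - 0.5 s", {
  cs <- index_series()
  fs <- extract_frames(cs, event_table(10))
  expect_identical(n_frames(fs), 1L)
  expect_equal(fs$values[1, ], 475:624)  # 0-based sample indices
  expect_equal(fs$info$pre_mean[1], mean(475:499))
})

test_that("onsets with incomplete windows are dropped and logged", {
  cs <- index_series(n = 400)  # 8 s of grid
  expect_message(fs <- extract_frames(cs, event_table(c(0.3, 2, 7))), "dropped 2")
  expect_identical(fs$info$trial, 2L)  # trial index keeps schedule position
  expect_warning(extract_frames(cs, event_table(100)), "empty frame set")
})

test_that("a full-coverage generator session yields one frame per stimulus", {
  s <- simulate_session(noiseless_config(seed = 1), "audio")
  fs <- extract_frames(clean_pupil(s$left), s$events)
  expect_identical(n_frames(fs), nrow(s$events))
})

test_that("QC keeps frames at exactly the boundary and counts losses", {
  m <- matrix(100, 3, 150)
  fs <- frame_set(m, n_interp = c(0L, 15L, 16L))
  out <- qc_filter(fs)
  expect_identical(n_frames(out), 2L)
  expect_identical(out$info$n_interp, c(0L, 15L))
  expect_identical(out$qc$kept + out$qc$discarded, out$qc$extracted)
  clean <- qc_filter(frame_set(m))
  expect_identical(n_frames(clean), 3L)
  # idempotent
  expect_identical(qc_filter(out)$values, out$values)
})

test_that("normalization fixes the pre-stimulus mean at 100 % or 0", {
  m <- matrix(80, 2, 150)
  m[2, ] <- c(rep(100, 25), rep(101, 125))
  fs <- frame_set(m)
  pct <- normalize_frames(fs, "percent")
  expect_equal(rowMeans(pct$values[, 1:25]), c(100, 100), tolerance = 1e-9)
  expect_true(all(pct$values[1, ] == 100))
  expect_equal(pct$values[2, 26], 101)
  dif <- normalize_frames(fs, "difference")
  expect_equal(rowMeans(dif$values[, 1:25]), c(0, 0), tolerance = 1e-9)
  expect_equal(dif$values[2, 26], 1)
})

test_that("percent and difference modes obey the algebraic identity", {
  withr::local_seed(5)
  m <- matrix(rnorm(5 * 150, 100, 4), 5, 150)
  fs <- frame_set(m)
  pct <- normalize_frames(fs, "percent")
  dif <- normalize_frames(fs, "difference")
  pm <- fs$info$pre_mean
  expect_equal(pct$values, 100 + 100 * dif$values / pm, tolerance = 1e-12)
})

test_that("frames with non-positive pre-stimulus means are excluded from percent mode", {
  m <- matrix(100, 2, 150)
  m[2, 1:25] <- 0
  expect_message(out <- normalize_frames(frame_set(m), "percent"), "non-positive")
  expect_identical(n_frames(out), 1L)
})

test_that("block labels follow nominal trial order", {
  fs <- frame_set(matrix(100, 5, 150), trial = c(1L, 15L, 16L, 31L, 120L))
  fs <- assign_blocks(fs)
  expect_identical(fs$info$block, c(1L, 1L, 2L, 3L, 3L))
})

test_that("frame extraction is translation-equivariant", {
  s <- simulate_session(fast_config(seed = 21), "audio")
  cs <- clean_pupil(s$left)
  shift <- 3.137
  shifted <- s$left
  shifted$timestamp <- shifted$timestamp + shift
  cs2 <- clean_pupil(shifted)
  f1 <- extract_frames(cs, s$events$onset_s)
  f2 <- extract_frames(cs2, s$events$onset_s + shift)
  expect_equal(f2$values, f1$values, tolerance = 1e-9)
})

test_that("baseline windowing at the audio schedule matches audio windowing", {
  cs <- index_series()
  onsets <- c(5, 12, 20)
  fa <- extract_frames(cs, event_table(onsets))
  fb <- baseline_frames(cs, onsets)
  expect_identical(fb$values, fa$values)
  expect_warning(fb0 <- baseline_frames(index_series(n = 400), numeric(0)), NA)
  expect_identical(n_frames(fb0), 0L)
})

test_that("left and right eye frames of a trial share trial and block labels", {
  s <- simulate_session(fast_config(seed = 4), "audio")
  sets <- lapply(list(s$left, s$right), function(raw) {
    extract_frames(clean_pupil(raw), s$events)
  })
  pooled <- assign_blocks(pool_frames(sets))
  per_trial <- split(pooled$info$block, pooled$info$trial)
  expect_true(all(vapply(per_trial, function(b) length(unique(b)) == 1L, logical(1))))
  both_eyes <- split(pooled$info$eye, pooled$info$trial)
  expect_true(all(vapply(both_eyes, function(e) all(c("left", "right") %in% e), logical(1))))
})

test_that("eye averaging halves the observation count per complete trial", {
  s <- simulate_session(noiseless_config(seed = 2), "audio")
  sets <- lapply(list(s$left, s$right), function(raw) {
    extract_frames(clean_pupil(raw), s$events)
  })
  pooled <- pool_frames(sets, method = "pool")
  avg <- pool_frames(sets, method = "average")
  expect_identical(n_frames(avg), length(unique(pooled$info$trial)))
  tr <- pooled$info$trial == 1
  expect_equal(avg$values[1, ], colMeans(pooled$values[tr, , drop = FALSE]),
               tolerance = 1e-12)
})
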
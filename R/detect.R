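# Signed-area statistic and audio-vs-baseline pooled-variance t-tests, per
# subject and on grand averages.

#' Canonical post-stimulus analysis intervals
#'
#' Times are relative to frame start; the stimulus begins at 0.5 s.
#'
#' @return Tibble with `start_s`, `end_s` for the three 0.5-s partitions
#'   and the full 0.5-2.0 s window.
#' @export
pdr_intervals <- function() {
  tibble::tibble(start_s = c(0.5, 1.0, 1.5, 0.5),
                 end_s = c(1.0, 1.5, 2.0, 2.0))
}

# Sample indices (1-based) covered by the half-open interval [start, end):
# samples k (0-based) with start <= k/rate < end.
interval_index <- function(start_s, end_s, rate, n_samples) {
  if (!(start_s >= 0 && end_s > start_s && end_s <= n_samples / rate)) {
    stopf("interval [%g, %g) outside the frame", start_s, end_s)
  }
  k0 <- ceiling(start_s * rate - 1e-9)
  k1 <- ceiling(end_s * rate - 1e-9) - 1
  seq.int(k0, k1) + 1L
}

norm_reference <- function(fs) {
  switch(fs$norm_mode,
         percent = 100,
         difference = 0,
         stopf("frames must be normalized before computing areas (norm_mode is '%s')",
               fs$norm_mode))
}

#' Signed area between the pupil trace and its normalization reference
#'
#' For each frame, the rectangle-rule integral of the deviation from the
#' reference level (100 in percent mode, 0 in difference mode) over the
#' half-open interval: `sum(value - ref) / rate`. Segments below the
#' reference contribute negatively. The rectangle rule keeps sub-interval
#' additivity exact.
#'
#' @param fs A normalized `frame_set`.
#' @param interval Numeric `c(start_s, end_s)` relative to frame start.
#' @return Numeric vector, one signed area (unit x s) per frame.
#' @export
signed_area <- function(fs, interval) {
  ref <- norm_reference(fs)
  idx <- interval_index(interval[1], interval[2], fs$rate, fs$n_samples)
  rowSums(fs$values[, idx, drop = FALSE] - ref) / fs$rate
}

# Per-frame mean pupil size within the interval (reporting convention).
interval_means <- function(fs, interval) {
  idx <- interval_index(interval[1], interval[2], fs$rate, fs$n_samples)
  rowMeans(fs$values[, idx, drop = FALSE])
}

#' Unpaired pooled-variance (Student) t-test
#'
#' The classic two-sample t statistic with pooled variance and
#' `nA + nB - 2` degrees of freedom, two-tailed. Degenerate inputs with
#' zero pooled variance return `t = 0, p = 1` when the means agree and
#' `p = 0` with a warning otherwise.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p`, group means, SDs and sizes.
#' @export
pooled_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("both samples need at least 2 observations")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  if (sp2 <= 0) {
    if (ma == mb) {
      tt <- 0; p <- 1
    } else {
      warnf("zero pooled variance with unequal means")
      tt <- sign(ma - mb) * Inf; p <- 0
    }
  } else {
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(t = tt, df = df, p = p,
       mean_a = ma, mean_b = mb,
       sd_a = sqrt(va), sd_b = sqrt(vb),
       n_a = na, n_b = nb)
}

#' Detect pupil dilation responses in one subject
#'
#' For each analysis interval, compares the signed areas of audio frames
#' against baseline frames with an unpaired pooled-variance t-test
#' (`df = nA + nB - 2`). A subject shows a PDR (`any_significant`) when
#' any interval reaches `p < alpha`. Mean +/- SD of the in-interval pupil
#' size per condition is reported alongside.
#'
#' @param audio,baseline QC-filtered `frame_set`s normalized in the same
#'   mode.
#' @param intervals Tibble of intervals, see [pdr_intervals()].
#' @param alpha Significance level (default 0.05).
#' @return Object of class `pdr_result`: subject metadata, a per-interval
#'   results tibble and the `any_significant` flag.
#' @export
detect_subject <- function(audio, baseline, intervals = pdr_intervals(),
                           alpha = 0.05) {
  if (!identical(audio$norm_mode, baseline$norm_mode)) {
    stopf("audio and baseline frames must share the same normalization mode")
  }
  norm_reference(audio)  # errors on raw frames
  rows <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    iv <- c(intervals$start_s[i], intervals$end_s[i])
    if (n_frames(audio) < 2 || n_frames(baseline) < 2) {
      warnf("interval %g-%g s skipped: fewer than 2 frames on one side", iv[1], iv[2])
      next
    }
    tt <- pooled_t_test(signed_area(audio, iv), signed_area(baseline, iv))
    sa <- interval_means(audio, iv)
    sb <- interval_means(baseline, iv)
    rows[[i]] <- tibble::tibble(
      start_s = iv[1], end_s = iv[2],
      n_audio = tt$n_a, n_baseline = tt$n_b,
      mean_audio = mean(sa), sd_audio = stats::sd(sa),
      mean_baseline = mean(sb), sd_baseline = stats::sd(sb),
      area_audio = tt$mean_a, area_baseline = tt$mean_b,
      t = tt$t, df = tt$df, p = tt$p,
      significant = tt$p < alpha
    )
  }
  results <- dplyr::bind_rows(rows)
  any_sig <- if (nrow(results)) any(results$significant) else FALSE
  structure(
    list(subject_id = audio$subject_id, luminance = audio$luminance,
         norm_mode = audio$norm_mode, alpha = alpha, results = results,
         any_significant = any_sig),
    class = "pdr_result"
  )
}

#' @export
print.pdr_result <- function(x, ...) {
  cat(sprintf("<pdr_result> subject %s (%s), %s normalization, alpha = %g\n",
              x$subject_id, x$luminance, x$norm_mode, x$alpha))
  if (nrow(x$results)) {
    df <- x$results
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %.1f-%.1f s: nA=%d nB=%d  t=%+.2f df=%d p=%.4g%s\n",
                  df$start_s[i], df$end_s[i], df$n_audio[i], df$n_baseline[i],
                  df$t[i], df$df[i], df$p[i],
                  if (df$significant[i]) "  *" else ""))
    }
  }
  cat(sprintf("  PDR detected: %s\n", if (x$any_significant) "yes" else "no"))
  invisible(x)
}

#' Grand-average traces and interval tests over pooled frames
#'
#' Pools frames across subjects and eyes, computes per-sample mean and
#' standard error traces per condition, and runs the same interval
#' t-tests as [detect_subject()] on the pooled frames, with `nA` and `nB`
#' the total pooled frame counts.
#'
#' @param audio_sets,baseline_sets A `frame_set` or list of `frame_set`s
#'   per condition.
#' @param intervals,alpha As in [detect_subject()].
#' @return Object of class `pdr_grand_average`: `trace` tibble
#'   (`t_rel_s`, mean and SE per condition), `tests` tibble, counts and
#'   `any_significant`.
#' @export
grand_average <- function(audio_sets, baseline_sets,
                          intervals = pdr_intervals(), alpha = 0.05) {
  as_list <- function(x) if (inherits(x, "frame_set")) list(x) else x
  audio <- pool_frames(as_list(audio_sets))
  baseline <- pool_frames(as_list(baseline_sets))
  if (n_frames(audio) == 0 || n_frames(baseline) == 0) stopf("empty group")
  se <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
  trace <- tibble::tibble(
    t_rel_s = (seq_len(audio$n_samples) - 1) / audio$rate,
    mean_audio = colMeans(audio$values),
    se_audio = if (n_frames(audio) > 1) se(audio$values) else 0,
    mean_baseline = colMeans(baseline$values),
    se_baseline = if (n_frames(baseline) > 1) se(baseline$values) else 0
  )
  det <- detect_subject(audio, baseline, intervals = intervals, alpha = alpha)
  structure(
    list(trace = trace, tests = det$results,
         n_audio = n_frames(audio), n_baseline = n_frames(baseline),
         norm_mode = audio$norm_mode, alpha = alpha,
         any_significant = det$any_significant),
    class = "pdr_grand_average"
  )
}

#' @export
print.pdr_grand_average <- function(x, ...) {
  cat(sprintf("<pdr_grand_average> nA=%d audio, nB=%d baseline frames (%s)\n",
              x$n_audio, x$n_baseline, x$norm_mode))
  print(x$tests[, c("start_s", "end_s", "t", "df", "p", "significant")])
  invisible(x)
}

#' Compare pre-stimulus pupil diameters between luminance conditions
#'
#' Two-tailed paired t-test on per-subject mean pre-stimulus diameters
#' (px) for subjects recorded under both luminance levels, plus group
#' mean +/- SD per condition.
#'
#' @param pre_tbl Tibble with columns `subject_id`, `luminance`
#'   (`"LL"`/`"HL"`) and `pre_px` (that subject's mean pre-stimulus
#'   diameter under that condition, one row per subject x condition).
#' @return List of class `prestim_comparison` with per-condition summary
#'   statistics and the paired test.
#' @export
prestim_diameter_compare <- function(pre_tbl) {
  need <- c("subject_id", "luminance", "pre_px")
  miss <- setdiff(need, names(pre_tbl))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  wide <- dplyr::summarise(
    dplyr::group_by(pre_tbl, subject_id, luminance),
    pre_px = mean(pre_px), .groups = "drop"
  )
  ll <- wide[wide$luminance == "LL", c("subject_id", "pre_px")]
  hl <- wide[wide$luminance == "HL", c("subject_id", "pre_px")]
  both <- merge(ll, hl, by = "subject_id", suffixes = c("_ll", "_hl"))
  if (nrow(both) < 2) stopf("need at least 2 subjects tested under both luminances")
  d <- both$pre_px_ll - both$pre_px_hl
  if (stats::sd(d) == 0) {
    # degenerate paired data: identical conditions give t = 0, p = 1
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = nrow(both) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
    if (mean(d) != 0) warnf("zero variance of paired differences with nonzero mean")
  } else {
    tt <- stats::t.test(both$pre_px_ll, both$pre_px_hl, paired = TRUE)
  }
  structure(
    list(n_pairs = nrow(both),
         mean_ll = mean(both$pre_px_ll), sd_ll = stats::sd(both$pre_px_ll),
         mean_hl = mean(both$pre_px_hl), sd_hl = stats::sd(both$pre_px_hl),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value),
    class = "prestim_comparison"
  )
}

#' @export
print.prestim_comparison <- function(x, ...) {
  cat(sprintf("<prestim_comparison> %d paired subjects\n", x$n_pairs))
  cat(sprintf("  LL %.1f +/- %.1f px, HL %.1f +/- %.1f px; paired t(%d) = %.2f, p = %.3g\n",
              x$mean_ll, x$sd_ll, x$mean_hl, x$sd_hl, x$df, x$t, x$p))
  invisible(x)
}

#' Per-subject mean pre-stimulus diameter of a frame set
#'
#' @param fs A `frame_set` (any normalization; pre-stimulus means are kept
#'   in raw px).
#' @return Mean pre-stimulus diameter in px.
#' @export
mean_prestim_px <- function(fs) mean(fs$info$pre_mean)
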
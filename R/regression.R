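# Dependence of the evoked response on pre-stimulus pupil size: per-trial
# points, subject centering, OLS fits, slope-equality and correlation
# comparisons.

#' Per-trial points: evoked amplitude vs pre-stimulus size
#'
#' One point per kept frame: `pre_px` is the mean raw diameter of the
#' pre-stimulus samples (px, taken from the frame metadata so percent
#' normalization does not erase between-trial variation) and `pdr_pct` is
#' the mean percent deviation from 100 within the analysis interval
#' (default 1.0-1.5 s, around the response peak).
#'
#' @param fs A percent-normalized `frame_set`.
#' @param interval Analysis window `c(start_s, end_s)`.
#' @return Tibble with `subject_id`, `condition`, `trial`, `block`, `eye`,
#'   `pre_px`, `pdr_pct`.
#' @export
trial_points <- function(fs, interval = c(1.0, 1.5)) {
  if (!identical(fs$norm_mode, "percent")) {
    stopf("trial_points() requires percent-normalized frames")
  }
  tibble::tibble(
    subject_id = fs$subject_id,
    condition = fs$condition,
    trial = fs$info$trial,
    block = fs$info$block,
    eye = fs$info$eye,
    pre_px = fs$info$pre_mean,
    pdr_pct = interval_means(fs, interval) - 100
  )
}

#' Select equally spaced baseline control frames
#'
#' Picks `n_needed` frames from the baseline pool at equal index spacing
#' with a seeded random starting offset (an arithmetic progression modulo
#' the pool size), then converts them to trial points. If the pool is
#' smaller than `n_needed`, all frames are taken with a warning.
#'
#' @param fs Percent-normalized baseline `frame_set`.
#' @param n_needed Number of control frames to select.
#' @param seed Integer seed for the starting offset.
#' @param interval Analysis window passed to [trial_points()].
#' @return Tibble of trial points with `condition = "baseline_control"`
#'   and the selected frame indices as an attribute.
#' @export
baseline_control_points <- function(fs, n_needed, seed = 1L,
                                    interval = c(1.0, 1.5)) {
  pool <- n_frames(fs)
  if (pool < n_needed) {
    warnf("baseline pool (%d) smaller than requested (%d); taking all", pool, n_needed)
    idx <- seq_len(pool)
  } else {
    step <- max(1L, pool %/% n_needed)
    offset <- with_seed_(seed, sample.int(pool, 1L)) - 1L
    idx <- sort((offset + (seq_len(n_needed) - 1L) * step) %% pool) + 1L
  }
  pts <- trial_points(subset_frames(fs, idx), interval = interval)
  pts$condition <- "baseline_control"
  attr(pts, "indices") <- idx
  pts
}

#' Center trial points on individual subject means
#'
#' Within each subject and condition, subtracts that subject's mean
#' `pre_px` and `pdr_pct`, so points from different subjects can be pooled
#' without between-subject offsets driving the regression.
#'
#' @param points Tibble of trial points.
#' @return The centered tibble.
#' @export
center_by_subject <- function(points) {
  key <- interaction(points$subject_id, points$condition, drop = TRUE)
  points$pre_px <- points$pre_px - stats::ave(points$pre_px, key)
  points$pdr_pct <- points$pdr_pct - stats::ave(points$pdr_pct, key)
  points
}

#' Ordinary least-squares fit of evoked amplitude on pre-stimulus size
#'
#' @param points Tibble with `pre_px` (predictor) and `pdr_pct`
#'   (response), n >= 3 with non-degenerate predictor variance.
#' @return Object of class `pdr_fit`: `slope`, `intercept`, `r` (Pearson
#'   correlation), `n`, `slope_se`, `residual_var`.
#' @export
ols_fit <- function(points) {
  n <- nrow(points)
  if (n < 3) stopf("need at least 3 points for a fit")
  if (stats::var(points$pre_px) == 0) stopf("zero predictor variance")
  fit <- stats::lm(pdr_pct ~ pre_px, data = points)
  sm <- summary(fit)
  r <- if (stats::var(points$pdr_pct) == 0) 0 else
    stats::cor(points$pre_px, points$pdr_pct)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r,
         n = n,
         slope_se = sm$coefficients[2, 2],
         residual_var = sm$sigma^2),
    class = "pdr_fit"
  )
}

#' @export
print.pdr_fit <- function(x, ...) {
  cat(sprintf("<pdr_fit> slope %.4f +/- %.4f %%/px, r = %.3f, n = %d\n",
              x$slope, x$slope_se, x$r, x$n))
  invisible(x)
}

#' Test equality of two independent regression slopes
#'
#' The classical equality-of-slopes test for unpaired data: the slope
#' difference divided by its standard error from the pooled residual
#' variance of the two fits, with `n1 + n2 - 4` degrees of freedom. This
#' statistic equals the interaction-term t of the joint model
#' `y ~ x * group` exactly.
#'
#' @param fit_a,fit_b Two independent [ols_fit()] results.
#' @return Object of class `pdr_slope_comparison` with both slopes, `t`,
#'   `df` and the two-tailed `p`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "pdr_fit")) stopf("inputs must be pdr_fit objects")
  }
  # Sxx recovered from slope SE: se^2 = residual_var / Sxx
  sxx_a <- fit_a$residual_var / fit_a$slope_se^2
  sxx_b <- fit_b$residual_var / fit_b$slope_se^2
  df <- fit_a$n + fit_b$n - 4L
  s2p <- ((fit_a$n - 2) * fit_a$residual_var +
            (fit_b$n - 2) * fit_b$residual_var) / df
  se_diff <- sqrt(s2p * (1 / sxx_a + 1 / sxx_b))
  if (!is.finite(se_diff) || se_diff == 0) stopf("degenerate standard error")
  tt <- (fit_a$slope - fit_b$slope) / se_diff
  structure(
    list(slope_a = fit_a$slope, slope_b = fit_b$slope,
         t = tt, df = df, p = 2 * stats::pt(-abs(tt), df)),
    class = "pdr_slope_comparison"
  )
}

#' @export
print.pdr_slope_comparison <- function(x, ...) {
  cat(sprintf("<pdr_slope_comparison> %.4f vs %.4f: t(%d) = %.2f, p = %.3g\n",
              x$slope_a, x$slope_b, x$df, x$t, x$p))
  invisible(x)
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' `z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3))`, two-tailed p
#' from the standard normal.
#'
#' @param r_a,r_b Correlations with `|r| < 1`.
#' @param n_a,n_b Sample sizes (> 3).
#' @return Object of class `pdr_corr_comparison` with `z` and `p`.
#' @export
compare_correlations <- function(r_a, n_a, r_b, n_b) {
  if (abs(r_a) >= 1 || abs(r_b) >= 1) stopf("correlations must satisfy |r| < 1")
  if (n_a <= 3 || n_b <= 3) stopf("sample sizes must exceed 3")
  z <- (atanh(r_a) - atanh(r_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  structure(
    list(r_a = r_a, n_a = n_a, r_b = r_b, n_b = n_b,
         z = z, p = 2 * stats::pnorm(-abs(z))),
    class = "pdr_corr_comparison"
  )
}

#' @export
print.pdr_corr_comparison <- function(x, ...) {
  cat(sprintf("<pdr_corr_comparison> r = %.3f (n=%d) vs %.3f (n=%d): z = %.2f, p = %.3g\n",
              x$r_a, x$n_a, x$r_b, x$n_b, x$z, x$p))
  invisible(x)
}

#' Audio-vs-baseline pre-stimulus regression comparison
#'
#' Convenience wrapper running the full regression analysis on one or
#' more subjects: audio trial points, a matched number of equally spaced
#' baseline control frames, subject centering, the two OLS fits and the
#' slope and correlation comparisons.
#'
#' @param audio_sets,baseline_sets A percent-normalized `frame_set` or
#'   list thereof (one per subject).
#' @param interval Analysis window.
#' @param seed Seed for the baseline control selection.
#' @return List of class `pdr_regression`: centered `points`, `fit_audio`,
#'   `fit_baseline`, `slope_test`, `corr_test`.
#' @export
regress_prestim <- function(audio_sets, baseline_sets,
                            interval = c(1.0, 1.5), seed = 1L) {
  as_list <- function(x) if (inherits(x, "frame_set")) list(x) else x
  audio_sets <- as_list(audio_sets)
  baseline_sets <- as_list(baseline_sets)
  if (length(audio_sets) != length(baseline_sets)) {
    stopf("need one baseline frame set per audio frame set")
  }
  pts <- list()
  for (i in seq_along(audio_sets)) {
    pa <- trial_points(audio_sets[[i]], interval = interval)
    pb <- baseline_control_points(baseline_sets[[i]], n_needed = nrow(pa),
                                  seed = derive_seed(seed, i),
                                  interval = interval)
    pts[[i]] <- dplyr::bind_rows(pa, pb)
  }
  points <- center_by_subject(dplyr::bind_rows(pts))
  fit_a <- ols_fit(points[points$condition == "audio", ])
  fit_b <- ols_fit(points[points$condition == "baseline_control", ])
  structure(
    list(points = points, fit_audio = fit_a, fit_baseline = fit_b,
         slope_test = compare_slopes(fit_a, fit_b),
         corr_test = compare_correlations(fit_a$r, fit_a$n, fit_b$r, fit_b$n)),
    class = "pdr_regression"
  )
}

#' @export
print.pdr_regression <- function(x, ...) {
  cat("<pdr_regression>\n  audio:    ")
  print(x$fit_audio)
  cat("  baseline: ")
  print(x$fit_baseline)
  print(x$slope_test)
  print(x$corr_test)
  invisible(x)
}
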
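# Cleaning chain: reliability masking, linear interpolation across
# unreliable samples, resampling to a regular 50 Hz grid and linear
# detrending with mean preservation. The order is fixed:
# mask -> interpolate -> resample -> detrend.

#' Mark unreliable samples
#'
#' A sample is unreliable iff its blink flag is set, its artifact flag is
#' set, or its confidence index falls below the threshold. A confidence of
#' exactly the threshold counts as reliable.
#'
#' @param raw A [raw_sample_table()].
#' @param threshold Confidence threshold (default 0.8).
#' @return The table with an added logical `reliable` column.
#' @export
mask_unreliable <- function(raw, threshold = 0.8) {
  need <- c("timestamp", "diameter", "confidence", "blink", "artifact")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  raw$reliable <- raw$blink == 0 & raw$artifact == 0 & raw$confidence >= threshold
  raw
}

#' Replace unreliable samples by linear interpolation
#'
#' Each unreliable diameter is replaced by linear interpolation between the
#' nearest reliable neighbours in time; unreliable runs at the edges are
#' filled by constant extension of the nearest reliable value. The
#' returned `interp` column is `TRUE` exactly on replaced samples.
#'
#' @param masked Output of [mask_unreliable()].
#' @return The table with `diameter` filled and an `interp` column.
#' @export
interpolate_gaps <- function(masked) {
  if (!"reliable" %in% names(masked)) stopf("run mask_unreliable() first")
  rel <- masked$reliable
  if (sum(rel) < 2) stopf("need at least 2 reliable samples to interpolate")
  if (!all(rel)) {
    filled <- stats::approx(masked$timestamp[rel], masked$diameter[rel],
                            xout = masked$timestamp, method = "linear",
                            rule = 2)$y
    masked$diameter <- filled
  }
  masked$interp <- !rel
  masked
}

#' A regular clean diameter series
#'
#' @param t0 Time of the first grid sample (s).
#' @param rate Sampling rate (Hz).
#' @param values Diameter values (px).
#' @param interp_mask Logical, `TRUE` where a value derives from
#'   interpolation over unreliable data.
#' @param eye Eye label.
#' @param meta Metadata list carried from the source table.
#' @return Object of class `clean_series`.
#' @export
clean_series <- function(t0, rate, values, interp_mask, eye = NA_character_,
                         meta = list()) {
  if (length(values) != length(interp_mask)) {
    stopf("values and interp_mask must have equal length")
  }
  if (any(!is.finite(values))) stopf("clean series values must be finite")
  structure(list(t0 = t0, rate = rate, values = as.numeric(values),
                 interp_mask = as.logical(interp_mask), eye = eye,
                 meta = meta),
            class = "clean_series")
}

#' @export
print.clean_series <- function(x, ...) {
  cat(sprintf("<clean_series> %s eye, %d samples at %g Hz from t0=%.3f s (%.1f %% interpolated)\n",
              x$eye, length(x$values), x$rate, x$t0, 100 * mean(x$interp_mask)))
  invisible(x)
}

#' Resample an interpolated table onto a regular grid
#'
#' Values are linearly interpolated onto `t0 + k/rate`; a grid point is
#' masked as interpolated if either flanking source sample is masked
#' (conservative, so the downstream interpolation-count QC cannot
#' undercount).
#'
#' @param filled Output of [interpolate_gaps()].
#' @param rate Target rate in Hz (default 50).
#' @return A [clean_series()].
#' @export
resample_50hz <- function(filled, rate = 50) {
  if (!"interp" %in% names(filled)) stopf("run interpolate_gaps() first")
  t <- filled$timestamp
  n <- length(t)
  if (n < 2 || (t[n] - t[1]) <= 1 / rate) {
    stopf("need >= 2 samples spanning more than one grid step")
  }
  t0 <- t[1]
  n_g <- floor((t[n] - t0) * rate + 1e-9) + 1
  tg <- t0 + (seq_len(n_g) - 1) / rate
  vals <- stats::approx(t, filled$diameter, xout = tg, method = "linear",
                        rule = 2)$y
  i <- findInterval(tg, t)
  i <- pmax(i, 1L)
  ri <- pmin(i + 1L, n)
  mask <- filled$interp[i] | filled$interp[ri]
  clean_series(t0, rate, vals, mask, eye = attr(filled, "eye"),
               meta = raw_meta(filled))
}

#' Remove a linear trend, preserving the grand mean
#'
#' Fits a least-squares straight line over the full recording and removes
#' its slope; because the removed component is centred, the original grand
#' mean is preserved, keeping the later percent normalization meaningful.
#'
#' @param series A [clean_series()].
#' @return The detrended [clean_series()].
#' @export
detrend_preserve_mean <- function(series) {
  if (!inherits(series, "clean_series")) stopf("series must be a clean_series")
  v <- series$values
  tc <- (seq_along(v) - 1) / series$rate
  tc <- tc - mean(tc)
  slope <- sum(tc * v) / sum(tc * tc)
  series$values <- v - slope * tc
  series
}

#' Full preprocessing chain for one eye stream
#'
#' Applies, in fixed order: reliability masking, linear interpolation over
#' unreliable samples, resampling to a regular grid, and linear detrending
#' with mean preservation.
#'
#' @param raw A [raw_sample_table()].
#' @param conf_threshold Confidence threshold (default 0.8).
#' @param rate Resampling rate in Hz (default 50).
#' @param detrend Apply detrending (default `TRUE`).
#' @param verbose Print interpolation statistics.
#' @return A [clean_series()].
#' @export
clean_pupil <- function(raw, conf_threshold = 0.8, rate = 50,
                        detrend = TRUE, verbose = FALSE) {
  m <- mask_unreliable(raw, threshold = conf_threshold)
  f <- interpolate_gaps(m)
  if (verbose) {
    message(sprintf("clean_pupil [%s %s]: %d/%d samples (%.1f %%) interpolated",
                    attr(raw, "subject_id"), attr(raw, "eye"),
                    sum(f$interp), nrow(f), 100 * mean(f$interp)))
  }
  cs <- resample_50hz(f, rate = rate)
  if (detrend) cs <- detrend_preserve_mean(cs) else cs
}

#' Serialize a clean series to a data frame
#'
#' @param series A [clean_series()].
#' @return Tibble with `t`, `value_px`, `interp_mask`.
#' @export
clean_series_df <- function(series) {
  tibble::tibble(
    t = series$t0 + (seq_along(series$values) - 1) / series$rate,
    value_px = series$values,
    interp_mask = series$interp_mask
  )
}
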
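# Segmentation of clean series into 3-s, 150-sample epochs around stimulus
# onsets (audio) or matched schedule instants (baseline), QC on the number
# of interpolated points, pre-stimulus normalization and block labelling.

new_frame_set <- function(values, info, rate, pre_samples, n_samples,
                          norm_mode = "raw", condition = NA_character_,
                          subject_id = NA_character_,
                          luminance = NA_character_,
                          qc = list()) {
  stopifnot(is.matrix(values), nrow(values) == nrow(info))
  structure(list(values = values, info = info, rate = rate,
                 pre_samples = pre_samples, n_samples = n_samples,
                 norm_mode = norm_mode, condition = condition,
                 subject_id = subject_id, luminance = luminance, qc = qc),
            class = "frame_set")
}

#' Construct a frame set from a matrix of epochs
#'
#' Builds a `frame_set` directly from a frames-by-samples matrix, e.g. for
#' epochs produced outside the segmentation pipeline or for constructing
#' known test cases.
#'
#' @param values Numeric matrix, one row per frame.
#' @param rate Sampling rate (Hz).
#' @param pre_samples Number of pre-stimulus samples.
#' @param norm_mode `"raw"`, `"percent"` or `"difference"` describing the
#'   scale `values` are already on.
#' @param condition,subject_id,luminance Metadata labels.
#' @param trial Trial indices (default sequential).
#' @param eye Eye label(s).
#' @param n_interp Per-frame interpolated-sample counts.
#' @param pre_mean Pre-stimulus means in px; computed from the
#'   pre-stimulus samples when `NULL` (only meaningful for raw values).
#' @return A `frame_set`.
#' @export
frame_set <- function(values, rate = 50, pre_samples = 25L,
                      norm_mode = "raw", condition = NA_character_,
                      subject_id = NA_character_, luminance = NA_character_,
                      trial = seq_len(nrow(values)), eye = "left",
                      n_interp = integer(nrow(values)), pre_mean = NULL) {
  values <- as.matrix(values)
  if (is.null(pre_mean)) {
    pre_mean <- rowMeans(values[, seq_len(pre_samples), drop = FALSE])
  }
  info <- tibble::tibble(
    trial = as.integer(trial), onset_s = NA_real_, block = NA_integer_,
    eye = rep_len(eye, nrow(values)),
    n_interp = as.integer(rep_len(n_interp, nrow(values))),
    pre_mean = rep_len(as.numeric(pre_mean), nrow(values))
  )
  new_frame_set(values, info, rate = rate, pre_samples = pre_samples,
                n_samples = ncol(values), norm_mode = norm_mode,
                condition = condition, subject_id = subject_id,
                luminance = luminance,
                qc = list(scheduled = nrow(values), extracted = nrow(values),
                          dropped_incomplete = 0L))
}

#' Number of frames in a frame set
#' @param fs A frame set.
#' @return Integer count.
#' @export
n_frames <- function(fs) nrow(fs$values)

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames x %d samples (%s, %s norm) subject %s\n",
              n_frames(x), x$n_samples, x$condition, x$norm_mode, x$subject_id))
  if (!is.null(x$qc$kept)) {
    cat(sprintf("  QC: %d extracted, %d kept, %d discarded\n",
                x$qc$extracted, x$qc$kept, x$qc$discarded))
  }
  invisible(x)
}

subset_frames <- function(fs, keep) {
  fs$values <- fs$values[keep, , drop = FALSE]
  fs$info <- fs$info[keep, , drop = FALSE]
  fs
}

#' Cut a clean series into stimulus-locked frames
#'
#' Each frame spans `n_samples` grid samples starting at the grid sample
#' at or before `onset - pre_s`; with the defaults that is a 3-s epoch
#' whose first 25 samples (0.5 s) precede the stimulus. Onsets whose
#' window falls outside the recording are dropped with a message. Trial
#' indices follow schedule position, so later QC losses never shift block
#' boundaries.
#'
#' @param series A [clean_series()].
#' @param events An [event_table()] or numeric vector of onset times on
#'   the series clock.
#' @param pre_s Pre-stimulus window length (s).
#' @param n_samples Frame length in samples.
#' @param pre_samples Number of pre-stimulus samples.
#' @return A `frame_set` with raw (px) values, per-frame interpolation
#'   counts and pre-stimulus means.
#' @export
extract_frames <- function(series, events, pre_s = 0.5, n_samples = 150L,
                           pre_samples = 25L) {
  if (!inherits(series, "clean_series")) stopf("series must be a clean_series")
  onsets <- if (inherits(events, "event_table") || is.data.frame(events)) {
    events$onset_s
  } else {
    as.numeric(events)
  }
  rate <- series$rate
  N <- length(series$values)
  i0 <- floor((onsets - pre_s - series$t0) * rate + 1e-9)
  ok <- i0 >= 0 & (i0 + n_samples) <= N
  if (length(onsets) && !any(ok)) {
    warnf("no stimulus window falls inside the recording; empty frame set")
  } else if (any(!ok)) {
    message(sprintf("extract_frames: dropped %d onset(s) with incomplete windows",
                    sum(!ok)))
  }
  idx0 <- i0[ok]
  vals <- matrix(numeric(0), 0, n_samples)
  nint <- integer(0)
  if (length(idx0)) {
    im <- outer(idx0, seq_len(n_samples), "+")
    vals <- matrix(series$values[im], nrow = length(idx0))
    nint <- as.integer(rowSums(matrix(series$interp_mask[im], nrow = length(idx0))))
  }
  info <- tibble::tibble(
    trial = which(ok), onset_s = onsets[ok],
    block = NA_integer_, eye = series$eye,
    n_interp = nint,
    pre_mean = if (length(idx0)) rowMeans(vals[, seq_len(pre_samples), drop = FALSE]) else numeric(0)
  )
  new_frame_set(vals, info, rate = rate, pre_samples = pre_samples,
                n_samples = n_samples,
                condition = series$meta$condition %||% NA_character_,
                subject_id = series$meta$subject_id %||% NA_character_,
                luminance = series$meta$luminance %||% NA_character_,
                qc = list(scheduled = length(onsets), extracted = sum(ok),
                          dropped_incomplete = sum(!ok)))
}

#' Cut baseline frames at the audio schedule instants
#'
#' Applies the identical windowing to a no-stimulation recording at the
#' same offsets from recording start as the audio schedule, producing the
#' null frames the detection statistics compare against.
#'
#' @param series Baseline-condition [clean_series()].
#' @param audio_schedule [event_table()] or numeric onsets of the audio
#'   session (or the nominal protocol schedule).
#' @param schedule_origin Clock time at which the audio recording started
#'   (0 for generator sessions, whose clocks start at zero).
#' @inheritParams extract_frames
#' @return A `frame_set` of baseline frames.
#' @export
baseline_frames <- function(series, audio_schedule, schedule_origin = 0,
                            pre_s = 0.5, n_samples = 150L, pre_samples = 25L) {
  onsets <- if (inherits(audio_schedule, "event_table") || is.data.frame(audio_schedule)) {
    audio_schedule$onset_s
  } else {
    as.numeric(audio_schedule)
  }
  extract_frames(series, series$t0 + (onsets - schedule_origin),
                 pre_s = pre_s, n_samples = n_samples,
                 pre_samples = pre_samples)
}

#' Discard frames with too many interpolated points
#'
#' Keeps frames whose interpolated-sample count is at most `max_interp`
#' (the rule is strict: more than `max_interp` corrected points discards
#' the frame, exactly `max_interp` keeps it).
#'
#' @param fs A `frame_set` with `n_interp` set.
#' @param max_interp Maximum tolerated interpolated samples per frame.
#' @return The filtered `frame_set`, with QC counts recorded.
#' @export
qc_filter <- function(fs, max_interp = 15L) {
  keep <- fs$info$n_interp <= max_interp
  out <- subset_frames(fs, keep)
  out$qc$extracted <- n_frames(fs)
  out$qc$kept <- sum(keep)
  out$qc$discarded <- sum(!keep)
  out
}

#' Normalize frames to their pre-stimulus mean
#'
#' Percent mode rescales each frame to `100 * value / pre_mean` so the
#' pre-stimulus mean is exactly 100; difference mode subtracts `pre_mean`
#' so it is exactly 0. The raw pixel `pre_mean` is retained in the frame
#' metadata for the pre-stimulus regression. Frames with a non-positive
#' pre-stimulus mean cannot be percent-normalized and are excluded with a
#' message.
#'
#' @param fs A raw `frame_set`.
#' @param mode `"percent"` or `"difference"`.
#' @return The normalized `frame_set` (`norm_mode` set accordingly).
#' @export
normalize_frames <- function(fs, mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  if (fs$norm_mode != "raw") stopf("frames are already normalized (%s)", fs$norm_mode)
  pm <- fs$info$pre_mean
  if (mode == "percent") {
    bad <- !(pm > 0)
    if (any(bad)) {
      message(sprintf("normalize_frames: excluded %d frame(s) with non-positive pre-stimulus mean",
                      sum(bad)))
      fs <- subset_frames(fs, !bad)
      pm <- fs$info$pre_mean
    }
    fs$values <- sweep(fs$values, 1, pm, "/") * 100
  } else {
    fs$values <- sweep(fs$values, 1, pm, "-")
  }
  fs$norm_mode <- mode
  fs
}

#' Assign adaptation blocks from trial order
#'
#' Trials 1-15 form block 1, 16-30 block 2 and all later trials block 3
#' (with the default block size). Labels derive from nominal schedule
#' position, not from post-QC order.
#'
#' @param fs A `frame_set` with `trial` set.
#' @param block_size Trials per block (default 15).
#' @return The `frame_set` with `block` filled in.
#' @export
assign_blocks <- function(fs, block_size = 15L) {
  fs$info$block <- block_of_trial(fs$info$trial, block_size)
  fs
}

#' Pool or average frames across eyes (or sessions)
#'
#' With `method = "pool"` (default) frames enter as separate observations.
#' With `method = "average"` frames sharing a trial index are averaged
#' across eyes (frames present in a single eye are kept as-is), mirroring
#' per-trial eye averaging; interpolation counts take the per-trial
#' maximum.
#'
#' @param ... `frame_set`s with identical geometry and normalization.
#' @param method `"pool"` or `"average"`.
#' @return A combined `frame_set`.
#' @export
pool_frames <- function(..., method = c("pool", "average")) {
  method <- match.arg(method)
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "frame_set")) {
    sets <- sets[[1]]
  }
  if (!length(sets)) stopf("no frame sets given")
  ref <- sets[[1]]
  for (s in sets) {
    if (!inherits(s, "frame_set")) stopf("all inputs must be frame_sets")
    if (s$n_samples != ref$n_samples || s$rate != ref$rate ||
        !identical(s$norm_mode, ref$norm_mode)) {
      stopf("frame sets differ in geometry or normalization")
    }
  }
  values <- do.call(rbind, lapply(sets, function(s) s$values))
  info <- dplyr::bind_rows(lapply(sets, function(s) s$info))
  qc <- list(
    scheduled = sum(vapply(sets, function(s) s$qc$scheduled %||% NA_integer_, numeric(1))),
    extracted = sum(vapply(sets, function(s) s$qc$extracted %||% NA_integer_, numeric(1))),
    kept = sum(vapply(sets, function(s) s$qc$kept %||% NA_integer_, numeric(1))),
    discarded = sum(vapply(sets, function(s) s$qc$discarded %||% NA_integer_, numeric(1)))
  )
  out <- new_frame_set(values, info, rate = ref$rate,
                       pre_samples = ref$pre_samples,
                       n_samples = ref$n_samples, norm_mode = ref$norm_mode,
                       condition = ref$condition, subject_id = ref$subject_id,
                       luminance = ref$luminance, qc = qc)
  if (method == "pool") return(out)
  # eye averaging: aggregate rows by trial index (rowsum/tapply both order
  # groups by sorted trial, so rows stay aligned)
  tr <- out$info$trial
  ut <- sort(unique(tr))
  grp <- match(tr, ut)
  cnt <- tabulate(grp, nbins = length(ut))
  out$values <- rowsum(out$values, grp) / cnt
  out$info <- tibble::tibble(
    trial = ut,
    onset_s = as.numeric(tapply(out$info$onset_s, grp, mean)),
    block = as.integer(tapply(out$info$block, grp, function(b) b[1])),
    eye = "both",
    n_interp = as.integer(tapply(out$info$n_interp, grp, max)),
    pre_mean = as.numeric(tapply(out$info$pre_mean, grp, mean))
  )
  out
}

#' Serialize a frame set to long format
#'
#' @param fs A `frame_set`.
#' @return Tibble with one row per frame sample: subject, condition, eye,
#'   trial, block, sample index, time relative to frame start and value.
#' @export
frames_df <- function(fs) {
  nf <- n_frames(fs)
  ns <- fs$n_samples
  tibble::tibble(
    subject_id = rep(fs$subject_id, nf * ns),
    condition = rep(fs$condition, nf * ns),
    eye = rep(fs$info$eye, each = ns),
    trial = rep(fs$info$trial, each = ns),
    block = rep(fs$info$block, each = ns),
    sample_index = rep(seq_len(ns), nf),
    t_rel_s = rep((seq_len(ns) - 1) / fs$rate, nf),
    value = as.vector(t(fs$values)),
    n_interp = rep(fs$info$n_interp, each = ns)
  )
}
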
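# Orchestration: run configuration, end-to-end commands over session
# directories, and report collation. These functions back the thin
# command-line wrapper shipped in inst/scripts/pdrkit.R.

#' Full pipeline run configuration
#'
#' Defaults reproduce the analysis parameters of the protocol: 0.8
#' confidence threshold, 50 Hz resampling, 150-sample frames with a
#' 25-sample pre-stimulus window, at most 15 interpolated points per kept
#' frame, alpha = 0.05 and blocks of 15 trials.
#'
#' @param out_dir Output directory.
#' @param seed Top-level seed; every randomised stage derives from it.
#' @param sim A [sim_config()] used by [run_simulate()].
#' @param audio_dir,baseline_dir Session directories; default to
#'   `out_dir/audio` and `out_dir/baseline` (as written by
#'   [run_simulate()]).
#' @param col_map Column map for reading sample tables.
#' @param conf_threshold,resample_rate,detrend Preprocessing parameters.
#' @param frame_samples,pre_samples,max_interp Frame geometry and QC.
#' @param norm_mode `"percent"` or `"difference"`.
#' @param pool `"pool"` or `"average"` (eye handling).
#' @param intervals,alpha Detection parameters.
#' @param block_size Trials per adaptation block.
#' @param regress_interval Window for the pre-stimulus regression.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "pdr-output", seed = 1L,
                       sim = sim_config(seed = seed),
                       audio_dir = NULL, baseline_dir = NULL,
                       col_map = pupil_col_map(),
                       conf_threshold = 0.8, resample_rate = 50,
                       detrend = TRUE,
                       frame_samples = 150L, pre_samples = 25L,
                       max_interp = 15L,
                       norm_mode = c("percent", "difference"),
                       pool = c("pool", "average"),
                       intervals = pdr_intervals(), alpha = 0.05,
                       block_size = 15L,
                       regress_interval = c(1.0, 1.5)) {
  norm_mode <- match.arg(norm_mode)
  pool <- match.arg(pool)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         audio_dir = audio_dir %||% file.path(out_dir, "audio"),
         baseline_dir = baseline_dir %||% file.path(out_dir, "baseline"),
         col_map = col_map, conf_threshold = conf_threshold,
         resample_rate = resample_rate, detrend = detrend,
         frame_samples = as.integer(frame_samples),
         pre_samples = as.integer(pre_samples),
         max_interp = as.integer(max_interp),
         norm_mode = norm_mode, pool = pool,
         intervals = intervals, alpha = alpha,
         block_size = as.integer(block_size),
         regress_interval = regress_interval),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file of configuration keys.
#' @return A [run_config()].
#' @export
run_config_from_file <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$sim)) vals$sim <- do.call(sim_config, vals$sim)
  if (!is.null(vals$intervals)) vals$intervals <- tibble::as_tibble(vals$intervals)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Simulate and write a subject's audio and baseline sessions
#'
#' @param config A [run_config()].
#' @return Invisibly, the two session directories.
#' @export
run_simulate <- function(config) {
  sim_cfg <- config$sim
  sim_cfg$seed <- derive_seed(config$seed, 11L)
  for (cond in c("audio", "baseline")) {
    dir <- if (cond == "audio") config$audio_dir else config$baseline_dir
    write_session(simulate_session(sim_cfg, cond), dir)
  }
  message(sprintf("run_simulate: wrote sessions under %s (seed %d)",
                  config$out_dir, config$seed))
  invisible(c(config$audio_dir, config$baseline_dir))
}

# Read both session directories and produce normalized, blocked, QC'd
# frame sets for each condition.
prepare_frames <- function(config) {
  for (d in c(config$audio_dir, config$baseline_dir)) {
    if (!dir.exists(d)) stopf("missing session directory: %s (run_simulate first?)", d)
  }
  ba <- read_session(config$audio_dir, col_map = config$col_map)
  bb <- read_session(config$baseline_dir, col_map = config$col_map)
  validate_session(ba, conf_threshold = config$conf_threshold)
  validate_session(bb, conf_threshold = config$conf_threshold)
  finish <- function(sets) {
    fs <- pool_frames(sets, method = config$pool)
    fs <- assign_blocks(fs, block_size = config$block_size)
    fs <- qc_filter(fs, max_interp = config$max_interp)
    normalize_frames(fs, config$norm_mode)
  }
  clean <- function(raw) {
    clean_pupil(raw, conf_threshold = config$conf_threshold,
                rate = config$resample_rate, detrend = config$detrend)
  }
  audio <- finish(lapply(list(ba$left, ba$right), function(raw) {
    extract_frames(clean(raw), ba$events,
                   n_samples = config$frame_samples,
                   pre_samples = config$pre_samples)
  }))
  schedule <- if (length(bb$schedule)) bb$schedule else ba$events$onset_s
  baseline <- finish(lapply(list(bb$left, bb$right), function(raw) {
    baseline_frames(clean(raw), schedule,
                    n_samples = config$frame_samples,
                    pre_samples = config$pre_samples)
  }))
  list(audio = audio, baseline = baseline,
       truth = ba$truth)
}

qc_summary <- function(fs) {
  list(scheduled = fs$qc$scheduled, extracted = fs$qc$extracted,
       kept = fs$qc$kept, discarded = fs$qc$discarded)
}

#' Detect PDRs for the configured session pair and write reports
#'
#' Writes `subject_results.csv` (one row per interval), the grand-average
#' trace `traces.csv` and a `qc.json` summary under `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [detect_subject()] result.
#' @export
run_detect <- function(config) {
  fr <- prepare_frames(config)
  res <- detect_subject(fr$audio, fr$baseline,
                        intervals = config$intervals, alpha = config$alpha)
  ga <- grand_average(fr$audio, fr$baseline,
                      intervals = config$intervals, alpha = config$alpha)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = res$subject_id, luminance = res$luminance,
                   norm_mode = res$norm_mode)[rep(1, nrow(res$results)), ],
    res$results
  )
  readr::write_csv(out, file.path(config$out_dir, "subject_results.csv"))
  readr::write_csv(ga$trace, file.path(config$out_dir, "traces.csv"))
  jsonlite::write_json(
    list(audio = qc_summary(fr$audio), baseline = qc_summary(fr$baseline),
         alpha = config$alpha, any_significant = res$any_significant),
    file.path(config$out_dir, "qc.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}

#' Block-wise detection for the configured session pair
#'
#' Writes `block_results.csv` and `block_summary.json` under `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [detect_by_block()] result.
#' @export
run_blocks <- function(config) {
  fr <- prepare_frames(config)
  br <- detect_by_block(fr$audio, fr$baseline,
                        intervals = config$intervals, alpha = config$alpha)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = br$subject_id,
                   luminance = br$luminance)[rep(1, nrow(br$results)), ],
    br$results
  )
  readr::write_csv(out, file.path(config$out_dir, "block_results.csv"))
  jsonlite::write_json(
    list(significant_by_block = as.list(br$significant_by_block),
         any_block_significant = br$any_block_significant,
         full_trace_significant = br$full_trace_significant),
    file.path(config$out_dir, "block_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(br)
}

#' Pre-stimulus regression analysis for the configured session pair
#'
#' Writes `regression_points.csv` and `regression.json` under `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [regress_prestim()] result.
#' @export
run_regress <- function(config) {
  fr <- prepare_frames(config)
  if (!identical(config$norm_mode, "percent")) {
    stopf("the pre-stimulus regression requires percent normalization")
  }
  reg <- regress_prestim(fr$audio, fr$baseline,
                         interval = config$regress_interval,
                         seed = derive_seed(config$seed, 21L))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(reg$points, file.path(config$out_dir, "regression_points.csv"))
  jsonlite::write_json(
    list(fit_audio = unclass(reg$fit_audio),
         fit_baseline = unclass(reg$fit_baseline),
         slope_test = unclass(reg$slope_test),
         corr_test = unclass(reg$corr_test)),
    file.path(config$out_dir, "regression.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(reg)
}

#' Collate pipeline outputs into a single report
#'
#' Gathers whichever of the detection, block and regression outputs exist
#' under `out_dir` into `report.json` and a human-readable
#' `report.txt`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report list.
#' @export
run_report <- function(config) {
  od <- config$out_dir
  if (!dir.exists(od)) stopf("missing output directory: %s", od)
  report <- list(seed = config$seed, alpha = config$alpha)
  f_sub <- file.path(od, "subject_results.csv")
  if (file.exists(f_sub)) {
    det <- readr::read_csv(f_sub, show_col_types = FALSE, progress = FALSE)
    report$detection <- list(n_intervals = nrow(det),
                             n_significant = sum(det$significant),
                             results = det)
  }
  f_blk <- file.path(od, "block_summary.json")
  if (file.exists(f_blk)) report$blocks <- jsonlite::fromJSON(f_blk)
  f_reg <- file.path(od, "regression.json")
  if (file.exists(f_reg)) report$regression <- jsonlite::fromJSON(f_reg)
  if (is.null(report$detection) && is.null(report$blocks) && is.null(report$regression)) {
    stopf("no upstream outputs found under %s", od)
  }
  jsonlite::write_json(report, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  lines <- c(sprintf("PDR pipeline report (seed %d, alpha %.3g)", config$seed, config$alpha))
  if (!is.null(report$detection)) {
    lines <- c(lines, sprintf("detection: %d/%d intervals significant",
                              report$detection$n_significant,
                              report$detection$n_intervals))
  }
  if (!is.null(report$blocks)) {
    sig <- report$blocks$significant_by_block
    lines <- c(lines, sprintf("blocks significant: %s",
                              paste(names(sig)[unlist(sig)], collapse = ", ")))
  }
  if (!is.null(report$regression)) {
    lines <- c(lines, sprintf("regression: audio slope %.4f vs baseline %.4f (slope test p = %.3g)",
                              report$regression$fit_audio$slope,
                              report$regression$fit_baseline$slope,
                              report$regression$slope_test$p))
  }
  writeLines(lines, file.path(od, "report.txt"))
  invisible(report)
}
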
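# Block-wise adaptation analysis: re-run PDR detection within trial
# blocks (first 15, second 15, remainder).

#' Run PDR detection separately per trial block
#'
#' Blocks 1-3 use only that block's audio frames; baseline frames are by
#' default partitioned by the same nominal trial indices (`"matched"`), so
#' each block's null has matched size and session-time coverage, with the
#' full baseline pool available as an option. The `"all"` entry re-runs
#' the full-trace detection and reproduces [detect_subject()] exactly.
#'
#' @param audio,baseline Normalized `frame_set`s with block labels (see
#'   [assign_blocks()]).
#' @param intervals,alpha As in [detect_subject()].
#' @param baseline_blocks `"matched"` (default) or `"full"`.
#' @return Object of class `pdr_block_result`: a results tibble with a
#'   `block` column (`"1"`, `"2"`, `"3"`, `"all"`) and per-block
#'   significance flags.
#' @export
detect_by_block <- function(audio, baseline, intervals = pdr_intervals(),
                            alpha = 0.05,
                            baseline_blocks = c("matched", "full")) {
  baseline_blocks <- match.arg(baseline_blocks)
  if (anyNA(audio$info$block) || anyNA(baseline$info$block)) {
    stopf("assign_blocks() must be run before detect_by_block()")
  }
  pieces <- list()
  for (b in 1:3) {
    a_sub <- subset_frames(audio, audio$info$block == b)
    b_sub <- if (baseline_blocks == "matched") {
      subset_frames(baseline, baseline$info$block == b)
    } else {
      baseline
    }
    if (n_frames(a_sub) < 2 || n_frames(b_sub) < 2) {
      warnf("block %d skipped: fewer than 2 frames on one side", b)
      next
    }
    res <- detect_subject(a_sub, b_sub, intervals = intervals, alpha = alpha)
    pieces[[as.character(b)]] <- dplyr::bind_cols(
      tibble::tibble(block = as.character(b)), res$results
    )
  }
  full <- detect_subject(audio, baseline, intervals = intervals, alpha = alpha)
  pieces[["all"]] <- dplyr::bind_cols(
    tibble::tibble(block = "all"), full$results
  )
  results <- dplyr::bind_rows(pieces)
  by_block <- vapply(split(results$significant, results$block),
                     any, logical(1))
  structure(
    list(subject_id = audio$subject_id, luminance = audio$luminance,
         alpha = alpha, results = results,
         significant_by_block = by_block,
         any_block_significant = any(by_block[names(by_block) != "all"]),
         full_trace_significant = isTRUE(by_block[["all"]])),
    class = "pdr_block_result"
  )
}

#' @export
print.pdr_block_result <- function(x, ...) {
  cat(sprintf("<pdr_block_result> subject %s (%s)\n", x$subject_id, x$luminance))
  for (b in names(x$significant_by_block)) {
    cat(sprintf("  block %s: %s\n", b,
                if (x$significant_by_block[[b]]) "significant" else "n.s."))
  }
  invisible(x)
}

#' Count cases with significant PDRs per luminance group
#'
#' A case is one subject x luminance session. Counting modes:
#' `full_trace` uses the all-trials result; `any_block` requires
#' significance in at least one of blocks 1-3; `either` is their union
#' (the reading under which restricting the averaging to blocks can add
#' cases to the full-trace count).
#'
#' @param block_results List of [detect_by_block()] results, one per case.
#' @param mode Counting mode.
#' @return Tibble with one row per luminance group plus a `total` row:
#'   number of cases, significant cases and percentage.
#' @export
count_significant_cases <- function(block_results,
                                    mode = c("full_trace", "any_block", "either")) {
  mode <- match.arg(mode)
  if (!length(block_results)) {
    return(tibble::tibble(luminance = character(0), n_cases = integer(0),
                          n_significant = integer(0), pct = numeric(0)))
  }
  flag <- function(r) {
    switch(mode,
           full_trace = r$full_trace_significant,
           any_block = r$any_block_significant,
           either = r$full_trace_significant || r$any_block_significant)
  }
  tbl <- tibble::tibble(
    luminance = vapply(block_results, function(r) r$luminance, character(1)),
    sig = vapply(block_results, flag, logical(1))
  )
  out <- dplyr::summarise(
    dplyr::group_by(tbl, luminance),
    n_cases = dplyr::n(), n_significant = sum(sig), .groups = "drop"
  )
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(luminance = "total", n_cases = nrow(tbl),
                   n_significant = sum(tbl$sig))
  )
  out$pct <- 100 * out$n_significant / out$n_cases
  out
}
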
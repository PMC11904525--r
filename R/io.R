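# Reading, writing and validation of per-eye pupil sample tables and
# stimulus event tables.

#' Default column-name map for pupil sample CSV files
#'
#' Maps canonical field names to the column names found in the file.
#' Override entries to read other export dialects.
#'
#' @param timestamp,diameter,confidence,blink,artifact Column names in the
#'   source file for each canonical field.
#' @return Named character vector.
#' @export
pupil_col_map <- function(timestamp = "timestamp", diameter = "diameter",
                          confidence = "confidence", blink = "blink",
                          artifact = "artifact") {
  c(timestamp = timestamp, diameter = diameter, confidence = confidence,
    blink = blink, artifact = artifact)
}

#' Construct a validated raw pupil sample table
#'
#' @param data Data frame with columns `timestamp` (s, non-decreasing),
#'   `diameter` (px), `confidence` (in `[0, 1]`), `blink` and `artifact`
#'   (0/1 flags); an optional `audio` flag column is carried through.
#' @param eye `"left"` or `"right"`.
#' @param subject_id,session_id,condition,luminance Session metadata.
#' @return Tibble of class `raw_samples` with metadata attributes.
#' @export
raw_sample_table <- function(data, eye = c("left", "right"),
                             subject_id = NA_character_,
                             session_id = NA_character_,
                             condition = NA_character_,
                             luminance = NA_character_) {
  eye <- match.arg(eye)
  need <- c("timestamp", "diameter", "confidence", "blink", "artifact")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(data)
  if (nrow(x) == 0) stopf("empty sample table")
  if (is.unsorted(x$timestamp)) stopf("timestamps must be non-decreasing (sort before constructing)")
  if (any(x$confidence < 0 | x$confidence > 1, na.rm = TRUE)) {
    stopf("confidence values must lie in [0, 1]")
  }
  rel <- x$confidence >= 0.8 & x$blink == 0 & x$artifact == 0
  if (any(!is.finite(x$diameter[rel]))) {
    stopf("diameter must be finite where samples are reliable")
  }
  attr(x, "eye") <- eye
  attr(x, "subject_id") <- subject_id
  attr(x, "session_id") <- session_id
  attr(x, "condition") <- condition
  attr(x, "luminance") <- luminance
  class(x) <- c("raw_samples", class(x))
  x
}

raw_meta <- function(x) {
  list(eye = attr(x, "eye"), subject_id = attr(x, "subject_id"),
       session_id = attr(x, "session_id"), condition = attr(x, "condition"),
       luminance = attr(x, "luminance"))
}

#' Read a per-eye pupil sample CSV
#'
#' Rows whose mandatory numeric fields fail to parse are dropped with a
#' message; the table is sorted by timestamp.
#'
#' @param path CSV file with a header.
#' @param eye `"left"` or `"right"`.
#' @param col_map Column-name map, see [pupil_col_map()].
#' @param subject_id,session_id,condition,luminance Metadata labels.
#' @return A [raw_sample_table()].
#' @export
read_pupil_table <- function(path, eye, col_map = pupil_col_map(),
                             subject_id = NA_character_,
                             session_id = NA_character_,
                             condition = NA_character_,
                             luminance = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stopf("empty pupil table: %s", path)
  miss <- col_map[!col_map %in% names(df)]
  if (length(miss)) {
    stopf("column(s) not found in %s: %s (canonical field(s): %s)",
          path, paste(miss, collapse = ", "), paste(names(miss), collapse = ", "))
  }
  out <- tibble::tibble(
    timestamp = suppressWarnings(as.numeric(df[[col_map[["timestamp"]]]])),
    diameter = suppressWarnings(as.numeric(df[[col_map[["diameter"]]]])),
    confidence = suppressWarnings(as.numeric(df[[col_map[["confidence"]]]])),
    blink = suppressWarnings(as.integer(df[[col_map[["blink"]]]])),
    artifact = suppressWarnings(as.integer(df[[col_map[["artifact"]]]]))
  )
  if ("audio" %in% names(df)) {
    out$audio <- suppressWarnings(as.integer(df[["audio"]]))
  }
  bad <- !stats::complete.cases(out[c("timestamp", "diameter", "confidence")])
  if (any(bad)) {
    message(sprintf("read_pupil_table: dropped %d unparseable row(s) from %s",
                    sum(bad), basename(path)))
    out <- out[!bad, ]
  }
  if (nrow(out) == 0) stopf("no parseable rows in %s", path)
  out <- out[order(out$timestamp), ]
  raw_sample_table(out, eye = eye, subject_id = subject_id,
                   session_id = session_id, condition = condition,
                   luminance = luminance)
}

#' Construct a stimulus event table
#'
#' @param onset_s Strictly increasing stimulus onset times (s) on the
#'   pupil-sample clock.
#' @param frequency_hz,level_db_htl,duration_ms Tone descriptor.
#' @return Tibble of class `event_table` with a `stimulus` attribute.
#' @export
event_table <- function(onset_s, frequency_hz = 2000, level_db_htl = 70,
                        duration_ms = 500) {
  onset_s <- as.numeric(onset_s)
  if (any(!is.finite(onset_s))) stopf("onset times must be finite numbers")
  if (length(onset_s) > 1 && any(diff(onset_s) <= 0)) {
    stopf("onset times must be strictly increasing")
  }
  x <- tibble::tibble(onset_s = onset_s)
  attr(x, "stimulus") <- list(frequency_hz = frequency_hz,
                              level_db_htl = level_db_htl,
                              duration_ms = duration_ms)
  class(x) <- c("event_table", class(x))
  x
}

#' Read a stimulus event table from CSV or JSON
#'
#' Unsorted onsets are sorted with a warning; duplicates are collapsed
#' with a warning; inter-onset gaps shorter than the 3-s frame length
#' trigger an overlap warning.
#'
#' @param path CSV file with an `onset_s` column (or a single numeric
#'   column), or a JSON array of onset times.
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    on <- if (is.list(raw) && !is.null(raw$onset_s)) raw$onset_s else unlist(raw)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0) return(event_table(numeric(0)))
    on <- if ("onset_s" %in% names(df)) {
      df[["onset_s"]]
    } else if (ncol(df) >= 1) {
      df[[1]]
    } else {
      stopf("no onset column in %s", path)
    }
  }
  on_num <- suppressWarnings(as.numeric(on))
  if (any(is.na(on_num))) stopf("non-numeric onset value(s) in %s", path)
  if (is.unsorted(on_num, strictly = FALSE)) {
    warnf("onsets in %s were not sorted; sorting", path)
    on_num <- sort(on_num)
  }
  if (anyDuplicated(on_num)) {
    warnf("duplicate onsets in %s collapsed", path)
    on_num <- unique(on_num)
  }
  if (length(on_num) > 1 && any(diff(on_num) < 3)) {
    warnf("inter-onset gap(s) below the 3-s frame length: frames will overlap")
  }
  event_table(on_num)
}

#' Bundle two eye streams and an event table into a session
#'
#' @param left,right [raw_sample_table()]s for the two eyes.
#' @param events An [event_table()].
#' @param schedule Optional nominal stimulus schedule (used for baseline
#'   sessions, whose `events` are empty).
#' @return List of class `session_bundle`.
#' @export
session_bundle <- function(left, right, events, schedule = NULL) {
  if (!identical(attr(left, "eye"), "left") || !identical(attr(right, "eye"), "right")) {
    stopf("left/right tables must carry matching eye labels")
  }
  for (f in c("subject_id", "session_id", "condition")) {
    if (!identical(attr(left, f), attr(right, f))) {
      stopf("both eyes must share the same %s", f)
    }
  }
  structure(list(left = left, right = right, events = events,
                 schedule = if (is.null(schedule)) events$onset_s else schedule,
                 condition = attr(left, "condition"),
                 subject_id = attr(left, "subject_id"),
                 luminance = attr(left, "luminance")),
            class = "session_bundle")
}

#' Validate a session bundle
#'
#' Summarises per-eye sample counts, effective sampling rate, fraction of
#' reliable samples (confidence >= 0.8 and not flagged) and the event
#' count. Fails only on empty or fully unreliable streams.
#'
#' @param bundle A [session_bundle()].
#' @param conf_threshold Reliability threshold on the confidence index.
#' @return List of class `session_report`.
#' @export
validate_session <- function(bundle, conf_threshold = 0.8) {
  eye_report <- function(x, eye) {
    if (is.null(x) || nrow(x) == 0) stopf("empty %s-eye stream", eye)
    rel <- x$confidence >= conf_threshold & x$blink == 0 & x$artifact == 0
    if (!any(rel)) stopf("no reliable samples in %s-eye stream", eye)
    span <- diff(range(x$timestamp))
    list(n = nrow(x), span_s = span,
         rate_hz = if (span > 0) (nrow(x) - 1) / span else NA_real_,
         reliable_fraction = mean(rel))
  }
  rep <- list(
    subject_id = bundle$subject_id, condition = bundle$condition,
    luminance = bundle$luminance,
    left = eye_report(bundle$left, "left"),
    right = eye_report(bundle$right, "right"),
    n_events = nrow(bundle$events)
  )
  structure(rep, class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s / %s (%s)\n", x$subject_id, x$condition, x$luminance))
  for (eye in c("left", "right")) {
    e <- x[[eye]]
    cat(sprintf("  %s: %d samples over %.1f s (%.1f Hz), %.1f %% reliable\n",
                eye, e$n, e$span_s, e$rate_hz, 100 * e$reliable_fraction))
  }
  cat(sprintf("  events: %d\n", x$n_events))
  invisible(x)
}

#' Write a simulated session to disk
#'
#' Produces the same CSV layout [read_session()] consumes: `left.csv` and
#' `right.csv` sample tables, `events.csv`, a `truth.json` ground-truth
#' sidecar and a `config.yaml` copy of the generator configuration.
#'
#' @param session A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, dir) {
  if (!inherits(session, "sim_session")) stopf("session must be a sim_session")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (eye in c("left", "right")) {
    p <- file.path(dir, paste0(eye, ".csv"))
    readr::write_csv(as.data.frame(session[[eye]]), p)
    paths <- c(paths, p)
  }
  pe <- file.path(dir, "events.csv")
  readr::write_csv(as.data.frame(session$events), pe)
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(condition = session$condition, tonic_px = session$tonic_px,
         schedule = session$schedule, truth = session$truth),
    pt, auto_unbox = TRUE, digits = NA
  )
  pc <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(session$config), pc)
  invisible(c(paths, pe, pt, pc))
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Directory containing `left.csv`, `right.csv` and
#'   `events.csv` (and optionally `config.yaml`, `truth.json`).
#' @param col_map Column map passed to [read_pupil_table()].
#' @return A [session_bundle()].
#' @export
read_session <- function(dir, col_map = pupil_col_map()) {
  cfg_path <- file.path(dir, "config.yaml")
  meta <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::fromJSON(truth_path) else NULL
  condition <- if (!is.null(truth)) truth$condition else NA_character_
  eyes <- lapply(c(left = "left", right = "right"), function(eye) {
    read_pupil_table(file.path(dir, paste0(eye, ".csv")), eye = eye,
                     col_map = col_map,
                     subject_id = meta$subject_id %||% NA_character_,
                     session_id = meta$session_id %||% NA_character_,
                     condition = condition,
                     luminance = meta$luminance %||% NA_character_)
  })
  events <- read_events(file.path(dir, "events.csv"))
  bundle <- session_bundle(eyes$left, eyes$right, events,
                           schedule = if (!is.null(truth)) truth$schedule else NULL)
  bundle$truth <- if (!is.null(truth)) tibble::as_tibble(truth$truth) else NULL
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
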
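# Shared fixtures: fast generator configurations and hand-built inputs.

# Short session for unit tests: ~70 s, 16 stimuli (blocks 1 and 2 are
# populated; tests needing a populated block 3 use n_stimuli >= 31).
fast_config <- function(...) {
  sim_config(duration_s = 70, n_stimuli = 16L, ...)
}

# Deterministic, artifact-free configuration: pure evoked signal on a
# constant tonic diameter.
noiseless_config <- function(...) {
  sim_config(duration_s = 70, n_stimuli = 16L,
             jitter_sd_s = 0, noise_sd_px = 0, drift_amp_px = 0,
             lin_trend_px_per_s = 0, blink_rate_per_min = 0,
             artifact_rate_per_min = 0, low_conf_rate = 0,
             base_diameter_sd_px = 0,
             adaptation_factors = c(1, 1, 1), coupling_kappa = 0, ...)
}

# Clean series whose value equals its 0-based grid index (for index math).
index_series <- function(n = 2000, rate = 50, t0 = 0) {
  clean_series(t0 = t0, rate = rate, values = seq_len(n) - 1,
               interp_mask = logical(n), eye = "left",
               meta = list(subject_id = "idx", condition = "audio",
                           luminance = "LL"))
}

# Raw sample table on a regular clock with full confidence.
make_raw <- function(timestamp, diameter, confidence = 1,
                     blink = 0L, artifact = 0L, eye = "left",
                     condition = "audio", luminance = "LL") {
  n <- length(timestamp)
  raw_sample_table(
    tibble::tibble(timestamp = timestamp, diameter = diameter,
                   confidence = rep_len(confidence, n),
                   blink = rep_len(as.integer(blink), n),
                   artifact = rep_len(as.integer(artifact), n)),
    eye = eye, subject_id = "t01", session_id = "s01",
    condition = condition, luminance = luminance
  )
}
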
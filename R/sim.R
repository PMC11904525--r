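# Synthetic pupil-session generator.
#
# Emulates an auditory pupillometry protocol: 8-min recordings at an
# irregular ~62 FPS per eye, 120 pure-tone stimuli at a 4-s inter-stimulus
# interval, spontaneous AR(1) pupil fluctuation riding on slow drift,
# blinks/artifacts with confidence dips, and a gamma-shaped evoked dilation
# transient whose amplitude adapts over trial blocks and couples negatively
# to the pre-stimulus tonic diameter.

#' Configuration of a synthetic pupil recording session
#'
#' Defaults reproduce the acquisition protocol the package targets: 8-min
#' sessions, ~62 FPS irregular sampling, 120 stimuli delivered every 4 s,
#' luminance-dependent tonic diameter (low luminance 100.6 +/- 26.2 px,
#' high luminance 68.8 +/- 17.2 px), evoked responses of roughly 1-3 % of
#' the tonic diameter peaking 1-1.5 s after onset, block-wise adaptation
#' (present / absent / partially recovered over blocks of 15 trials), and
#' negative coupling between pre-stimulus tonic deviation and evoked
#' amplitude.
#'
#' @param seed Integer seed; identical configurations are bit-reproducible.
#' @param duration_s Recording length in seconds.
#' @param raw_rate_hz Nominal raw sampling rate (frames per second).
#' @param jitter_sd_s SD of Gaussian jitter on inter-sample gaps (s),
#'   clipped so gaps stay positive.
#' @param n_stimuli Number of scheduled stimuli.
#' @param isi_s Inter-stimulus interval (s).
#' @param first_onset_s Onset of the first stimulus (s).
#' @param luminance `"LL"` (low) or `"HL"` (high); sets tonic diameter
#'   defaults when `base_diameter_px`/`base_diameter_sd_px` are `NULL`.
#' @param base_diameter_px,base_diameter_sd_px Mean and between-session SD
#'   of the tonic pupil diameter (px).
#' @param ar_coeff AR(1) coefficient of the spontaneous fluctuation, in
#'   `[0, 1)` at the raw sampling rate.
#' @param noise_sd_px Innovation SD of the AR(1) process (px).
#' @param drift_amp_px,drift_period_s Amplitude (px) and period (s) of the
#'   slow sinusoidal arousal drift shared by both eyes.
#' @param lin_trend_px_per_s Linear drift slope (px/s).
#' @param blink_rate_per_min,blink_dur_ms Blink rate and min/max duration.
#' @param artifact_rate_per_min,artifact_dur_ms Tracking-artifact rate and
#'   min/max duration.
#' @param low_conf_rate Fraction of isolated samples given a sub-threshold
#'   confidence score outside blinks/artifacts.
#' @param pdr_amp_pct Evoked peak amplitude as percent of the tonic
#'   diameter; `0` produces a null (no-response) session.
#' @param pdr_latency_s,pdr_peak_s Response latency and time-to-peak (s),
#'   measured from stimulus onset.
#' @param pdr_shape Shape exponent of the gamma-family response kernel.
#' @param adaptation_factors Length-3 multiplicative factors applied to the
#'   evoked amplitude in trial blocks 1-15, 16-30 and 31+.
#' @param coupling_kappa Dimensionless coefficient linking the standardized
#'   pre-stimulus tonic deviation to the evoked amplitude (negative:
#'   larger pre-stimulus pupils respond less).
#' @param subject_id,session_id Labels carried into the sample tables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 480,
                       raw_rate_hz = 62,
                       jitter_sd_s = 0.003,
                       n_stimuli = 120L,
                       isi_s = 4,
                       first_onset_s = 1,
                       luminance = c("LL", "HL"),
                       base_diameter_px = NULL,
                       base_diameter_sd_px = NULL,
                       ar_coeff = 0.98,
                       noise_sd_px = 0.6,
                       drift_amp_px = 2,
                       drift_period_s = 90,
                       lin_trend_px_per_s = -0.005,
                       blink_rate_per_min = 12,
                       blink_dur_ms = c(100, 250),
                       artifact_rate_per_min = 2,
                       artifact_dur_ms = c(50, 150),
                       low_conf_rate = 0.01,
                       pdr_amp_pct = 1.8,
                       pdr_latency_s = 0.3,
                       pdr_peak_s = 1.2,
                       pdr_shape = 2,
                       adaptation_factors = c(1, 0, 0.7),
                       coupling_kappa = -0.3,
                       subject_id = "sim01",
                       session_id = "ses01") {
  luminance <- match.arg(luminance)
  if (is.null(base_diameter_px)) {
    base_diameter_px <- if (luminance == "LL") 100.6 else 68.8
  }
  if (is.null(base_diameter_sd_px)) {
    base_diameter_sd_px <- if (luminance == "LL") 26.2 else 17.2
  }
  cfg <- list(
    seed = as.integer(seed), duration_s = duration_s,
    raw_rate_hz = raw_rate_hz, jitter_sd_s = jitter_sd_s,
    n_stimuli = as.integer(n_stimuli), isi_s = isi_s,
    first_onset_s = first_onset_s, luminance = luminance,
    base_diameter_px = base_diameter_px,
    base_diameter_sd_px = base_diameter_sd_px,
    ar_coeff = ar_coeff, noise_sd_px = noise_sd_px,
    drift_amp_px = drift_amp_px, drift_period_s = drift_period_s,
    lin_trend_px_per_s = lin_trend_px_per_s,
    blink_rate_per_min = blink_rate_per_min, blink_dur_ms = blink_dur_ms,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_dur_ms = artifact_dur_ms, low_conf_rate = low_conf_rate,
    pdr_amp_pct = pdr_amp_pct, pdr_latency_s = pdr_latency_s,
    pdr_peak_s = pdr_peak_s, pdr_shape = pdr_shape,
    adaptation_factors = adaptation_factors,
    coupling_kappa = coupling_kappa,
    subject_id = subject_id, session_id = session_id
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c(
    "duration_s", "raw_rate_hz", "jitter_sd_s", "isi_s", "first_onset_s",
    "base_diameter_px", "base_diameter_sd_px", "ar_coeff", "noise_sd_px",
    "drift_amp_px", "drift_period_s", "lin_trend_px_per_s",
    "blink_rate_per_min", "artifact_rate_per_min", "low_conf_rate",
    "pdr_amp_pct", "pdr_latency_s", "pdr_peak_s", "pdr_shape",
    "coupling_kappa"
  )
  for (f in num_fields) {
    if (!is_number(cfg[[f]])) stopf("sim_config field '%s' must be a finite number", f)
  }
  if (cfg$duration_s <= 0) stopf("duration_s must be positive")
  if (cfg$raw_rate_hz <= 0) stopf("raw_rate_hz must be positive")
  if (abs(cfg$ar_coeff) >= 1) stopf("ar_coeff must satisfy |ar_coeff| < 1 (stationarity)")
  if (cfg$noise_sd_px < 0) stopf("noise_sd_px must be non-negative")
  if (cfg$pdr_amp_pct < 0) stopf("pdr_amp_pct must be non-negative")
  if (cfg$pdr_peak_s <= cfg$pdr_latency_s) stopf("pdr_peak_s must exceed pdr_latency_s")
  if (length(cfg$adaptation_factors) != 3L || any(!is.finite(cfg$adaptation_factors)) ||
      any(cfg$adaptation_factors < 0)) {
    stopf("adaptation_factors must be 3 non-negative finite numbers")
  }
  if (length(cfg$blink_dur_ms) != 2L || any(cfg$blink_dur_ms <= 0)) {
    stopf("blink_dur_ms must be a positive (min, max) pair")
  }
  if (length(cfg$artifact_dur_ms) != 2L || any(cfg$artifact_dur_ms <= 0)) {
    stopf("artifact_dur_ms must be a positive (min, max) pair")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %s session, %.0f s at ~%.0f FPS, tonic %.1f +/- %.1f px\n",
              x$luminance, x$duration_s, x$raw_rate_hz,
              x$base_diameter_px, x$base_diameter_sd_px))
  cat(sprintf("  %d stimuli every %.1f s from %.1f s\n",
              x$n_stimuli, x$isi_s, x$first_onset_s))
  cat(sprintf("  PDR %.2f %% peaking at %.2f s; adaptation %s; coupling %.2f\n",
              x$pdr_amp_pct, x$pdr_peak_s,
              paste(x$adaptation_factors, collapse = "/"), x$coupling_kappa))
  invisible(x)
}

#' Gamma-family evoked pupil response kernel
#'
#' A unimodal transient used as the shape of the evoked dilation: zero
#' before `latency_s`, rising to exactly `amp_pct` at `peak_s`, then
#' decaying back toward zero. With `u = (t - latency) / (peak - latency)`
#' the kernel is `amp * u^shape * exp(shape * (1 - u))`, i.e. a
#' peak-normalized gamma-density profile.
#'
#' @param t_since_onset Time(s) since stimulus onset (s); values below the
#'   latency (including negative times) map to 0.
#' @param latency_s Response onset delay (s).
#' @param peak_s Time-to-peak (s); must exceed `latency_s`.
#' @param amp_pct Peak amplitude (percent units).
#' @param shape Positive shape exponent controlling rise/decay sharpness.
#' @return Numeric vector of percent deviations, same length as
#'   `t_since_onset`.
#' @export
pdr_kernel <- function(t_since_onset, latency_s = 0.3, peak_s = 1.2,
                       amp_pct = 1, shape = 2) {
  for (p in list(latency_s = latency_s, peak_s = peak_s,
                 amp_pct = amp_pct, shape = shape)) {
    if (!is_number(p)) stopf("pdr_kernel parameters must be finite numbers")
  }
  if (peak_s <= latency_s) stopf("peak_s must exceed latency_s")
  if (shape <= 0) stopf("shape must be positive")
  u <- (t_since_onset - latency_s) / (peak_s - latency_s)
  out <- numeric(length(u))
  pos <- !is.na(u) & u > 0
  out[pos] <- amp_pct * u[pos]^shape * exp(shape * (1 - u[pos]))
  out[is.na(u)] <- NA_real_
  out
}

#' Spontaneous pupil fluctuation process
#'
#' Stationary-mean AR(1) noise plus a deterministic sinusoidal drift and a
#' linear trend, in pixel units. The AR(1) component is initialised from
#' its stationary distribution so the series has no startup transient.
#'
#' @param n Number of samples (> 0).
#' @param ar_coeff AR(1) coefficient, `|ar_coeff| < 1`.
#' @param noise_sd_px Innovation SD (px).
#' @param drift_amp_px,drift_period_s,drift_phase Sinusoid amplitude (px),
#'   period (s) and phase (rad).
#' @param lin_trend_px_per_s Linear slope (px/s).
#' @param t Optional sample times (s); defaults to a regular grid at
#'   `rate_hz`.
#' @param rate_hz Sampling rate used when `t` is `NULL`.
#' @param seed Optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return Numeric vector of pixel deviations around zero mean (plus the
#'   deterministic components).
#' @export
spontaneous_process <- function(n, ar_coeff = 0.98, noise_sd_px = 0.6,
                                drift_amp_px = 0, drift_period_s = 90,
                                drift_phase = 0, lin_trend_px_per_s = 0,
                                t = NULL, rate_hz = 62, seed = NULL) {
  if (!is_number(n) || n <= 0 || n != round(n)) stopf("n must be a positive integer")
  if (!is_number(ar_coeff) || abs(ar_coeff) >= 1) {
    stopf("ar_coeff must satisfy |ar_coeff| < 1 (stationarity)")
  }
  n <- as.integer(n)
  if (is.null(t)) t <- (seq_len(n) - 1) / rate_hz
  if (length(t) != n) stopf("t must have length n")
  gen <- function() {
    if (noise_sd_px == 0) return(numeric(n))
    sd_stat <- noise_sd_px / sqrt(1 - ar_coeff^2)
    innov <- stats::rnorm(n, 0, noise_sd_px)
    init <- stats::rnorm(1, 0, sd_stat)
    as.numeric(stats::filter(innov, ar_coeff, method = "recursive", init = init))
  }
  ar <- if (is.null(seed)) gen() else with_seed_(seed, gen())
  drift <- if (drift_amp_px != 0) {
    drift_amp_px * sin(2 * pi * t / drift_period_s + drift_phase)
  } else {
    0
  }
  ar + drift + lin_trend_px_per_s * t
}

# Nominal stimulus schedule implied by a config (onsets in session seconds).
sim_schedule <- function(config) {
  on <- config$first_onset_s + (seq_len(config$n_stimuli) - 1) * config$isi_s
  on[on < config$duration_s]
}

block_of_trial <- function(trial, block_size = 15L) {
  pmin(3L, (as.integer(trial) - 1L) %/% as.integer(block_size) + 1L)
}

# Mark samples falling inside any [start, start + dur) interval.
# Vectorized as a +1/-1 step function over sorted interval edges.
mark_intervals <- function(t, starts, durs) {
  if (!length(starts)) return(logical(length(t)))
  pos <- c(starts, starts + durs)
  step <- rep(c(1L, -1L), each = length(starts))
  ord <- order(pos, -step)  # opens sort before closes at identical positions
  depth <- cumsum(step[ord])
  idx <- findInterval(t, pos[ord])
  idx > 0 & depth[pmax(idx, 1L)] > 0
}

#' Simulate a two-eye pupil recording session
#'
#' Generates left- and right-eye raw sample tables at irregular timestamps,
#' a stimulus event table (empty for the baseline condition, whose nominal
#' schedule is kept as metadata), and a ground-truth table of realized
#' per-trial evoked amplitudes.
#'
#' The two eye streams share the tonic diameter, the slow drift and the
#' evoked response (pupil responses are consensual) but carry independent
#' AR(1) fluctuations, so pooled-eye statistics remain calibrated. In the
#' audio condition the realized amplitude of trial *k* is
#' `pdr_amp_pct * adaptation_factor(block_k) * (1 + coupling_kappa * z_k)`,
#' floored at zero, where `z_k` is the standardized noise-free (drift-only)
#' pre-stimulus deviation, recorded in the truth table.
#'
#' @param config A [sim_config()].
#' @param condition `"audio"` (tones delivered) or `"baseline"` (silence).
#' @return An object of class `sim_session`: a list with elements `left`
#'   and `right` (raw sample tables), `events` (event table), `truth`
#'   (tibble with `trial`, `onset_s`, `block`, `amp_pct`,
#'   `pre_tonic_dev_px`), `schedule`, `tonic_px`, `condition` and `config`.
#' @export
simulate_session <- function(config, condition = c("audio", "baseline")) {
  condition <- match.arg(condition)
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  cfg <- config
  schedule <- sim_schedule(cfg)
  salt <- if (condition == "audio") 101L else 202L

  with_seed_(derive_seed(cfg$seed, salt), {
    tonic <- max(20, stats::rnorm(1, cfg$base_diameter_px, cfg$base_diameter_sd_px))
    drift_phase <- stats::runif(1, 0, 2 * pi)

    # Noise-free pre-stimulus tonic deviation per scheduled trial: mean of
    # the deterministic drift over the 0.5-s window preceding each onset.
    drift_fun <- function(tt) {
      cfg$drift_amp_px * sin(2 * pi * tt / cfg$drift_period_s + drift_phase) +
        cfg$lin_trend_px_per_s * tt
    }
    pre_offsets <- -0.5 + (seq_len(25) - 0.5) / 50
    d_k <- vapply(schedule, function(o) mean(drift_fun(o + pre_offsets)), numeric(1))
    dev <- d_k - mean(d_k)
    z <- if (length(dev) > 1 && stats::sd(dev) > 0) dev / stats::sd(dev) else rep(0, length(dev))
    blk <- block_of_trial(seq_along(schedule))
    amp_k <- if (condition == "audio") {
      pmax(0, cfg$pdr_amp_pct * cfg$adaptation_factors[blk] * (1 + cfg$coupling_kappa * z))
    } else {
      rep(0, length(schedule))
    }

    make_eye <- function(eye) {
      n_est <- ceiling(cfg$duration_s * cfg$raw_rate_hz * 1.2) + 10L
      gaps <- pmax(0.2 / cfg$raw_rate_hz,
                   stats::rnorm(n_est, 1 / cfg$raw_rate_hz, cfg$jitter_sd_s))
      ts <- cumsum(gaps)
      ts <- ts - ts[1]
      ts <- ts[ts < cfg$duration_s]
      n <- length(ts)

      ar <- spontaneous_process(n, cfg$ar_coeff, cfg$noise_sd_px, t = ts)
      diam <- tonic + stats::rnorm(1, 0, 0.01 * tonic) + drift_fun(ts) + ar

      if (condition == "audio" && any(amp_k > 0)) {
        horizon <- cfg$pdr_peak_s + 5 * (cfg$pdr_peak_s - cfg$pdr_latency_s)
        for (k in seq_along(schedule)) {
          if (amp_k[k] == 0) next
          i0 <- findInterval(schedule[k], ts) + 1L
          i1 <- findInterval(schedule[k] + horizon, ts)
          if (i0 > i1) next
          idx <- i0:i1
          diam[idx] <- diam[idx] + tonic / 100 *
            pdr_kernel(ts[idx] - schedule[k], cfg$pdr_latency_s,
                       cfg$pdr_peak_s, amp_k[k], cfg$pdr_shape)
        }
      }

      n_bl <- stats::rpois(1, cfg$blink_rate_per_min * cfg$duration_s / 60)
      bl_start <- stats::runif(n_bl, 0, cfg$duration_s)
      bl_dur <- stats::runif(n_bl, cfg$blink_dur_ms[1], cfg$blink_dur_ms[2]) / 1000
      blink <- mark_intervals(ts, bl_start, bl_dur)

      n_ar <- stats::rpois(1, cfg$artifact_rate_per_min * cfg$duration_s / 60)
      ar_start <- stats::runif(n_ar, 0, cfg$duration_s)
      ar_dur <- stats::runif(n_ar, cfg$artifact_dur_ms[1], cfg$artifact_dur_ms[2]) / 1000
      artifact <- mark_intervals(ts, ar_start, ar_dur) & !blink

      conf <- stats::runif(n, 0.82, 1)
      dip <- stats::runif(n) < cfg$low_conf_rate
      conf[dip] <- stats::runif(sum(dip), 0.3, 0.79)
      occ <- blink | artifact
      conf[occ] <- stats::runif(sum(occ), 0.05, 0.6)
      diam[blink] <- pmax(1, 0.2 * diam[blink])
      diam[artifact] <- diam[artifact] * stats::runif(sum(artifact), 0.6, 1.4)
      diam <- pmax(diam, 0.5)

      audio_flag <- integer(n)
      if (condition == "audio" && length(schedule)) {
        fi <- findInterval(ts, schedule)
        inside <- fi >= 1 & (ts - schedule[pmax(fi, 1L)]) < 0.5
        audio_flag[inside] <- 1L
      }

      raw_sample_table(
        tibble::tibble(timestamp = ts, diameter = diam, confidence = conf,
                       blink = as.integer(blink), artifact = as.integer(artifact),
                       audio = audio_flag),
        eye = eye, subject_id = cfg$subject_id,
        session_id = paste0(cfg$session_id, "_", condition),
        condition = condition, luminance = cfg$luminance
      )
    }

    left <- make_eye("left")
    right <- make_eye("right")

    events <- if (condition == "audio") {
      event_table(schedule)
    } else {
      event_table(numeric(0))
    }
    truth <- tibble::tibble(
      trial = seq_along(schedule), onset_s = schedule, block = blk,
      amp_pct = amp_k, pre_tonic_dev_px = dev
    )
    if (condition == "baseline") truth <- truth[0, ]

    structure(
      list(left = left, right = right, events = events, truth = truth,
           schedule = schedule, tonic_px = tonic,
           condition = condition, config = cfg),
      class = "sim_session"
    )
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s / %s, %d + %d samples, %d events, tonic %.1f px\n",
              x$config$subject_id, x$condition, nrow(x$left), nrow(x$right),
              nrow(x$events), x$tonic_px))
  invisible(x)
}
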
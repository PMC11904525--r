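---
title: "Detecting pupil dilation responses to tones: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pupil dilation responses to tones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrkit)
```

## The measurement problem

A brief tone evokes a transient dilation of the pupil of roughly 1–3 %
of its tonic diameter, peaking one to one and a half seconds after
onset. Spontaneous pupil fluctuations are of the same order or larger,
so "does this subject respond to the tone?" is a statistical question.
The design `pdrkit` supports answers it with a within-subject null: an
equal-length recording without stimulation (*Baseline*), segmented at
the very same schedule instants as the stimulated recording (*Audio*),
provides the distribution of the test statistic in the absence of a
response.

## Preprocessing model

Raw per-eye streams are sampled irregularly (nominally 62 FPS) and
carry a per-sample confidence score plus blink and artifact flags. The
cleaning chain is fixed, in this order:

1. **Reliability**: a sample is unreliable iff its blink flag or
   artifact flag is set or its confidence is below 0.8. The threshold
   is inclusive — exactly 0.8 counts as reliable — because the
   threshold is *defined* as the score at which a measurement is
   classified reliable.
2. **Interpolation**: unreliable diameters are replaced by linear
   interpolation between the nearest reliable neighbours in time.
   Edge runs are filled by constant extension rather than
   extrapolation, which would manufacture trends from endpoint noise.
3. **Resampling** to a regular 50 Hz grid by linear interpolation. A
   grid sample is marked "interpolated" if *either* flanking source
   sample was — deliberately conservative, so the downstream
   interpolation-count QC can only over-count, never under-count.
4. **Detrending**: one least-squares line over the whole recording is
   removed and the grand mean added back. Mean preservation matters
   because the later normalization expresses frames relative to an
   absolute reference (100 %); removing the mean would destroy it.
   Detrending is global rather than per-frame (a per-frame option
   exists but is off by default): per-frame detrending would subtract
   part of the evoked ramp itself.

Permuting masking/interpolation with resampling is not an equivalent
pipeline — unreliable values would leak through the resampler before
being repaired — and the test suite pins the canonical order.

## Frames and the signed-area statistic

Frames are 150 samples (3 s) starting at the grid sample at or before
onset − 0.5 s; sub-sample alignment is not attempted (20 ms granularity
at 50 Hz). The first 25 samples are the pre-stimulus period; frames
with more than 15 interpolated points are discarded (exactly 15 is
kept). Trial indices — and hence adaptation-block labels (1–15, 16–30,
31+) — come from schedule position *before* QC, so discarded frames
never shift block boundaries. Left- and right-eye frames enter the
statistics as separate observations by default; per-trial eye
averaging is available (`pool_frames(..., method = "average")`). With
percent normalization each frame is scaled so its pre-stimulus mean is
exactly 100; with difference normalization it is shifted to exactly 0.
Both modes are provided and give closely corresponding decisions; the
algebraic relation `pct = 100 + 100 · diff / pre_mean` is exact.

The per-frame statistic is the signed area between the trace and its
reference over a post-stimulus window, computed by the rectangle rule
on half-open windows: samples *k* with `start ≤ k/50 < end`, each
contributing `(value − ref)/50`. The rectangle rule was chosen over
trapezoids for two exact properties: the 0.5–2.0 s area equals the sum
of the three 0.5-s partition areas, and a t-test on areas is identical
to a t-test on in-window means (the two quantities differ by a positive
constant factor), which removes any ambiguity about which of the two a
report used. Windows end at 2.0 s; 0.5–1.0, 1.0–1.5, 1.5–2.0 and
0.5–2.0 s form the canonical set.

Audio and Baseline areas are compared with the classical
pooled-variance (Student) unpaired t-test, two-tailed, with
`df = nA + nB − 2` — pooled rather than Welch, matching that df
formula. No multiple-testing correction is applied across the four
windows: a subject is scored as responding when *any* window reaches
p < 0.05, mirroring the detection criterion the pipeline replicates
(an optional Holm flag would be a stricter variant; the default keeps
the replicated criterion). Grand averages pool frames across subjects
and eyes and run the identical tests with the pooled counts.

## Pre-stimulus regression

Per kept frame, the evoked amplitude is the mean percent deviation
from 100 in the 1.0–1.5 s window (around the response peak) and the
predictor is the raw pre-stimulus diameter in px. Percent units cannot
be used for the predictor — normalization pins the pre-window at 100
and would erase all between-trial variation. A matched number of
Baseline control frames is drawn at equal index spacing with a seeded
random offset (an arithmetic progression modulo the pool size), so the
control spans the session uniformly instead of clustering. For pooled
multi-subject fits both variables are first centred on the
subject-by-condition means.

Slope equality is tested by the classical pooled-residual-variance
equality-of-slopes t with `df = n1 + n2 − 4`, which is algebraically
identical to the interaction-term t of the joint model `y ~ x × group`
— the identity is enforced by test. (The simpler
`Δb / √(se₁² + se₂²)` form is *not* identical to the interaction
model and was rejected for that reason.) Correlations are compared by
Fisher r-to-z for independent samples.

Mean reversion makes the Baseline slope genuinely negative: after a
spontaneous dilation the pupil tends to drift back, so high pre-windows
precede lower post-windows even in silence. The scientific claim is
therefore not "the Audio slope is negative" but "the Audio slope is
*steeper*", and the package tests exactly that contrast.

## The synthetic generator

`simulate_session()` emulates the recording conditions rather than any
particular dataset:

| parameter | default | meaning |
|---|---|---|
| `duration_s` | 480 s | session length |
| `raw_rate_hz`, `jitter_sd_s` | 62 FPS, 3 ms | irregular sampling |
| `n_stimuli`, `isi_s`, `first_onset_s` | 120, 4 s, 1 s | tone schedule (onsets 1, 5, …, 477 s) |
| `base_diameter_px` (LL / HL) | 100.6 ± 26.2 / 68.8 ± 17.2 px | tonic diameter by luminance |
| `ar_coeff`, `noise_sd_px` | 0.98, 0.6 px | AR(1) fluctuation (≈0.8 s time constant, ≈3 px stationary SD) |
| `drift_amp_px`, `drift_period_s`, `lin_trend_px_per_s` | 2 px, 90 s, −0.005 | slow arousal drift |
| `blink_rate_per_min`, `blink_dur_ms` | 12, 100–250 ms | blinks (flag + low confidence + occluded diameter) |
| `pdr_amp_pct`, `pdr_latency_s`, `pdr_peak_s`, `pdr_shape` | 1.8 %, 0.3 s, 1.2 s, 2 | evoked kernel |
| `adaptation_factors` | (1, 0, 0.7) | block-wise amplitude factors |
| `coupling_kappa` | −0.3 | pre-stimulus coupling |

The evoked kernel is gamma-shaped,
`amp · u^shape · e^{shape(1−u)}` with `u = (t − latency)/(peak −
latency)`: zero before the latency, unit peak at `peak_s`, smooth
decay — the simplest unimodal family placing the response inside the
0.5–2.0 s analysis region with its peak in the 1.0–1.5 s window.
Trial *k*'s realized amplitude is
`pdr_amp_pct · adaptation_factor(block_k) · (1 + κ·z_k)`, floored at 0,
where `z_k` standardizes the *noise-free* (drift-only) pre-stimulus
deviation; using the noise-free deviation gives recovery tests a
well-defined target uncontaminated by measurement noise. The defaults
— a 1.8 % response in the middle of the plausible 0.9–2.7 % amplitude
range, full adaptation in block 2 with partial recovery in block 3,
negative coupling — reproduce the qualitative phenomenology the
pipeline is designed to detect. Blinks set the flag *and* drop the
confidence below 0.8 while clamping the diameter, so the blink flag and
the confidence rule each independently catch them.

The two eyes share the tonic level, the slow drift and the evoked
response (pupil responses are consensual) but receive *independent*
AR(1) fluctuations. This is a deliberate idealization: with fully
shared noise, pooling eyes would double the nominal sample size without
doubling the information, and no pooled test could be calibrated. Real
eyes are more strongly consensual than the generator's, so on real
recordings eye pooling is somewhat anticonservative — a limitation of
the passing tests, not a property they certify.

What the generator does not emulate: gaze-direction and
fixation-depth effects on apparent diameter, luminance transients,
pixel-to-mm calibration error (everything stays in px), non-stationary
blink clustering, and any between-eye asymmetry of the response.

## Calibration, power and test regimes

The validation suite runs the *entire* pipeline (generation through
detection) as a black box:

* **Type-I calibration** — 500 simulated null subjects
  (`pdr_amp_pct = 0`, all protocol defaults otherwise): each window's
  rejection rate must fall inside the 99 % binomial band around 0.05.
  The slow drift correlates areas of nearby frames, and the t-test
  assumes independence — an assumption the method also makes on real
  data — so calibration is expected to sit near, not below, the nominal
  level.
* **Power monotonicity** — rejection of the 0.5–2.0 s test must be
  non-decreasing over evoked amplitudes 0.5 / 1.5 / 3 % (200
  replicates each).
* **Coupling recovery** — with κ < 0 the Audio slope must be negative
  and steeper than the Baseline-control slope in ≥95 % of 200
  replicates. This property is asserted in a *low-noise regime*
  (`noise_sd_px = 0.05`): at realistic noise levels spontaneous mean
  reversion dominates both slopes and single replicates need not
  separate them — the same reason the Baseline slopes are negative in
  real data. The regime was fixed once, from the observation that the
  reversion contribution scales with the AR variance while the coupling
  contribution does not.
* **Adaptation pattern** — with factors (1, 0, 0.7), blocks 1 and 3
  must be significant and block 2 not, on the 0.5–2.0 s window. The
  *high-power regime* for this check isolates adaptation: 3 %
  amplitude, low noise, no coupling, fixed tonic diameter. Coupling
  and tonic-diameter variability are separate generator features that
  dilute per-block effect sizes (15 trials per block) and are tested
  by their own properties. Because a null block still has a 5 %
  false-positive chance per window, block 2 is bounded by the 99 %
  binomial upper limit at 20 replicates (≤ 0.25) rather than asserted
  to be never significant.

## Numerical conventions and degenerate inputs

* Half-open windows (`start ≤ t < end`) everywhere; frame windows snap
  to the grid sample at or before onset − 0.5 s.
* Zero pooled variance: equal means give `t = 0, p = 1`; unequal means
  give `p = 0` with a warning. Identical paired conditions give
  `p = 1`.
* A constant response vector gives `slope = 0, r = 0`; a constant
  predictor is an error (no fit is meaningful).
* Fewer than two frames on either side of a comparison skips that
  window (or block) with a warning rather than failing the run.
* All randomness derives from integer seeds through a single
  `derive_seed()` mixing function, so a top-level seed reproduces every
  stage, including the baseline control-frame selection.
* Monte-Carlo problem sizes (500 null subjects; 200 replicates per
  power point and for coupling; 20 for the block pattern; 2 000 for
  one-off precision checks during development) keep each validation
  under a few minutes on a single core while leaving binomial
  uncertainty well below the margins being asserted.

## Known limitations

* The pooled t-test treats frames as independent; slow drift (real or
  simulated) induces weak positive dependence, making detection
  slightly liberal. The Baseline-null design bounds, but does not
  remove, this effect.
* Eye pooling assumes approximately independent per-eye noise; see
  above.
* The signed-area statistic integrates the whole window: a response
  whose latency pushes its mass outside 0.5–2.0 s (unusually slow
  responders) loses power; the window set is configurable.
* Percent normalization is undefined for non-positive pre-stimulus
  means; such frames (possible only with pathological input) are
  excluded with a message.
* No mixed-effects modelling of the coupling: pooled centred
  regression follows the replicated analysis; subjects with few frames
  are under-weighted accordingly.
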
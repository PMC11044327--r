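---
title: "Methods: breath-by-breath EIT analysis around a spontaneous breathing trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-by-breath EIT analysis around a spontaneous breathing trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Electrical impedance tomography (EIT) monitors regional lung aeration at the
bedside: a thoracic electrode belt yields a stream of reconstructed pixel
impedance maps (here nominally at 50.2 Hz) in which the global lung-region
signal rises with inspiration and falls with expiration. Around a spontaneous
breathing trial (SBT) — a T-piece weaning test in which positive pressure is
removed and later restored — trends in a handful of EIT-derived parameters
describe how the lung responds: end-expiratory lung impedance (EELI, a
surrogate for end-expiratory lung volume), the tidal impedance swing (ΔZ, a
surrogate for tidal volume), respiratory rate, calibrated minute ventilation,
the rapid shallow breathing index (RSBI), the global inhomogeneity index
(GI), the center of ventilation (CoV), silent spaces and regional
ventilation fractions.

`eitsbt` implements the full chain from raw frame sequences to per-epoch
trend tables: ingestion and alignment, artifact removal, cardiac filtering,
breath segmentation, automated selection of stable tidal-breathing periods,
parameter computation per breath, and epoch-wise summaries (pre-SBT baseline,
five equal SBT epochs, post-SBT), plus a synthetic generator with known
ground truth against which every stage is validated.

# Signal model and preprocessing

The global signal is the sum of pixel impedance over the lung contour. Three
disturbance classes are handled before breath analysis:

**Spike artifacts** (single-frame outliers, e.g. electrode transients) are
frames whose global signal deviates from a short rolling median (0.1 s) by
more than `mad_k = 6` robust standard deviations. The robust scale is the
98th percentile of absolute residuals scaled by `1/qnorm(0.99)` rather than
the raw MAD: on monotone stretches of a breath the median of a window equals
its center sample, so residuals are exactly zero for most frames and a plain
MAD collapses, flagging every breath extremum. The upper-quantile scale
stays calibrated and tolerates spike contamination of up to 2% of frames.
Flagged runs of up to 5 frames are repaired by per-pixel linear
interpolation; longer runs are marked *unrepaired* and disqualify stable
periods that contain them.

**Step artifacts** (sudden, sustained baseline shifts, e.g. belt contact
changes) are detected by comparing the rolling median over 5 s before and
after each frame; shifts above a threshold (default 3× the robust tidal
amplitude estimate, so physiological EELI changes of ±20–30% of ΔZ never
trigger it) are localized to ±1 frame via the largest single-frame jump
nearby. Steps are **not** corrected: they split the recording into segments
across which end-expiratory levels must not be compared, and no stable
period ever spans one.

**Cardiac oscillation** is removed from the global signal by a zero-phase
FFT low-pass with cutoff midway between the spectral respiratory and
cardiac fundamentals (geometric mean with a warning when they are closer
than 0.2 Hz; identity when no cardiac peak is found and none is supplied).
The filter has *exactly* unit gain below its raised-cosine transition band
(half-width one quarter of the smaller cutoff-to-fundamental distance), so
respiratory fundamental and low harmonics pass unattenuated — an IIR
low-pass at these normalized cutoffs does not achieve that, which is why the
filter is built directly on the FFT with mirror padding. Pixel-level tidal
images are computed from unfiltered (artifact-repaired) frames at the
detected extrema, keeping the image indices free of filter ringing.

# Breath segmentation and stable periods

Breaths are alternating troughs (end-expiration) and peaks (end-inspiration)
found by prominence-gated extremum detection: a swing counts only if it
exceeds `prominence_frac = 0.3` times a rolling tidal-amplitude estimate
(5%–95% spread of the baseline-detrended signal over ~30 s windows).
Plateaus are collapsed to their center frame. Breaths shorter than 1 s or
longer than 15 s are discarded.

Per breath, EELI is the filtered signal at the end-expiratory trough, and
the tidal swing ΔZ is the peak value minus the *straight line connecting the
two flanking troughs* evaluated at the peak time. When the end-expiratory
level is steady this equals the plain peak-minus-trough difference; when
EELI moves quickly (right after disconnection or reconnection) the
line-referenced swing removes the first-order baseline contamination from
the volume surrogate, which otherwise biases the post-reconnection ΔZ trend
by several percent.

Stable tidal-breathing periods are maximal runs of consecutive breaths with
coefficient of variation of both swing and duration ≤ `cv_max = 0.25`,
at least `min_breaths = 5` breaths, no step boundary or SBT phase boundary
inside, at most 1% unrepaired artifact frames and at most 5% repaired spike
frames. The whole screen is scale invariant: multiplying the signal by any
constant changes no period boundary.

# Parameters

With `DI_xy` the per-pixel impedance change between the end-inspiratory and
end-expiratory frame (negative pixels retained), over lung pixels only:

- **GI** = Σ|DI_xy − median(DI_lung)| / Σ DI_xy. Zero for perfectly
  homogeneous ventilation; undefined (missing, with a diagnostic) when the
  denominator is non-positive.
- **CoV** is the DI-weighted centroid (negative pixels clipped to zero for
  weighting), expressed in percent of the lung-pixel bounding box per axis;
  0% is ventral/left, 100% dorsal/right (row 0 is ventral; supine
  orientation, so "dependent" = dorsal).
- **Silent spaces**: lung pixels with DI below 10% of the maximum. Silent
  pixels below the CoV line (dorsal) are dependent (DSS), above it
  nondependent (NSS); pixels exactly on the line split evenly with the
  remainder to DSS. FLS = 100 − (NSS + DSS), computed in that order so
  NSS + DSS + FLS ≡ 100 exactly in floating point.
- **Volume calibration**: c (ml/AU) is the mean over stable pre-SBT breaths
  of ventilator tidal volume / ΔZ, with ventilator samples matched to each
  breath's interval ± 1 s (single-point mode uses the first matched breath).
- **Rates and indices**: RR = 60/duration, VT = c·ΔZ,
  MV = RR·VT/1000, RSBI = RR/(VT/1000) (missing when VT ≤ 0).
- **Regional fractions**: share of positive DI in each half of the
  lung-pixel bounding box, split at the midline column (left/right) and
  midline row (ventral/dorsal); pixels exactly on an odd-width midline
  contribute half to each side.

Per-period and per-epoch values are means of per-breath values
(`gi_mode = "per_breath"`, the default). With `gi_mode = "period_image"`
the image indices are instead computed once on the period-averaged tidal
image; averaging suppresses pixel noise before the nonlinear GI, so this
mode gives systematically lower (less noise-inflated) GI on noisy data.
Which variant a study should report is a genuine modelling choice; both are
exposed.

# Epoch trends

The SBT span is cut into five equal-duration, half-open intervals; pre and
post are single epochs. A breath belongs to the interval containing its
end-expiration start time (boundary breaths go to the later interval). An
equal-breath-count mode is available (`epoch_mode = "count"`). Empty epochs
are reported with zero counts rather than dropped; an empty pre-SBT baseline
is an error because every trend is normalized to it:
`pct_change = 100·(mean_epoch − mean_pre)/|mean_pre|` (the absolute value
keeps signs meaningful for negative baselines). The post epoch starts at
reconnection; breaths within the first 30 s are flagged `post_early`
because the tidal swing typically restores within tens of seconds and those
breaths mix the transient with the recovered state.

Group statistics (mixed models, multiple-comparison corrections) are out of
scope by design: `cohort_table()` emits the tidy long-format table
(patient, outcome, phase, parameter, value) those tools consume.

# The synthetic generator

`generate_scenario()` builds a session with complete ground truth. The
pixel signal is

```
x(p, t) = share(p)·EELI(t) + amp(p)·w(t)·s(t) + cardiac(p, t) + noise + artifacts
```

with `w` a raised-cosine breath cycle (inspiratory fraction 0.4, zero slope
at both extrema so end-expiratory troughs are flat, as in ventilated
breathing), `amp` a spatially smooth log-normal random field raised to the
inhomogeneity exponent γ and renormalized to sum to the tidal amplitude
(γ = 0 is perfectly uniform; GI grows monotonically with γ), `share` the
normalized amplitude shape carrying the EELI track, and cardiac a sinusoid
concentrated in a medial heart region whose lung-summed amplitude is an
exact fraction of the tidal swing. EELI phase transitions are exponential
(τ = 8 s). The ventilator log reports exactly `ml_per_au` times the true
per-breath swing, so calibration recovery is measurable to arbitrary
precision. Spikes are single-frame, single-pixel outliers; steps are
sustained global shifts; both are logged in the ground truth.

Default conditions mirror the reference SBT scenario used throughout the
tests: 2 min baseline, 5 min trial, 2 min post; respiratory rate 15 → 25
breaths/min; EELI −20% during the trial with incomplete (−10%) recovery; ΔZ
−15% with full recovery; cardiac 90 beats/min at 20% of ΔZ; pixel noise
0.1 AU (≈1.4% of ΔZ on the global signal); spikes on 1% of frames. A
5-minute trial keeps ≥25 breaths per epoch — ample for stable epoch means —
while a full 30-minute protocol is one configuration change away. The
packaged presets `scenario_success()` (moderate γ, rising during the trial,
flat CO₂) and `scenario_failure()` (high γ throughout, faster and shallower
breathing, CO₂ rising 15 mmHg) encode the qualitative contrast between
trial outcomes at fixed effect sizes.

What the generator does *not* emulate: electrode physics and image
reconstruction (the pipeline starts at reconstructed images), perfusion
signals, weaning-induced pulmonary oedema, posture changes, or realistic
artifact morphology beyond spikes and steps. Passing the recovery tests
therefore demonstrates correctness of the analysis chain under a controlled
signal model, not clinical validity on device data.

# Numerical choices and edge cases

- Timestamps map to frames by nearest-frame with ties toward the earlier
  frame — deterministic and order-preserving.
- Non-finite pixels are replaced by temporal interpolation at ingestion and
  logged; a recording with more than 50% bad frames is rejected outright.
- The even-count median in the GI is the mean of the two central order
  statistics.
- A constant global signal yields an empty breath list, not an error; an
  all-silent tidal image yields FLS = 0 with a warning; GI with
  non-positive denominator and CoV with no positive weight are missing
  values with diagnostics.
- All generator randomness flows from one integer seed through an isolated
  RNG scope; identical seeds give bit-identical sessions.

# Known limitations

- The lung mask is supplied by the user (or the generator); no CT-derived
  contour models or proprietary device formats are read.
- The one-point ml/AU calibration assumes the AU↔ml relation is stable
  across the trial; it can change with airway opening or collapse, so
  absolute volumes during the trial inherit that uncertainty.
- CoV and bounding-box normalization conventions differ between vendors;
  values here are internally consistent but not directly interchangeable
  with proprietary software outputs.
- Per-breath GI on noisy images carries an upward noise bias; compare GI
  values only between analyses using the same `gi_mode` and similar noise
  levels, or prefer `period_image` mode.
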
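---
title: "Video-landmark tremor quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-landmark tremor quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorcv)
```

## The measurement problem

Hand tremor — involuntary rhythmic oscillation of the hand, typically 2–12 Hz —
is clinically characterized by two numbers: its **amplitude** (which drives
disability and maps onto ordinal severity scales such as TETRAS) and its
**peak frequency** (which informs diagnosis). Smartphone video plus a learned
hand-landmark tracker offers an instrument-free way to measure both: the
tracker emits per-frame positions of 21 hand landmarks, and the trajectory of
the middle fingertip (landmark 12) carries the tremor signal.

`tremorcv` implements that measurement pipeline, together with a synthetic
tremulous-hand generator that stands in for a rendered 3D hand and the tracker
networks, so every stage can be validated against known ground truth at desk
scale.

## The amplitude estimator

For a chosen method variant (which trace and which axes enter; see
`method_variants()`), the pipeline is:

1. **Displacement.** The Euclidean distance between the fingertip positions of
   consecutive frames, over the variant's axes. Metric traces are converted to
   millimeters (`world_m` × 1000); pixel and frame-normalized traces pass
   through the fiducial-marker calibration (below).
2. **Band-pass.** A 4th-order Butterworth band-pass, 2–10 Hz, applied forward
   and backward (zero phase) to the per-axis *positions*. The low edge removes
   drift and voluntary motion, the high edge tracking noise. Zero-phase
   filtering preserves the timing of motion reversals.
3. **Turning points.** Motion reversals are the local minima of the
   displacement computed from the filtered positions, with an enforced minimum
   separation of `sample_rate / (2 * high)` samples — no two reversals within
   half a cycle of the fastest passband tremor.
4. **Swings.** A swing is the motion between two consecutive turning points;
   its amplitude is the sum of the *unfiltered* displacement over the interval
   — the path length traveled between reversals. For a pure sinusoid of
   half-amplitude $A$ each swing is the peak-to-peak path $2A$.
5. **Median.** The recording's amplitude estimate is the median over swings,
   robust to occasional tracking outliers; even swing counts average the two
   central values.

A deliberate ordering choice: filtering is applied to positions, not to the
displacement magnitude. The displacement magnitude of an $f$-Hz tremor
oscillates at $2f$; filtering *it* with the same 2–10 Hz band would suppress
any tremor above 5 Hz, including the canonical 6 Hz validation case. Detecting
reversals on filtered-position displacement while summing raw-position
displacement keeps reversal timing noise-robust without losing path length.

### Scale calibration

Pixel and normalized traces are converted to millimeters from the projected
size of a fiducial of known diameter — a 9.5 mm optical motion-capture marker
at the fingertip. `calibrate_scale()` produces componentwise mm-per-px factors
for x and y; displacement components are scaled before the Euclidean norm.
Normalized traces are first denormalized with the frame resolution; the
pseudo-depth channel shares the x-axis scale, following the convention of
normalized-landmark trackers.

### Missing frames

Trackers drop frames; undetected frames carry missing positions end-to-end and
are never zero-filled. Gaps of at most 0.25 s are bridged by linear
interpolation (and counted in `n_interpolated`); longer gaps split the
recording into segments analyzed independently, with swings pooled before the
median — interpolating across a long gap would fabricate path length. Segments
shorter than half a second (or too short to filter) are dropped. When nothing
oscillates — fewer than two usable frames, no in-band motion, fewer than two
turning points — the result is flagged *not estimable* rather than raising an
error, mirroring viewpoints where tracking fails.

## The frequency estimator

Per-axis positions (band-passed 2–10 Hz) feed Welch's method: Hann-windowed
10 s segments, 50% overlap, demeaned, zero-padded 4-fold. Zero-padding
interpolates the spectrum to ≈ 0.025 Hz spacing — frequency errors of clinical
interest are below 0.1 Hz, unreachable from a 30 s recording's native
resolution without interpolation. Per-axis densities are averaged (robust to
viewpoint-dependent axis dominance), local maxima inside the 3–8 Hz
frequency-of-interest band are located, and peaks below 10% of the combined
spectrum's global maximum are discarded; the highest-power qualifying peak
wins. **Absence is a value**: a recording whose tremor does not rise above the
noise floor yields no peak, not an error.

Video-based variants contribute only their x and y axes to the spectrum — the
depth channel of image-based trackers is an estimate of much lower quality and
degrades frequency estimation — while optical motion capture and the IMU use
all three axes. IMU spectra are computed on band-passed accelerations (gravity
sits far below the 2 Hz edge).

## The synthetic scene generator

The generator replaces a rendered hand plus tracker networks with a
statistically equivalent model:

- **Kinematics** (`simulate_hand_trajectory()`): a rigid 21-landmark splayed
  hand whose fingertip displaces by $E(t)\,\sin\phi(t)$ along a configurable
  axis; the envelope $E$ interpolates linearly between start and end
  half-amplitudes (mm) and the phase can accumulate cycle-wise frequency
  jitter. Fingers do not articulate — the pipeline reads only landmark 12, so
  rigid translation carries all consumed information. Defaults: 6 Hz, 30 s,
  120 Hz video rate, tremor along the palm normal (the up/down flap of
  postural tremor with a supported wrist), deterministic tone.
- **Camera** (`project_to_camera()`): pinhole projection from a viewpoint
  sphere (default 1.5 m, 1500 px focal length, 1920×1080), azimuth −90…90°,
  elevation −90° (top-down) … 0° (frontal). The projected extent of the
  9.5 mm fingertip marker is emitted for calibration.
- **Tracking noise** (`apply_tracking_noise()`): per-frame confidence
  $c = \mathrm{clip}(c_0 |\cos\theta|^k + \varepsilon)$ with $\theta$ the
  angle between palm normal and viewing direction — confidence is highest for
  palm-on views and collapses toward frontal views, the qualitative pattern
  learned trackers exhibit (exponent default 2; only the pattern, not the
  exponent, is anchored to observed tracker behavior). Frames below the
  dropout threshold (default 0.3) lose their positions. Localization jitter is
  AR(1)-correlated in time (0.05 s correlation, 1 px / 1 mm marginal SD):
  trackers smooth landmarks across frames, so white per-frame jitter at
  120 fps would misrepresent them and artificially inflate path-sum
  amplitudes.
- **Method emulation** (`synthesize_scene()`): the *normalized* trace is the
  projection divided by frame size plus a pseudo-depth channel scaled like x;
  the *world* trace is camera-frame metric coordinates, centered, with slow
  multiplicative scale noise (cv 10%, ~2 s correlation) emulating the "2.5D"
  scale/depth uncertainty of image-based metric landmark estimates; depth
  channels receive 10× the in-plane jitter. The *pixel* trace has x/y only.
  An OMC-like trace (three markers, 100 Hz, 0.1 mm noise) and an IMU-like
  series (palm acceleration at 200 Hz + gravity + white noise) provide
  co-registered references.
- **Cohort** (`synthesize_cohort()`): per-subject swing amplitudes drawn
  log-uniformly (default 1–100 mm — spanning barely-visible to severe tremor),
  frequencies uniformly (3.5–7.5 Hz), one scene per subject under a common
  camera, and an ordinal TETRAS-like score from the true amplitude via a
  monotone threshold map (`default_tetras_map()`: full points at 1, 10, 30,
  100, 200 mm, half points at geometric midpoints). The map approximates
  published performance-item anchors and is configurable; it is not a clinical
  instrument.

What the generator does **not** emulate: articulated finger pose, appearance-
dependent tracker failures (lighting, skin tone, occlusion), rolling-shutter
and motion blur, tracker-specific bias fields, or correlated multi-landmark
error structure. Passing tests therefore demonstrate the *pipeline's*
correctness and the geometry-driven phenomena (viewpoint trade-offs,
foreshortening, depth-noise sensitivity) — not the field performance of any
particular tracker.

## Experiment runners

- `run_angle_sweep()` re-runs a recording from every viewpoint of the
  half-sphere grid (15° steps by default), recording mean detection accuracy
  (per-frame confidence, undetected frames scored 0 — the generator's analogue
  of a tracker's internal accuracy measure) and the estimated amplitude where
  at least half the frames survive. Frontal cells drop out entirely;
  amplitude and accuracy anti-correlate across estimable cells, since views
  that see the palm best look down the tremor axis.
- `run_ramp_experiment()` scores each variant's z-scored per-swing amplitude
  sequence against a linearly increasing true envelope (Kendall's tau);
  variants that include a depth channel track the envelope less faithfully.
- `run_cohort_experiment()` runs amplitude and frequency estimation for every
  variant over a synthetic cohort and computes the agreement statistics:
  error metrics against the OMC-like ground truth, peak-frequency errors,
  Kendall correlation of log amplitude with the TETRAS-like scores, and the
  systematic-error test (truth vs. error). With the default geometry (camera
  45° above frontal, tremor along the palm normal) the normalized variant
  shows a genuine systematic error: in-plane projection captures only
  $\cos 45° ≈ 0.71$ of the true path, an error proportional to the tremor
  itself, on top of the depth/scale noise.

## Statistics

Kendall's tau is tau-b (tie-corrected) with a two-sided p-value from the
tie-adjusted normal approximation (`stats::cor.test`, exact = FALSE) — cohort
sizes around 20 make the approximation adequate, and rank invariance means log
transforms for display never change tau. Group comparisons screen normality
with Shapiro–Wilk at α = 0.05 and pick the paired t-test or Wilcoxon
signed-rank (one-way ANOVA or Kruskal–Wallis beyond two groups), reporting
which ran. Amplitude errors are summarized as medians with IQRs, absolutely
(mm) and relative to ground truth (%); logs are natural, with no offset —
amplitudes are strictly positive by construction.

## Numerical choices and edge cases

- **Filter edges**: forward–backward filtering is preceded by odd-reflection
  padding (three periods of the low cutoff) and mean removal, suppressing the
  edge transients plain forward–backward filtering leaves; series shorter than
  three filter lengths are rejected.
- **Turning-point ties** resolve to the earliest index (left-strict,
  right-nonstrict window minimum), so exactly symmetric sampling cannot yield
  two reversals in one half-cycle.
- **Oscillation gate**: a segment whose peak filtered displacement is below 5%
  of its median raw displacement (a monotone drift, a static hand) yields no
  turning points — numerically negligible filter ripple must not produce
  spurious swings.
- **Sampling quantization**: at 120 Hz an 8 Hz tremor has 7.5 samples per
  half-cycle; swings alternate between 7- and 8-sample path sums and the
  median can sit ~3% from the continuous-path value. Closed-form validation
  therefore samples its test signals at 240 Hz (integer samples per half-cycle
  across 4–8 Hz); the 120 Hz behavior is tested at its actual magnitude.
- **Degenerate statistics**: all-tied inputs make tau undefined and raise a
  named error; identical groups short-circuit to p = 1; systematic-error tests
  on constant errors surface the degeneracy instead of fabricating a tau.

## Validation problem sizes

The shipped validation suite uses 30 s recordings at 120 Hz (3600 frames),
10 noise seeds for the ramp experiment, a 20-subject cohort for parameter
recovery, and a 30° sweep grid — sizes chosen so the full suite exercises
every stage end-to-end in well under a minute per experiment while leaving
Monte-Carlo margins far wider than the assertion tolerances.

## Known limitations

- Amplitude from a single camera is inherently a projection: out-of-plane
  motion is foreshortened, and the calibration assumes the motion plane sits
  at the fiducial's depth. The systematic-error statistics quantify, but do
  not correct, this.
- The swing decomposition quantizes to the frame grid (see above).
- The TETRAS-like map is an approximation used to give the synthetic cohort a
  plausible ordinal structure.
- Peak-frequency absence depends on the spectral shape of the tracking noise;
  colored noise can place qualifying maxima inside the band for near-zero
  tremor, where a real tracker's failure mode may differ.
- The video adapter (`extract_landmarks_from_video()`) is a seam for an
  external tracking backend; the package's correctness never depends on one
  being present.
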
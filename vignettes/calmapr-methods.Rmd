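---
title: "Methods: calcium optical-mapping metrics and bioprocess analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium optical-mapping metrics and bioprocess analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmapr)
```

# Scope

`calmapr` covers two quantitative workflows that arise when cardiomyocyte
cultures are expanded as 3D aggregates in perfused stirred-tank bioreactors
and then characterized functionally:

1. **Calcium-transient optical mapping.** Fluorescence video stacks of
   calcium-dye-loaded spheroids or monolayers are conditioned into per-pixel
   ΔF/F traces, from which the package computes dominant frequency (DF),
   inter-beat interval (IBI), calcium transient duration at 20/50/70/90%
   repolarization (CaTD~p~), 10–90% upstroke duration, single-beat
   activation maps, conduction velocity (CV), and pacing-capture /
   refractoriness reports.
2. **Bioprocess arithmetic.** Dissolved-oxygen setpoint conversion between
   % O~2~ and % air saturation, constant power-per-volume (P/V) agitation
   scale-up, specific metabolic rates from the perfusion mass balance,
   expansion factors, and Feret-diameter morphometry of aggregate images.

Because raw recordings of this kind are rarely shared, the package ships a
first-class synthetic generator that produces videos, aggregate images and
perfusion series together with their exact ground truth, so every estimator
can be validated end to end.

# The transient model and its ground truth

A single calcium transient is modelled as a cubic smoothstep rise
($s(x) = 3x^2 - 2x^3$) from the diastolic level to the peak, followed by a
single-exponential recovery with time constant $\tau$. The smoothstep was
chosen because it is differentiable (so the maximum-derivative activation
reference is well defined) and its 10–90% rise fraction is analytically
known (0.6082 of the total rise), which ties the `upstroke_duration_s`
parameter exactly to the measurable quantity. Linear and instantaneous
rises are available for closed-form checks.

Ground-truth CaTD~p~ follows from the exponential recovery:

$$\mathrm{CaTD}_p = t_\mathrm{rise} - t_\mathrm{act} +
  \tau \ln\!\frac{100}{100 - p},$$

referenced to the **maximum-derivative activation time** (mid-rise for the
smoothstep), the convention the measurement pipeline also uses. CaTD is
measured from activation rather than from the peak, mirroring action
potential duration conventions; a `reference = "onset"` switch exists in
`catd_analytic()`.

Beat trains are composed as the pointwise maximum of single-beat kernels.
Because the recovery is monotone, only the two most recent beats can attain
the maximum at any instant, so the composition is exact and linear-time,
and a new beat rises smoothly out of the previous recovery tail.

**Refractoriness.** A stimulus elicits a beat only if at least
`refractory_period_s` has elapsed since the previous accepted activation; a
blocked stimulus is skipped entirely (no graded response). This is the
simplest model reproducing the tolerated-vs-refractory contrast seen when
immature aggregates are paced at 3 Hz: with a 0.8 s refractory period only
every third stimulus captures (ratio 1/3), while a 0.2 s period captures
all of them.

**Scenes.** Spheroid (`aggregate`) scenes place a synchronous disc covering
42% of the frame diameter on a dark background, emulating a 128×128-pixel
EMCCD field of view. Monolayer scenes delay each pixel's activation by its
distance from the stimulus origin divided by the conduction velocity;
delays are computed in continuous time before frame sampling, so the
ground-truth CV is exact. The default wavefront is planar (distance along
the propagation axis) with a point-source option; all CV validation uses
plane waves because a curved front is only locally planar. Polarity
`down` inverts the transient around the resting level, modelling
single-excitation Fura-2 imaging at 380 nm where fluorescence falls on
calcium rise (rhod-2 monolayer recordings are polarity `up`). Illumination
heterogeneity (multiplicative gradient), photobleaching (exponential decay
of the whole signal) and i.i.d. Gaussian noise scaled to the transient
amplitude are applied after composition, then frames are quantized to
16-bit camera counts. All randomness flows from one recorded seed;
noise-free scenes are bit-reproducible by construction.

What the generator does **not** emulate: camera-specific noise physics
(EMCCD gain registers, photon shot statistics), motion, ratiometric
acquisition, reentry or spiral waves, and cell-to-cell heterogeneity of
waveform parameters. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under idealized optics, not
robustness to every pathology of real recordings.

# Signal conditioning

Per-pixel traces are processed as: zero-phase moving-average smoothing →
polarity resolution → sliding-percentile baseline removal → pointwise ΔF/F
normalization.

* **Smoothing: 3-frame zero-phase moving average.** A centered (zero-phase)
  window does not shift peak or crossing times. The width was set to 3
  frames because at the 50 fps EMCCD class of acquisition a wider window
  (e.g. 100 ms at 5 frames) becomes comparable to the upstroke itself and
  measurably widens the 10–90% rise and flattens peaks; 3 frames suppresses
  shot noise while keeping both upstroke and CaTD biases well under one
  frame period.
* **Baseline: sliding 10th-percentile window (default 3 s).** A percentile
  tracker is robust to beat-rate changes across protocol segments, unlike a
  global polynomial fit. The window should span at least two beat cycles.
  The baseline is evaluated at coarse anchors and linearly interpolated;
  the half-open edge windows carry a known small bias.
* **ΔF/F: pointwise division by the removed baseline.** Dividing by the
  *local* baseline (not a scalar reference) cancels multiplicative drifts —
  photobleaching and illumination gradients — to first order. Traces whose
  baseline is indistinguishable from zero at the signal scale are treated
  as already normalized and only re-centered, which makes conditioning
  idempotent up to smoothing.
* **Polarity `auto`:** the sign of the skewness of the detrended trace.
  Calcium transients are positively skewed; a downward-pointing trace is
  flipped before baseline removal. An explicit override is available.
* **Masking:** a pixel is analyzable if its temporal mean reaches the given
  quantile of the frame-mean image *and* the peak-to-noise ratio of its
  detrended trace reaches `snr_floor` (default 3; smoothed pure noise
  reaches ≈ 2.2, signal at SNR 8 reaches ≈ 8). Raising the floor can only
  remove pixels.
* **Spatial binning** (2×2 default) is standard optical-mapping practice to
  trade resolution for SNR before per-pixel analysis.

# Beat metrics

`detect_beats()` finds peaks by prominence (≥ 5 noise MADs and ≥ 30% of the
robust trace range) with a minimum spacing, plus a peak-height floor (40%
of the robust range above the 2nd percentile) that rejects noise bumps
riding on recovery tails. Noise is estimated from the MAD of the
first-differenced trace, which is insensitive to the slowly varying signal.

* **Activation time** = time of maximum first derivative on the rising
  limb, refined to sub-frame precision by a three-point parabola through
  the derivative samples. At 50–100 fps, frame quantization would otherwise
  dominate every timing metric.
* **Diastolic level.** The textbook estimate — the median of the
  pre-activation window — is biased upward whenever recovery is incomplete
  at the next beat (fast rates, long CaTD), which in turn biases CaTD
  short by many milliseconds. The package therefore extrapolates each
  inter-beat decay with a Shanks-type three-means estimator: for
  $y = d + A e^{-t/\tau}$ sampled uniformly, the means $m_1, m_2, m_3$ of
  three equal consecutive thirds satisfy
  $d = (m_1 m_3 - m_2^2)/(m_1 + m_3 - 2 m_2)$ exactly, and linear
  zero-phase smoothing rescales $A$ but leaves $d$ untouched. The
  per-trace median of these estimates replaces the valley median whenever
  it is lower; degenerate fits fall back to the valley median.
* **Amplitude.** Smoothing flattens the sharp transient peak, so the peak
  sample underestimates the true amplitude and would bias CaTD long. The
  same decay fit is extrapolated back to the peak time (to the activation
  time itself when the rise spans ≤ 2 samples, where the maximum and the
  activation coincide); implausible extrapolations (outside 0.8–1.6× the
  observed peak) fall back to the observed value. Rising-limb levels (the
  10% and 90% upstroke crossings) use the sampled peak amplitude so both
  crossings always exist on the sampled rise.
* **CaTD~p~** = activation → first interpolated downward crossing of
  `diastole + (1 - p/100) × amplitude` after the peak; flagged `NA` when
  the next activation arrives first (encroachment), never zero-filled.
* **Dominant frequency** = argmax of the zero-padded FFT periodogram within
  0.2–8 Hz on a ≤ 0.02 Hz grid, ties toward the lower frequency; the band's
  lower edge is raised to `2/duration` for short acquisitions. Per-pixel DF
  uses one multi-column FFT pass; a global DF from the mask-mean trace is
  also reported.
* **IBI** uses activation times (peak times optionally) and population SD.

# Activation maps and conduction velocity

`activation_map()` takes the per-pixel maximum-derivative time within a
single-beat window, zero-referenced to the earliest pixel; pixels whose
beat amplitude falls below `snr_floor` × the raw-trace noise are
invalidated, and a map with beats in fewer than half the masked pixels is
rejected. `conduction_velocity()` fits a local plane
$t(x, y) = ax + by + c$ over a radius-3 neighborhood (the standard gradient
method — parameter-light, no streamline tracking) and reports
$1/\sqrt{a^2+b^2}$ per pixel with the fit $R^2$. The default quality floor
$R^2 \ge 0.9$ suits clean data; for noisy recordings a floor of ~0.7 is
appropriate — activation-time noise lowers the local $R^2$ without biasing
the fitted slope, while the floor's real job is rejecting degenerate
(near-synchronous) regions. CV estimates are invariant to a constant shift
of activation times and to the pixel-size/delay rescaling of imaging the
same wave at different magnification.

Reentry and rotor detection are deliberately out of scope; rhythm
regularity is summarized by the scalar index SD(IBI)/mean(IBI) on basal
segments. `capture_report()` counts detected beats against delivered
stimuli per paced segment and flags a segment refractory when the capture
ratio falls below 0.8 — the binary tolerated/refractory outcome is all the
experimental contrast requires.

# Bioprocess computations

* **DO conversion:** % air saturation = % O~2~ / 21 × 100, with the oxygen
  fraction of air fixed at 21.0% (not 20.95%) because that is the
  convention controller setpoints are computed with (10% O~2~ → 47.6%,
  5% → 23.8%, 15% → 71.4%). The inverse round-trips to 1e-12.
* **Scale-up:** constant P/V with $P = N_p \rho N^3 D_i^5$ gives
  $N_\mathrm{target} = \left[(N^3 \rho D_i^5 N_p / V)_\mathrm{source}
  \cdot (V / (\rho D_i^5 N_p))_\mathrm{target}\right]^{1/3}$; rpm↔rev/s
  conversion happens at the interface and both P/V values are returned
  (equal by construction). With identical geometry an 8× volume doubles
  the speed. The published 80 rpm (0.2 L) → 149 rpm (2 L) pair cannot be
  verified numerically because the impeller power numbers and diameters of
  the two vessels are not public; it remains a worked example requiring
  user-supplied geometry.
* **Specific rates:** per sampling interval,
  $q = \left[\Delta C/\Delta t - D\,(C_\mathrm{in} - \bar C_\mathrm{out})
  \right] / \bar X_V$ — the whole bracket over the mean viable-cell
  density, the only dimensionally consistent reading of the mass balance.
  $\bar X_V$ is the arithmetic mean of the interval endpoints (a
  logarithmic mean is available for exponentially growing cultures).
  Production is positive, consumption negative. Units: with C in mM, X in
  cells/mL and t in days, 1 pmol · mL⁻¹ = 10⁻⁶ mM converts q to
  pmol·cell⁻¹·day⁻¹.
* **Forward simulator:** `simulate_perfusion()` integrates
  $dC/dt = qX(t) + D(C_\mathrm{in} - C)$ with $X(t) = X_0 e^{\mu t}$ by
  adaptive stepping (lsoda, rtol 1e-10), matching the washout closed form
  to < 1e-6 relative error; it errors, naming the time, if the trajectory
  goes negative.
* **Expansion factor** = max(X) / X(day 0).

# Aggregate morphometry

Segmentation is global Otsu thresholding (aggregate images are strongly
bimodal; a manual threshold override exists), hole filling, connected
components, and removal of objects below 40 µm equivalent diameter.
Touching aggregates merge into one object — watershed splitting is
deliberately omitted since no splitting procedure is part of the validated
workflow. The maximum Feret diameter is the largest pairwise distance
between convex-hull vertices of the object's pixel centers plus one pixel
width (accounting for the pixel extent; a disc of radius r px measures
≈ 2r px, within ~1%, rotation-invariant to ≤ 1.5%). Quality flags follow
the culture rules: a size-risk flag when the mean or any aggregate exceeds
300 µm (necrotic-core threshold) and an undersampling flag below 200
measured aggregates.

# Validation conditions and problem sizes

The test-suite and the acceptance script regenerate everything from seeds:

* Parameter recovery: 50 videos at 128×128 px, 10 s, 50 fps, per-pixel
  SNR 8, DF drawn uniformly from [0.5, 3] Hz and CaTD50 from
  [200, 800] ms **capped at 80% of the beat cycle** — restitution shortens
  CaTD at fast rates, and the 50% recovery crossing must exist before the
  next beat for the metric to be defined. Upstroke durations are drawn
  from [60, 120] ms. Metrics are measured on the mask-mean trace after 2×2
  binning. Acceptance thresholds: median |DF error| ≤ 0.05 Hz, median
  |CaTD50 error| ≤ 1 frame.
* CV: 64×64 px plane waves at 100 fps, 0.1 mm pixels; exact (≤ 1%)
  noise-free recovery at 20 mm/s, ≤ 10% at SNR 8, and a paired 40%
  reduction (a sodium-channel-blocker-style intervention) recovered as a
  ratio of 0.6 ± 0.1 over six seed pairs.
* Refractoriness: 3 Hz pacing for 5 s (15 stimuli) against 0.8 s vs 0.2 s
  refractory periods; capture ratios 1/3 vs 1, DF 1 Hz vs 3.00 ± 0.05 Hz.
* Perfusion: D = 0.5 day⁻¹ (the culture's operating point), q = −3
  pmol·cell⁻¹·day⁻¹, daily sampling → recovery within 3%; exact against
  the constant-X batch closed form.
* Morphometry: disc (100 px), square (side 100 px) and ellipse
  (120 × 60 px) at 8 rotations.

These sizes keep the full validation run in a few minutes on one CPU while
exercising the estimators at the study's own acquisition geometry.

# Numerical choices and degenerate inputs

* Sub-frame timing everywhere via parabola/linear interpolation; ties in
  the DF periodogram break toward the lower frequency.
* Undefined metrics propagate as `NA` and are counted, never zero-filled —
  zeros would corrupt map summaries.
* Flat traces yield zero beats (not an error); empty masks, pure-noise
  activation windows, non-positive baselines, degenerate geometry, and
  protocols exceeding the video duration raise informative errors.
* Whether the IBI uses activation or peak times is configurable; activation
  times are the default (consistent with the activation-referenced CaTD).
* The refractory bookkeeping in the generator is global (origin-referenced)
  rather than per-pixel; for synchronous spheroids and single plane waves
  the two coincide.

# Known limitations

* The decay-tail diastole/amplitude corrections assume a single-exponential
  recovery; multi-exponential or alternans-bearing recoveries will fall
  back to the (biased) valley median more often.
* Upstroke durations in heavily smoothed, low-frame-rate data retain a
  positive bias of a fraction of a frame (box-filter widening of the rise).
* The Feret estimate assumes convex-ish objects; deeply concave aggregates
  are measured by their convex hull.
* The capture report trusts beat detection; at very low SNR missed beats
  are indistinguishable from capture failure.
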
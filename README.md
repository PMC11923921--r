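# calmapr

Calcium optical-mapping metrics and bioreactor process analytics for
cardiomyocyte aggregate cultures.

## What it is for

Labs that expand human iPSC-derived cardiomyocytes as 3D aggregates in
perfused stirred-tank bioreactors characterize the product functionally by
calcium-transient optical mapping, and steer the process with a handful of
recurring calculations. `calmapr` implements both workflows as tested,
reusable R functions:

* **Optical mapping** — conditioning of fluorescence video stacks into
  per-pixel ΔF/F traces (zero-phase smoothing, sliding-percentile
  detrending, polarity auto-detection, SNR masking, spatial binning), and
  from them: dominant frequency (DF), inter-beat interval (IBI), calcium
  transient duration at 20/50/70/90% repolarization (CaTD₂₀…CaTD₉₀), 10–90%
  upstroke duration, per-pixel metric maps, single-beat activation maps,
  conduction velocity (CV) by local plane fitting of activation times, and
  pacing capture / refractoriness reports.
* **Bioprocess** — dissolved-oxygen setpoint conversion
  (% O₂ ↔ % air saturation), constant power-per-volume agitation scale-up
  (`N_target = [(N³ρD_i⁵N_p/V)_source · (V/(ρD_i⁵N_p))_target]^{1/3}`),
  specific metabolic rates from the perfusion mass balance
  (`q = [ΔC/Δt − D(C_in − C̄_out)] / X̄_V`), expansion factors, and Feret
  diameter morphometry of aggregate images with the 300 µm necrosis-risk
  and 200-object sampling flags.
* **Synthetic data** — a seeded generator for 16-bit calcium videos
  (synchronous spheroids, travelling-wave monolayers, pacing protocols with
  refractoriness, polarity, bleaching, illumination gradients, noise),
  aggregate images and perfusion series, each with serialized ground truth,
  so the whole pipeline is testable without raw recordings.

## Worked example

Simulate a spheroid paced through a basal segment, analyze it, and read the
metrics back:

```r
library(calmapr)

wave  <- waveform_params(upstroke_duration_s = 0.08, decay_tau_s = 0.3,
                         refractory_period_s = 0.3)
scene <- scene_config("aggregate", 128, 128, frame_rate_hz = 50,
                      noise_sd = 1/8, seed = 42)
proto <- pacing_protocol(0, 10, 1, "basal")

sim <- generate_video(scene, wave, proto)
st  <- bin_stack(sim$stack, 2)
tr  <- condition_trace(roi_trace(st, build_mask(st)), 50)

dominant_frequency(tr)
#> [1] 1.000977
beats <- detect_beats(tr)
mean(beats$catd50_ms)
#> [1] 279.2082
sim$truth$catd_ms[["catd50"]]
#> [1] 273.6904
ibi_series(beats)$mean_s
#> [1] 0.9998955
```

The estimated dominant frequency matches the configured 1 Hz to the
periodogram resolution, and the measured CaTD₅₀ sits ~6 ms from the
generator's analytic truth (at 50 fps one frame is 20 ms). A monolayer
scene plus `activation_map()` / `conduction_velocity()` does the same for
wave propagation:

```r
ml  <- scene_config("monolayer", 64, 64, frame_rate_hz = 100,
                    pixel_size_mm = 0.1, cv_mm_s = 20, seed = 1)
sim <- generate_video(ml, wave, pacing_protocol(0, 2, 1, "paced"))
am  <- activation_map(sim$stack, mask = matrix(TRUE, 64, 64),
                      window_s = c(0, 1))
conduction_velocity(am, pixel_size_mm = 0.1)
#> conduction velocity: 20.19 +/- 0.82 mm/s over 4096 pixels
```

Bioprocess one-liners:

```r
do_to_air_saturation(10)            # 47.6  (% air saturation)
expansion_factor(c(0.27e6, 2.1e6))  # 7.78
ps <- simulate_perfusion(q_true = -3, X0 = 0.27e6, mu = 0.2, D = 0.5,
                         Cin = 20, C0 = 18, t_grid = 0:9)
range(specific_rates(ps)$q_pmol_cell_day)
#> [1] -3.020098 -2.997239
```

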
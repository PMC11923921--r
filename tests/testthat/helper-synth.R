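# Shared builders for small synthetic inputs used across tests.

# Standard transient: 80 ms upstroke, 300 ms recovery constant.
std_wave <- function(refractory = 0.3, tau = 0.3, upstroke = 0.08) {
  waveform_params(upstroke, tau, amplitude = 1, diastolic_level = 1,
                  refractory_period_s = refractory)
}

basal_protocol <- function(duration = 10, freq = 1) {
  pacing_protocol(0, duration, freq, "basal")
}

small_aggregate_scene <- function(seed = 1, noise_sd = 0, fps = 50,
                                  side = 64, ...) {
  scene_config("aggregate", side, side, frame_rate_hz = fps,
               noise_sd = noise_sd, seed = seed, ...)
}

monolayer_scene <- function(cv = 20, seed = 1, noise_sd = 0, fps = 100,
                            side = 64, pixel_mm = 0.1) {
  scene_config("monolayer", side, side, frame_rate_hz = fps,
               pixel_size_mm = pixel_mm, cv_mm_s = cv, noise_sd = noise_sd,
               seed = seed)
}

# Analytic trace: beat train sampled from the kernel plus optional noise.
kernel_trace <- function(wave, fps = 50, duration = 10,
                         activations = seq(0.5, duration - 0.5, by = 1),
                         noise_sd = 0, seed = 1) {
  tt <- seq(0, duration - 1 / fps, by = 1 / fps)
  y <- waveform_kernel(wave, tt, activations = activations)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd * wave$amplitude)
  }
  y
}

skewness_of <- function(x) {
  z <- x - mean(x)
  mean(z^3) / (sqrt(mean(z^2))^3)
}

# Waveform whose analytic CaTD50 (max-derivative reference) equals the
# requested value, given the upstroke duration.
wave_for_catd50 <- function(catd50_ms, upstroke = 0.08, ...) {
  frac <- 1 - 2 * uniroot(function(x) 3 * x^2 - 2 * x^3 - 0.1,
                          c(0, 0.5), tol = 1e-14)$root
  t_half <- upstroke / frac / 2
  tau <- (catd50_ms / 1000 - t_half) / log(2)
  waveform_params(upstroke, tau, ...)
}
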
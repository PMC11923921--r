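# Pacing protocols: ordered, non-overlapping segments of spontaneous (basal)
# activity or field stimulation at a fixed frequency, mirroring the standard
# optical-mapping acquisition ladder (basal, then 1/2/3/5 Hz).

#' Define a pacing protocol
#'
#' @param start_s Numeric vector of segment start times, seconds.
#' @param duration_s Numeric vector of segment durations, seconds.
#' @param freq_hz Stimulation frequency (paced segments) or spontaneous beat
#'   rate (basal segments), Hz.
#' @param mode Character vector, `"basal"` or `"paced"` per segment.
#' @return A data frame of class `pacing_protocol` with one row per segment.
#' @examples
#' # 5-s acquisitions: basal then paced at 1, 2, 3 and 5 Hz
#' standard_protocol <- pacing_protocol(
#'   start_s    = c(0, 5, 10, 15, 20),
#'   duration_s = rep(5, 5),
#'   freq_hz    = c(1, 1, 2, 3, 5),
#'   mode       = c("basal", rep("paced", 4)))
#' @export
pacing_protocol <- function(start_s, duration_s, freq_hz, mode) {
  n <- length(start_s)
  if (length(duration_s) != n || length(freq_hz) != n || length(mode) != n)
    stop("all protocol fields must have the same length")
  if (!all(mode %in% c("basal", "paced")))
    stop("mode must be 'basal' or 'paced'")
  if (any(duration_s <= 0) || any(freq_hz <= 0))
    stop("durations and frequencies must be positive")
  o <- order(start_s)
  start_s <- start_s[o]; duration_s <- duration_s[o]
  freq_hz <- freq_hz[o]; mode <- mode[o]
  if (n > 1 && any(start_s[-1] < (start_s + duration_s)[-n] - 1e-9))
    stop("protocol segments must not overlap")
  structure(data.frame(start_s = start_s, duration_s = duration_s,
                       freq_hz = freq_hz, mode = mode,
                       stringsAsFactors = FALSE),
            class = c("pacing_protocol", "data.frame"))
}

# Stimulus (or spontaneous-beat) times of one segment: evenly spaced at
# 1/freq from the segment start, strictly inside the segment.
segment_stimulus_times <- function(segment) {
  k <- seq(0L, floor(segment$duration_s * segment$freq_hz - 1e-9))
  segment$start_s + k / segment$freq_hz
}

# Number of stimuli a paced segment delivers.
segment_stimulus_count <- function(segment) {
  length(segment_stimulus_times(segment))
}

#' Scene configuration for synthetic calcium videos
#'
#' Describes the imaging scene the generator emulates: a spatially synchronous
#' spheroid (`mode = "aggregate"`, a bright disc on dark background whose
#' pixels all share the activation schedule) or a monolayer supporting a
#' travelling wave (`mode = "monolayer"`, per-pixel activation delayed by
#' distance from the stimulus origin divided by the conduction velocity).
#'
#' @param mode `"aggregate"` or `"monolayer"`.
#' @param height_px,width_px Frame dimensions in pixels (>= 8).
#' @param frame_rate_hz Acquisition rate, frames per second.
#' @param pixel_size_mm Pixel pitch at the sample plane, mm/pixel.
#' @param cv_mm_s Conduction velocity, mm/s (monolayer only).
#' @param stim_origin_px Stimulus origin, `c(row, col)` in pixels.
#' @param wave_geometry `"plane"` (delay grows with axial distance from the
#'   origin column; default) or `"point"` (radial distance from the origin).
#' @param polarity `"up"` (fluorescence rises on calcium rise, e.g. rhod-2) or
#'   `"down"` (single-excitation Fura-2 at 380 nm: fluorescence falls).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the transient
#'   amplitude, applied per pixel and frame.
#' @param bleach_tau_s Photobleaching time constant, seconds; `Inf` disables.
#' @param illumination_rel_range Relative peak-to-peak range of a smooth
#'   multiplicative illumination gradient across the field (0 = uniform).
#' @param seed Integer seed controlling all randomness of the scene.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(mode = c("aggregate", "monolayer"),
                         height_px = 128, width_px = 128,
                         frame_rate_hz = 50, pixel_size_mm = 0.05,
                         cv_mm_s = NULL, stim_origin_px = c(1, 1),
                         wave_geometry = c("plane", "point"),
                         polarity = c("up", "down"),
                         noise_sd = 0, bleach_tau_s = Inf,
                         illumination_rel_range = 0, seed = 1L) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  wave_geometry <- match.arg(wave_geometry)
  if (height_px < 8 || width_px < 8) stop("frame dimensions must be >= 8 px")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (mode == "monolayer") {
    if (is.null(cv_mm_s) || cv_mm_s <= 0)
      stop("cv_mm_s must be positive in monolayer mode")
    if (is.null(pixel_size_mm) || pixel_size_mm <= 0)
      stop("pixel_size_mm must be positive in monolayer mode")
  }
  structure(list(mode = mode, height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 frame_rate_hz = frame_rate_hz,
                 pixel_size_mm = pixel_size_mm, cv_mm_s = cv_mm_s,
                 stim_origin_px = stim_origin_px,
                 wave_geometry = wave_geometry, polarity = polarity,
                 noise_sd = noise_sd, bleach_tau_s = bleach_tau_s,
                 illumination_rel_range = illumination_rel_range,
                 seed = as.integer(seed)),
            class = "scene_config")
}
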
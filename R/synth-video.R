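# Synthetic calcium-transient video generator.  Emulates 16-bit EMCCD
# acquisitions of beating cardiomyocyte spheroids (spatially synchronous
# transients) and monolayers (travelling waves at a configured conduction
# velocity), under a pacing protocol with refractoriness, and serializes the
# ground truth needed to score every downstream metric.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a fluorescence video stack
#'
#' @param frames Numeric array `height x width x frames` of intensities
#'   (arbitrary camera units; all finite).
#' @param frame_rate_hz Acquisition rate, frames/s.
#' @param pixel_size_mm Pixel pitch, mm/pixel, or `NULL` if unknown.
#' @param polarity `"up"`, `"down"`, or `"auto"`.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate_hz, pixel_size_mm = NULL,
                        polarity = "auto") {
  if (length(dim(frames)) != 3) stop("frames must be a H x W x T array")
  if (dim(frames)[3] < 2) stop("a video stack needs at least 2 frames")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (any(!is.finite(frames))) stop("frame intensities must all be finite")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_mm = pixel_size_mm, polarity = polarity),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_stack: %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, d[3] / x$frame_rate_hz))
  if (!is.null(x$pixel_size_mm))
    cat(sprintf("  pixel size: %g mm; polarity: %s\n",
                x$pixel_size_mm, x$polarity))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

# Per-pixel activation delay map (seconds) for a scene; NA outside the
# active region (aggregate background).
.delay_map <- function(scene) {
  H <- scene$height_px; W <- scene$width_px
  if (scene$mode == "aggregate") {
    r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
    rad <- 0.42 * min(H, W)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    inside <- (rr - r0)^2 + (cc - c0)^2 <= rad^2
    d <- matrix(NA_real_, H, W)
    d[inside] <- 0
    return(d)
  }
  org <- scene$stim_origin_px
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist_px <- if (scene$wave_geometry == "plane") abs(cc - org[2])
             else sqrt((rr - org[1])^2 + (cc - org[2])^2)
  dist_px * scene$pixel_size_mm / scene$cv_mm_s
}

# Resolve the accepted activation schedule under the refractoriness rule:
# a stimulus (or spontaneous beat) fires only if at least refractory_period_s
# has elapsed since the last accepted activation.
.resolve_schedule <- function(protocol, wave) {
  segs <- split(protocol, seq_len(nrow(protocol)))
  last <- -Inf
  accepted <- numeric(0)
  seg_rows <- lapply(segs, function(s) {
    cand <- segment_stimulus_times(s)
    ok <- logical(length(cand))
    for (i in seq_along(cand)) {
      if (cand[i] - last >= wave$refractory_period_s - 1e-12) {
        ok[i] <- TRUE
        last <<- cand[i]
      }
    }
    accepted <<- c(accepted, cand[ok])
    data.frame(start_s = s$start_s, duration_s = s$duration_s,
               freq_hz = s$freq_hz, mode = s$mode,
               stimuli = length(cand), beats = sum(ok),
               capture_ratio = sum(ok) / length(cand),
               df_true_hz = if (all(ok)) s$freq_hz
                            else sum(ok) / s$duration_s)
  })
  list(activations = accepted, segments = do.call(rbind, seg_rows))
}

#' Generate a synthetic calcium-transient video with ground truth
#'
#' Composes a beat train from the pacing protocol (respecting the waveform's
#' refractory period), delays it per pixel according to the scene geometry,
#' applies polarity, an illumination gradient, photobleaching and Gaussian
#' noise, and quantizes to 16-bit camera counts.  Per-pixel delays are exact
#' (computed in continuous time before frame sampling), so the ground-truth
#' conduction velocity equals the configured value.
#'
#' @param scene A [scene_config()].
#' @param wave A [waveform_params()].
#' @param protocol A [pacing_protocol()].
#' @param duration_s Video duration, seconds; defaults to the protocol end.
#' @return A list with elements `stack` (a [video_stack()]) and `truth`
#'   (ground-truth list: activation schedule, per-segment capture table and
#'   true dominant frequencies, delay map, analytic CaTD/upstroke, true CV,
#'   and the seed).
#' @export
generate_video <- function(scene, wave, protocol,
                           duration_s = NULL) {
  stopifnot(inherits(scene, "scene_config"), inherits(wave, "waveform_params"),
            inherits(protocol, "pacing_protocol"))
  proto_end <- max(protocol$start_s + protocol$duration_s)
  if (is.null(duration_s)) duration_s <- proto_end
  if (proto_end > duration_s + 1e-9)
    stop("pacing protocol extends beyond the video duration")
  H <- scene$height_px; W <- scene$width_px
  nt <- as.integer(round(duration_s * scene$frame_rate_hz))
  if (nt < 2) stop("video must span at least 2 frames")
  t <- (seq_len(nt) - 1) / scene$frame_rate_hz

  sched <- .resolve_schedule(protocol, wave)
  delay <- .delay_map(scene)
  active <- !is.na(delay)
  d <- delay[active]

  # shifted times for every (active pixel, frame) pair; exact kernel values
  tau <- rep(t, each = length(d)) - rep(d, times = nt)
  v <- .beat_train_shape(tau, sched$activations, wave)
  A <- wave$amplitude; dia <- wave$diastolic_level
  f_active <- if (scene$polarity == "up") dia + A * v else dia + A * (1 - v)

  frames <- matrix(0.1 * dia, nrow = H * W, ncol = nt)
  frames[active, ] <- f_active

  # multiplicative illumination gradient across columns
  if (scene$illumination_rel_range > 0) {
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    ill <- 1 + scene$illumination_rel_range * ((cc - 1) / (W - 1) - 0.5)
    frames <- frames * as.vector(ill)
  }
  # photobleaching of the whole signal
  if (is.finite(scene$bleach_tau_s))
    frames <- frames * rep(exp(-t / scene$bleach_tau_s), each = H * W)

  gain <- 20000 / (dia + A)
  frames <- frames * gain
  if (scene$noise_sd > 0) {
    frames <- frames + with_seed(scene$seed,
      matrix(stats::rnorm(length(frames), sd = scene$noise_sd * A * gain),
             nrow = H * W))
  }
  frames <- round(pmin(pmax(frames, 0), 65535))
  dim(frames) <- c(H, W, nt)

  stack <- video_stack(frames, scene$frame_rate_hz, scene$pixel_size_mm,
                       polarity = scene$polarity)
  truth <- list(
    activations_s = sched$activations,
    segments = sched$segments,
    delay_map_s = delay,
    footprint = active,
    cv_mm_s = if (scene$mode == "monolayer") scene$cv_mm_s else NA_real_,
    catd_ms = stats::setNames(catd_analytic(wave, c(20, 50, 70, 90)),
                              c("catd20", "catd50", "catd70", "catd90")),
    upstroke_s = wave$upstroke_duration_s,
    refractory_period_s = wave$refractory_period_s,
    polarity = scene$polarity,
    seed = scene$seed)
  list(stack = stack, truth = truth)
}
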
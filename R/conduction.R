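# Single-beat activation maps, conduction velocity by local plane fitting of
# activation times (gradient method), and pacing capture / refractoriness
# accounting.

#' Single-beat activation map
#'
#' For each valid pixel, the activation time is the sub-frame time of the
#' maximum temporal derivative of the conditioned trace within the beat
#' window, zero-referenced to the earliest activation.  Pixels without a
#' detectable beat (peak amplitude below `snr_floor` times the raw-trace
#' noise) are invalidated; the map is rejected when fewer than half of the
#' masked pixels show a beat.
#'
#' @param stack A [video_stack()].
#' @param mask An [build_mask()] result, logical matrix, or NULL (defaults).
#' @param window_s `c(t0, t1)` window containing one beat, seconds.
#' @param snr_floor Minimum beat amplitude in units of the per-pixel noise.
#' @return An object of class `activation_map`: `time_ms` (H x W, NA where
#'   invalid), `valid`, `n_masked`, `n_valid`.
#' @export
activation_map <- function(stack, mask = NULL, window_s, snr_floor = 4) {
  stopifnot(inherits(stack, "video_stack"))
  if (is.null(mask)) mask <- build_mask(stack)
  m <- if (inherits(mask, "analysis_mask")) mask$mask else mask
  d <- dim(stack$frames)
  fs <- stack$frame_rate_hz
  X <- traces_matrix(stack)
  fr <- which((seq_len(d[3]) - 1) / fs >= window_s[1] &
              (seq_len(d[3]) - 1) / fs < window_s[2])
  if (length(fr) < 4) stop("beat window spans too few frames")
  valid <- which(as.vector(m))
  Xw <- X[fr, valid, drop = FALSE]
  sigma_raw <- apply(Xw, 2, function(v) stats::mad(diff(v)) / sqrt(2))
  cc <- condition_cols(Xw, fs, polarity = stack$polarity %||% "auto")
  dff <- cc$dff
  amp <- apply(dff, 2, max) - apply(dff, 2, stats::median)
  # noise on the DF/F scale: raw noise over the normalization reference
  ref <- apply(Xw, 2, function(v) stats::quantile(v, 0.1, names = FALSE))
  ref <- pmax(ref, .Machine$double.eps)
  has_beat <- amp >= snr_floor * sigma_raw / ref
  if (sum(has_beat) < 0.5 * length(valid))
    stop(sprintf(paste0("activation map rejected: beat detected in only ",
                        "%d of %d masked pixels"),
                 sum(has_beat), length(valid)))
  der <- apply(dff, 2, diff) * fs
  act <- rep(NA_real_, length(valid))
  for (k in which(has_beat)) {
    i <- which.max(der[, k])
    refn <- .parabolic_refine(der[, k], i)
    act[k] <- (fr[1] - 1 + i - 1 + 0.5 + refn$offset) / fs
  }
  tmap <- matrix(NA_real_, d[1], d[2])
  tmap[valid] <- act * 1000
  tmap <- tmap - min(tmap, na.rm = TRUE)
  structure(list(time_ms = tmap, valid = !is.na(tmap),
                 n_masked = length(valid), n_valid = sum(has_beat)),
            class = "activation_map")
}

#' Conduction velocity from an activation map
#'
#' Fits a local plane `t(x, y) = a x + b y + c` (x, y in mm) over each
#' pixel's neighborhood of activation times and converts the gradient
#' magnitude to a local speed `1 / |grad t|`.  Pixels whose fit explains less
#' than `r2_floor` of the local variance are excluded.
#'
#' @param act_map An [activation_map()].
#' @param pixel_size_mm Pixel pitch, mm/pixel.
#' @param neighborhood_radius_px Half-width of the square fitting window.
#' @param r2_floor Minimum local plane-fit R-squared for acceptance.
#' @param min_points Minimum valid neighbors required to attempt a fit.
#' @return An object of class `cv_result`: `speed_mm_s` (H x W, NA where not
#'   accepted), `r2` map, `mean_mm_s`, `sd_mm_s`, `n_accepted`.
#' @export
conduction_velocity <- function(act_map, pixel_size_mm,
                                neighborhood_radius_px = 3, r2_floor = 0.9,
                                min_points = 10) {
  stopifnot(inherits(act_map, "activation_map"))
  if (is.null(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be a positive number")
  tmap <- act_map$time_ms
  H <- nrow(tmap); W <- ncol(tmap)
  r <- as.integer(neighborhood_radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  speed <- matrix(NA_real_, H, W)
  r2map <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!act_map$valid[i, j]) next
    rr <- i + offs$dr; cc <- j + offs$dc
    inb <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    rr <- rr[inb]; cc <- cc[inb]
    tv <- tmap[cbind(rr, cc)]
    ok <- !is.na(tv)
    if (sum(ok) < min_points) next
    x <- (cc[ok] - j) * pixel_size_mm
    y <- (rr[ok] - i) * pixel_size_mm
    tv <- tv[ok]
    A <- cbind(x, y, 1)
    fit <- tryCatch(solve(crossprod(A), crossprod(A, tv)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    res <- tv - A %*% fit
    sst <- sum((tv - mean(tv))^2)
    if (sst <= 0) next                     # synchronous: no gradient to fit
    r2 <- 1 - sum(res^2) / sst
    g <- sqrt(fit[1]^2 + fit[2]^2)         # ms per mm
    if (g <= 0) next
    r2map[i, j] <- r2
    if (r2 >= r2_floor) speed[i, j] <- 1000 / g
  }
  acc <- which(!is.na(speed))
  if (length(acc) < 10)
    stop(sprintf(paste0("conduction velocity undefined: only %d pixels ",
                        "passed the plane-fit quality floor"), length(acc)))
  structure(list(speed_mm_s = speed, r2 = r2map,
                 mean_mm_s = mean(speed[acc]),
                 sd_mm_s = stats::sd(speed[acc]),
                 n_accepted = length(acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("conduction velocity: %.2f +/- %.2f mm/s over %d pixels\n",
              x$mean_mm_s, x$sd_mm_s, x$n_accepted))
  invisible(x)
}

#' Pacing capture and refractoriness report
#'
#' Compares detected beats against the stimuli each paced segment delivered:
#' capture ratio = detected beats / expected stimuli, with a refractory flag
#' when the ratio falls below the threshold.  Basal segments get a rhythm
#' regularity index, SD(IBI)/mean(IBI).
#'
#' @param beats A [detect_beats()] table or numeric activation times, s.
#' @param protocol The [pacing_protocol()] used during acquisition.
#' @param refractory_flag_threshold Capture ratio below which a paced
#'   segment is flagged refractory (default 0.8).
#' @return A data frame of class `capture_report`, one row per segment:
#'   `mode`, `freq_hz`, `stimuli`, `beats`, `capture_ratio`,
#'   `refractory_flag`, `regularity_index`.
#' @export
capture_report <- function(beats, protocol, refractory_flag_threshold = 0.8) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  times <- if (is.numeric(beats)) beats else beats$activation_time_s
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    s <- protocol[i, ]
    inseg <- times[times >= s$start_s - 1e-9 &
                   times < s$start_s + s$duration_s]
    expected <- segment_stimulus_count(s)
    ratio <- length(inseg) / expected
    reg <- NA_real_
    if (s$mode == "basal" && length(inseg) >= 3) {
      iv <- diff(inseg)
      reg <- sqrt(mean((iv - mean(iv))^2)) / mean(iv)
    }
    data.frame(mode = s$mode, freq_hz = s$freq_hz, stimuli = expected,
               beats = length(inseg), capture_ratio = ratio,
               refractory_flag = s$mode == "paced" &
                 ratio < refractory_flag_threshold,
               regularity_index = reg)
  })
  structure(do.call(rbind, rows),
            class = c("capture_report", "data.frame"))
}
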
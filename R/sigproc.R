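# Signal conditioning: turn raw camera counts into analyzable per-pixel
# ΔF/F traces.  Zero-phase smoothing, sliding-percentile baseline removal
# (robust to beat-rate changes across protocol segments), polarity handling,
# SNR-based masking and spatial binning.
#
# Internally per-pixel traces are held as a T x P matrix (time in rows) so
# the same code paths serve single traces and whole stacks.

# T x P trace matrix from a stack (column p = pixel (row, col) in column-major
# order of the H x W frame).
traces_matrix <- function(stack) {
  d <- dim(stack$frames)
  matrix(aperm(stack$frames, c(3, 1, 2)), d[3], d[1] * d[2])
}

# Zero-phase (centered) moving average along time; edges use a truncated
# window so no samples are lost and peak positions are not shifted.
movavg_cols <- function(X, k) {
  if (k <= 1) return(X)
  nt <- nrow(X)
  half <- (k - 1) %/% 2
  cs <- rbind(0, apply(X, 2, cumsum))
  lo <- pmax(seq_len(nt) - half, 1L)
  hi <- pmin(seq_len(nt) + half, nt)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Sliding-window percentile baseline, evaluated at coarse anchors and
# linearly interpolated in between (the baseline varies slowly by design).
rolling_percentile_cols <- function(X, width_frames, q) {
  nt <- nrow(X)
  width_frames <- max(3L, min(as.integer(width_frames), nt))
  half <- width_frames %/% 2
  step <- max(1L, half %/% 2)
  anchors <- unique(c(seq(1L, nt, by = step), nt))
  qv <- vapply(anchors, function(a) {
    rows <- max(1L, a - half):min(nt, a + half)
    apply(X[rows, , drop = FALSE], 2, stats::quantile, probs = q,
          names = FALSE, type = 7)
  }, numeric(ncol(X)))
  qv <- matrix(qv, nrow = ncol(X))          # P x n_anchors
  # linear interpolation of anchor values onto the full time grid
  idx <- findInterval(seq_len(nt), anchors, rightmost.closed = TRUE)
  idx <- pmin(idx, length(anchors) - 1L)
  w <- (seq_len(nt) - anchors[idx]) / (anchors[idx + 1L] - anchors[idx])
  B <- qv[, idx, drop = FALSE] * rep(1 - w, each = ncol(X)) +
       qv[, idx + 1L, drop = FALSE] * rep(w, each = ncol(X))
  t(B)                                      # T x P
}

skewness <- function(x) {
  z <- x - mean(x)
  s <- sqrt(mean(z^2))
  if (s == 0) return(0)
  mean(z^3) / s^3
}

# Matrix backbone of condition_trace(); returns list(dff, baseline, flipped).
condition_cols <- function(X, frame_rate_hz, polarity = "auto",
                           baseline_window_s = 3, smooth_frames = 3,
                           baseline_quantile = 0.1) {
  sm <- movavg_cols(X, smooth_frames)
  flipped <- logical(ncol(X))
  if (polarity == "auto") {
    med <- apply(sm, 2, stats::median)
    sk <- vapply(seq_len(ncol(sm)), function(j) skewness(sm[, j] - med[j]), 0)
    flipped <- sk < 0
  } else if (polarity == "down") {
    flipped <- rep(TRUE, ncol(X))
  }
  width <- round(baseline_window_s * frame_rate_hz)
  base <- matrix(NA_real_, nrow(X), ncol(X))
  if (any(!flipped))
    base[, !flipped] <- rolling_percentile_cols(sm[, !flipped, drop = FALSE],
                                                width, baseline_quantile)
  if (any(flipped))
    base[, flipped] <- rolling_percentile_cols(sm[, flipped, drop = FALSE],
                                               width, 1 - baseline_quantile)
  # DF/F: pointwise division by the removed baseline, which also cancels
  # multiplicative drifts (photobleaching, illumination).  Traces already
  # normalized (baseline indistinguishable from zero at the signal scale)
  # are only re-centered.
  rng <- apply(sm, 2, function(v) diff(stats::quantile(v, c(0.02, 0.98),
                                                       names = FALSE)))
  med_base <- apply(base, 2, stats::median)
  already_norm <- abs(med_base) <= 0.05 * pmax(rng, .Machine$double.eps)
  bad <- !already_norm & apply(base <= 0, 2, any)
  if (any(bad))
    stop("baseline is non-positive for ", sum(bad),
         " trace(s); cannot form DF/F")
  ref <- base
  ref[, already_norm] <- 1
  sgn <- ifelse(flipped, -1, 1)
  dff <- (sm - base) / ref * rep(sgn, each = nrow(X))
  list(dff = dff, baseline = base, flipped = flipped)
}

#' Condition a raw fluorescence trace into ΔF/F
#'
#' Applies zero-phase moving-average smoothing, flips the polarity when the
#' transients point downward (`polarity = "auto"` decides by the sign of the
#' skewness; calcium transients are positively skewed), removes the baseline
#' by a sliding-window percentile, and normalizes by the removed baseline
#' (ΔF/F).  Traces whose baseline is already indistinguishable from zero at
#' the signal scale are treated as pre-normalized and only re-centered.
#'
#' @param values Raw intensity samples on a uniform time grid, or a
#'   [video_stack()] pixel trace.
#' @param frame_rate_hz Sampling rate, frames/s.
#' @param polarity `"up"`, `"down"`, or `"auto"` (default).
#' @param baseline_window_s Sliding-percentile window, seconds; should span
#'   at least two expected beat cycles.
#' @param smooth_frames Width of the zero-phase moving average, frames.
#' @param baseline_quantile Percentile tracked as the diastolic baseline.
#' @return An object of class `ca_trace`: list with `time_s`, `dff`,
#'   `frame_rate_hz`, `flipped`, `baseline`.
#' @export
condition_trace <- function(values, frame_rate_hz, polarity = "auto",
                            baseline_window_s = 3, smooth_frames = 3,
                            baseline_quantile = 0.1) {
  values <- as.numeric(values)
  if (length(values) < 2 * frame_rate_hz)
    stop("trace must span at least 2 s of samples")
  if (any(!is.finite(values))) stop("trace values must be finite")
  cc <- condition_cols(matrix(values, ncol = 1), frame_rate_hz, polarity,
                       baseline_window_s, smooth_frames, baseline_quantile)
  structure(list(time_s = (seq_along(values) - 1) / frame_rate_hz,
                 dff = as.numeric(cc$dff),
                 frame_rate_hz = frame_rate_hz,
                 flipped = cc$flipped[1],
                 baseline = as.numeric(cc$baseline)),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace: %d samples @ %g fps (%.2f s)%s\n",
              length(x$dff), x$frame_rate_hz,
              length(x$dff) / x$frame_rate_hz,
              if (isTRUE(x$flipped)) ", polarity-flipped" else ""))
  invisible(x)
}

#' @export
plot.ca_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$dff, type = "l", xlab = "time (s)",
                 ylab = expression(Delta * F / F), ...)
  invisible(x)
}

#' Build an analysis mask for a video stack
#'
#' A pixel is valid when its temporal mean intensity reaches the given
#' quantile of the frame-mean image and the peak-to-noise ratio of its
#' detrended trace reaches `snr_floor`.
#'
#' @param stack A [video_stack()].
#' @param intensity_quantile Quantile of the frame-mean image used as the
#'   intensity floor (0 keeps all pixels).
#' @param snr_floor Minimum peak-to-noise ratio of the detrended trace.
#' @return An object of class `analysis_mask`: list with logical `mask`
#'   (H x W) and the criteria used.
#' @export
build_mask <- function(stack, intensity_quantile = 0.5, snr_floor = 3) {
  stopifnot(inherits(stack, "video_stack"))
  X <- traces_matrix(stack)
  d <- dim(stack$frames)
  mean_img <- colMeans(X)
  ok_int <- mean_img >= stats::quantile(mean_img, intensity_quantile,
                                        names = FALSE)
  sm <- movavg_cols(X, 3)
  resid <- X - sm
  noise <- sqrt(colMeans(resid^2))
  # detrended peak approximated as max over the slowly varying median level;
  # adequate for a validity mask and fully vectorized
  med <- apply(sm, 2, stats::median)
  peak <- apply(sm, 2, max) - med
  snr <- peak / pmax(noise, .Machine$double.eps)
  ok_snr <- snr >= snr_floor
  mask <- matrix(ok_int & ok_snr, d[1], d[2])
  if (!any(mask))
    stop("empty analysis mask; lower intensity_quantile or snr_floor")
  structure(list(mask = mask, intensity_quantile = intensity_quantile,
                 snr_floor = snr_floor),
            class = "analysis_mask")
}

#' Mean trace over a region of interest
#'
#' Averages the raw pixel traces over the mask (boosting SNR by the pixel
#' count), the standard way to obtain a global trace for whole-preparation
#' metrics.
#'
#' @param stack A [video_stack()].
#' @param mask An [build_mask()] result, a logical matrix, or NULL to
#'   average over every pixel.
#' @return Numeric vector of raw mean intensities, one per frame.
#' @export
roi_trace <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  X <- traces_matrix(stack)
  if (is.null(mask)) return(rowMeans(X))
  m <- if (inherits(mask, "analysis_mask")) mask$mask else mask
  rowMeans(X[, as.vector(m), drop = FALSE])
}

#' Spatially bin a video stack
#'
#' Averages `factor x factor` pixel blocks (standard optical-mapping SNR
#' practice) and scales the pixel size accordingly.  Trailing rows/columns
#' that do not fill a block are dropped.
#'
#' @param stack A [video_stack()].
#' @param factor Integer binning factor (default 2).
#' @return A binned [video_stack()] (intensities are block means, no longer
#'   integer counts).
#' @export
bin_stack <- function(stack, factor = 2L) {
  stopifnot(inherits(stack, "video_stack"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(stack)
  d <- dim(stack$frames)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  fr <- stack$frames[seq_len(H), seq_len(W), , drop = FALSE]
  H2 <- H %/% factor; W2 <- W %/% factor
  dim(fr) <- c(factor, H2, factor, W2, d[3])
  binned <- rowMeans(matrix(aperm(fr, c(2, 4, 5, 1, 3)),
                            H2 * W2 * d[3], factor * factor))
  dim(binned) <- c(H2, W2, d[3])
  out <- stack
  out$frames <- binned
  if (!is.null(stack$pixel_size_mm))
    out$pixel_size_mm <- stack$pixel_size_mm * factor
  out
}

# Bin a logical mask consistently with bin_stack (block majority).
bin_mask <- function(mask, factor = 2L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  d <- dim(mask)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  m <- mask[seq_len(H), seq_len(W)]
  dim(m) <- c(factor, H %/% factor, factor, W %/% factor)
  apply(m, c(2, 4), mean) >= 0.5
}
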
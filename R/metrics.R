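# Per-trace and per-pixel electrophysiology metrics.  Conventions:
#  * activation time = time of maximum first derivative on the rising limb,
#    refined to sub-frame precision by quadratic interpolation (the standard
#    optical-mapping reference);
#  * CaTD_p = time from activation to the first interpolated downward
#    crossing of diastolic + (1 - p/100) * amplitude after the peak,
#    flagged NA when the next activation arrives first;
#  * upstroke duration = 10-90% rise time, linearly interpolated;
#  * undefined metrics propagate as NA, never as zeros.

# Quadratic (3-point parabola) refinement of a discrete extremum at index i;
# returns fractional offset in (-0.5, 0.5] and refined value.
.parabolic_refine <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(list(offset = 0, value = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(list(offset = 0, value = y[i]))
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  off <- max(min(off, 0.5), -0.5)
  list(offset = off,
       value = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * off)
}

# Prominence of each local maximum: height above the higher of the two
# bounding minima (walking out to the nearest higher peak or trace end).
.peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    lmin <- x[p]; i <- p
    while (i > 1 && x[i - 1] <= x[p]) { i <- i - 1; lmin <- min(lmin, x[i]) }
    rmin <- x[p]; i <- p
    n <- length(x)
    while (i < n && x[i + 1] <= x[p]) { i <- i + 1; rmin <- min(rmin, x[i]) }
    x[p] - max(lmin, rmin)
  }, 0)
}

# Interpolated upward crossing of level L on [i1, i2] closest to i2
# (time of last crossing before the peak); NA if never crossed.
.rise_crossing <- function(x, t, L, i1, i2) {
  if (i2 <= i1) return(NA_real_)
  idx <- seq(i1, i2 - 1)
  cross <- idx[x[idx] <= L & x[idx + 1] > L]
  if (length(cross) == 0) return(NA_real_)
  j <- cross[length(cross)]
  t[j] + (L - x[j]) / (x[j + 1] - x[j]) * (t[j + 1] - t[j])
}

# Diastolic level by exponential-tail extrapolation: a Shanks-type
# three-means estimator on one decay segment.  For y = dia + A exp(-t/tau)
# sampled uniformly, the means m1, m2, m3 of three equal consecutive thirds
# satisfy dia = (m1 m3 - m2^2) / (m1 + m3 - 2 m2) exactly; linear zero-phase
# smoothing rescales A but leaves dia untouched.  Returns NA when the
# segment is too short, non-monotone, or numerically degenerate.
.tail_diastole <- function(x, i1, i2) {
  seg <- x[i1:i2]
  n3 <- length(seg) %/% 3
  if (n3 < 2) return(NA_real_)
  m1 <- mean(seg[seq_len(n3)])
  m2 <- mean(seg[n3 + seq_len(n3)])
  m3 <- mean(seg[2 * n3 + seq_len(n3)])
  if (!(m1 > m2 && m2 > m3)) return(NA_real_)
  den <- m1 + m3 - 2 * m2
  if (den <= 1e-6 * (m1 - m3)) return(NA_real_)
  dia <- (m1 * m3 - m2^2) / den
  # sanity: the asymptote must lie at or below the observed tail, and not
  # absurdly far below it
  if (dia > m3 + 0.05 * (m1 - m3) || dia < m3 - 5 * (m1 - m3)) NA_real_
  else dia
}

# Fit A exp(-(i - c1)/tau) to a decay segment (diastole already removed)
# from the same three-means construction; used to extrapolate the true
# transient amplitude back to the peak time, undoing the peak flattening of
# the zero-phase smoother.  Returns NA when degenerate.
.decay_fit <- function(x, i1, i2, dia) {
  y <- x[i1:i2] - dia
  if (length(y) < 6 || y[1] <= 0) return(NULL)
  j2 <- which(y >= 0.15 * y[1])
  j2 <- if (length(j2)) max(j2) else length(y)
  y <- y[seq_len(j2)]
  n3 <- length(y) %/% 3
  if (n3 < 2) return(NULL)
  m1 <- mean(y[seq_len(n3)])
  m2 <- mean(y[n3 + seq_len(n3)])
  m3 <- mean(y[2 * n3 + seq_len(n3)])
  if (!(m1 > m2 && m2 > m3 && m3 > 0)) return(NULL)
  r <- (m3 - m2) / (m2 - m1)
  if (r <= 0.05 || r >= 0.98) return(NULL)
  tau <- -n3 / log(r)                     # samples
  delta <- 1 / tau
  g <- sinh(n3 * delta / 2) / (n3 * sinh(delta / 2))
  list(tau = tau, c1 = i1 + (n3 - 1) / 2, A = m1 / g)
}

# First interpolated downward crossing of level L at or after index i1,
# strictly before index i2; NA if none.
.fall_crossing <- function(x, t, L, i1, i2) {
  if (i2 <= i1) return(NA_real_)
  idx <- seq(i1, i2 - 1)
  cross <- idx[x[idx] >= L & x[idx + 1] < L]
  if (length(cross) == 0) return(NA_real_)
  j <- cross[1]
  t[j] + (L - x[j]) / (x[j + 1] - x[j]) * (t[j + 1] - t[j])
}

#' Detect calcium-transient beats in a conditioned trace
#'
#' Finds peaks whose prominence exceeds `min_prominence_mads` times the MAD
#' noise scale of the detrended trace (plus a fractional-amplitude guard) and
#' that are at least `min_interval_s` apart, then characterizes each beat:
#' sub-frame activation time (maximum-derivative reference), peak time and
#' value, diastolic level, amplitude, 10-90% upstroke duration, and CaTD at
#' 20/50/70/90% repolarization.  The diastolic level is the median of the
#' pre-activation window, replaced by an exponential-tail extrapolation of
#' the inter-beat decays whenever recovery is incomplete at the next beat
#' (the valley level would otherwise overestimate diastole and bias CaTD
#' short).
#'
#' @param trace A `ca_trace` from [condition_trace()].
#' @param min_prominence_mads Prominence floor in units of the noise MAD.
#' @param min_interval_s Minimum spacing between accepted peaks, seconds.
#' @param min_prominence_frac Additional prominence floor as a fraction of
#'   the trace's robust amplitude (guards against noise peaks when the MAD
#'   scale collapses on heavily smoothed traces).
#' @param min_height_frac Peaks must additionally rise above the 2nd
#'   percentile by this fraction of the robust amplitude, rejecting noise
#'   bumps riding on recovery tails.
#' @return A data frame of class `beat_table`, one row per beat, with columns
#'   `activation_time_s`, `peak_time_s`, `amplitude`, `diastolic_level`,
#'   `upstroke_s`, `catd20_ms` .. `catd90_ms` (NA where undefined), plus the
#'   sample indices used.  Zero rows when no beat is found.
#' @export
detect_beats <- function(trace, min_prominence_mads = 5,
                         min_interval_s = 0.25,
                         min_prominence_frac = 0.3,
                         min_height_frac = 0.4) {
  stopifnot(inherits(trace, "ca_trace"))
  x <- trace$dff
  t <- trace$time_s
  fs <- trace$frame_rate_hz
  if (length(unique(round(diff(t), 9))) > 1)
    stop("trace time grid must be uniform")
  n <- length(x)
  empty <- structure(
    data.frame(activation_time_s = numeric(0), peak_time_s = numeric(0),
               amplitude = numeric(0), amplitude_obs = numeric(0),
               diastolic_level = numeric(0),
               upstroke_s = numeric(0), catd20_ms = numeric(0),
               catd50_ms = numeric(0), catd70_ms = numeric(0),
               catd90_ms = numeric(0), peak_idx = integer(0),
               valley_idx = integer(0)),
    class = c("beat_table", "data.frame"))
  peaks <- which(x[-c(1, n)] > x[-c(n - 1, n)] &
                 x[-c(1, n)] >= x[-c(1, 2)]) + 1L
  if (length(peaks) == 0) return(empty)
  prom <- .peak_prominences(x, peaks)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  qq <- stats::quantile(x, c(0.02, 0.98), names = FALSE)
  rng <- qq[2] - qq[1]
  floor_prom <- max(min_prominence_mads * sigma,
                    min_prominence_frac * rng, .Machine$double.eps)
  keep <- prom >= floor_prom & x[peaks] >= qq[1] + min_height_frac * rng
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) == 0) return(empty)
  # enforce minimum spacing, keeping the more prominent peak
  o <- order(prom, decreasing = TRUE)
  sel <- logical(length(peaks))
  for (k in o) {
    if (!any(sel & abs(t[peaks] - t[peaks[k]]) < min_interval_s)) sel[k] <- TRUE
  }
  peaks <- sort(peaks[sel])

  d <- diff(x) * fs                       # derivative at t + dt/2
  nb <- length(peaks)
  valleys <- vapply(seq_len(nb), function(b) {
    lo <- if (b == 1) 1L else peaks[b - 1]
    lo + which.min(x[lo:peaks[b]]) - 1L
  }, 0L)
  # trace-level diastole from the exponential recovery tails; with
  # incomplete recovery between beats the valley level overestimates the
  # true diastole, which the tail extrapolation restores
  skip <- 3L
  dia_tail <- vapply(seq_len(nb), function(b) {
    i1 <- peaks[b] + skip
    i2 <- if (b < nb) valleys[b + 1] else n
    if (i2 - i1 < 6) NA_real_ else .tail_diastole(x, i1, i2)
  }, 0)
  dia_global <- if (all(is.na(dia_tail))) NA_real_
                else stats::median(dia_tail, na.rm = TRUE)

  rows <- lapply(seq_len(nb), function(b) {
    p <- peaks[b]
    v <- valleys[b]
    seg <- if (p - 1 >= v) v:(p - 1) else v
    imax <- seg[which.max(d[seg])]
    ref <- .parabolic_refine(d, imax)
    act_t <- t[imax] + (0.5 + ref$offset) / fs
    pk <- .parabolic_refine(x, p)
    peak_t <- t[p] + pk$offset / fs
    dia_idx <- v:max(v, imax - 1L)
    dia_valley <- stats::median(x[dia_idx])
    dia <- if (!is.na(dia_global) && dia_global <= dia_valley) dia_global
           else dia_valley
    amp <- pk$value - dia
    # amplitude corrected for smoothing-induced peak flattening: the fitted
    # recovery exponential extrapolated back to the peak time
    i2 <- if (b < nb) valleys[b + 1] else n
    if (i2 - (p + skip) >= 6) {
      fitd <- .decay_fit(x, p + skip, i2, dia)
      if (!is.null(fitd)) {
        # extrapolation target: the true transient maximum.  For a rise
        # resolved over several samples the refined sample peak is the best
        # estimate; for a near-instantaneous rise (<= 2 samples) the maximum
        # coincides with the activation time itself.
        tgt <- if (p - imax <= 2) act_t * fs + 1 else p + pk$offset
        extra <- (fitd$c1 - tgt) / fitd$tau
        if (extra > 0 && extra < 1.5) {
          amp_ext <- fitd$A * exp(extra)
          if (amp_ext > 0.8 * amp && amp_ext < 1.6 * amp) amp <- amp_ext
        }
      }
    }
    # rising-limb levels use the sampled peak amplitude so both crossings
    # are guaranteed to exist on the sampled rise
    amp_obs <- x[p] - dia
    t10 <- .rise_crossing(x, t, dia + 0.1 * amp_obs, v, p)
    t90 <- .rise_crossing(x, t, dia + 0.9 * amp_obs, v, p)
    ups <- if (is.na(t10) || is.na(t90) || t90 <= t10) NA_real_ else t90 - t10
    # recovery search ends at the following beat's rise onset (its valley)
    nxt_v <- if (b < nb) valleys[b + 1] else n
    catd <- vapply(c(20, 50, 70, 90), function(pp) {
      L <- dia + (1 - pp / 100) * amp
      tc <- .fall_crossing(x, t, L, p, nxt_v)
      if (is.na(tc)) NA_real_ else 1000 * (tc - act_t)
    }, 0)
    data.frame(activation_time_s = act_t, peak_time_s = peak_t,
               amplitude = amp, amplitude_obs = amp_obs,
               diastolic_level = dia, upstroke_s = ups,
               catd20_ms = catd[1], catd50_ms = catd[2],
               catd70_ms = catd[3], catd90_ms = catd[4],
               peak_idx = p, valley_idx = v)
  })
  structure(do.call(rbind, rows), class = c("beat_table", "data.frame"))
}

#' 10-90% upstroke duration of one beat
#'
#' @param trace The `ca_trace` the beat was detected in.
#' @param beat One row of a [detect_beats()] table.
#' @return Rise time in seconds, or NA when the rising limb does not bracket
#'   both crossings.
#' @export
upstroke_duration <- function(trace, beat) {
  x <- trace$dff; t <- trace$time_s
  a <- if (!is.null(beat$amplitude_obs)) beat$amplitude_obs else beat$amplitude
  t10 <- .rise_crossing(x, t, beat$diastolic_level + 0.1 * a,
                        beat$valley_idx, beat$peak_idx)
  t90 <- .rise_crossing(x, t, beat$diastolic_level + 0.9 * a,
                        beat$valley_idx, beat$peak_idx)
  if (is.na(t10) || is.na(t90) || t90 <= t10) NA_real_ else t90 - t10
}

#' Calcium transient duration of one beat at p% repolarization
#'
#' Time from the beat's activation to the first interpolated downward
#' crossing of `diastolic + (1 - p/100) * amplitude` after the peak; NA
#' (flagged undefined) if the next activation occurs first.
#'
#' @param trace The `ca_trace` the beat was detected in.
#' @param beat One row of a [detect_beats()] table.
#' @param p Repolarization percentage in (0, 100).
#' @param next_activation_idx Sample index bounding the recovery search
#'   (default: end of trace).
#' @return CaTD in milliseconds, or NA.
#' @export
catd <- function(trace, beat, p, next_activation_idx = length(trace$dff)) {
  if (p <= 0 || p >= 100) stop("p must lie in (0, 100)")
  L <- beat$diastolic_level + (1 - p / 100) * beat$amplitude
  tc <- .fall_crossing(trace$dff, trace$time_s, L, beat$peak_idx,
                       next_activation_idx)
  if (is.na(tc)) NA_real_ else 1000 * (tc - beat$activation_time_s)
}

#' Inter-beat interval series
#'
#' Successive differences of beat activation times (peak times optionally).
#'
#' @param beats A [detect_beats()] table.
#' @param use `"activation"` (default) or `"peak"` reference times.
#' @return A list with `intervals_s`, `mean_s` and `sd_s` (population SD);
#'   all NA when fewer than two beats.
#' @export
ibi_series <- function(beats, use = c("activation", "peak")) {
  use <- match.arg(use)
  times <- if (use == "activation") beats$activation_time_s
           else beats$peak_time_s
  if (length(times) < 2)
    return(list(intervals_s = numeric(0), mean_s = NA_real_, sd_s = NA_real_))
  iv <- diff(times)
  list(intervals_s = iv, mean_s = mean(iv),
       sd_s = sqrt(mean((iv - mean(iv))^2)))
}

# Shared periodogram backbone: zero-padded FFT power spectrum of the
# mean-removed columns of X; returns list(freq_hz, power matrix).
.periodogram_cols <- function(X, fs, resolution_hz) {
  X <- sweep(X, 2, colMeans(X))
  nfft <- 2^ceiling(log2(max(nrow(X), fs / resolution_hz)))
  pad <- rbind(X, matrix(0, nfft - nrow(X), ncol(X)))
  P <- Mod(stats::mvfft(pad))^2
  keep <- seq_len(nfft %/% 2 + 1)
  list(freq_hz = (keep - 1) * fs / nfft, power = P[keep, , drop = FALSE])
}

#' Dominant frequency of a conditioned trace
#'
#' Frequency of the maximum of the zero-padded periodogram within the
#' physiological band; ties break toward the lower frequency.
#'
#' @param trace A `ca_trace`, or a numeric vector with `frame_rate_hz` given.
#' @param band_hz Search band, Hz (default 0.2-8).
#' @param resolution_hz Maximum frequency-grid spacing after zero padding.
#' @param frame_rate_hz Required when `trace` is a bare numeric vector.
#' @return Dominant frequency, Hz.
#' @export
dominant_frequency <- function(trace, band_hz = c(0.2, 8),
                               resolution_hz = 0.02, frame_rate_hz = NULL) {
  if (inherits(trace, "ca_trace")) {
    x <- trace$dff; fs <- trace$frame_rate_hz
  } else {
    if (is.null(frame_rate_hz)) stop("frame_rate_hz required for raw vectors")
    x <- as.numeric(trace); fs <- frame_rate_hz
  }
  if (length(x) / fs < 2 / band_hz[1])
    stop("trace too short to resolve the lower band edge")
  pg <- .periodogram_cols(matrix(x, ncol = 1), fs, resolution_hz)
  inb <- pg$freq_hz >= band_hz[1] & pg$freq_hz <= band_hz[2]
  f <- pg$freq_hz[inb]
  f[which.max(pg$power[inb, 1])]
}

#' Per-pixel metric maps for a video stack
#'
#' Conditions every valid pixel trace (after optional spatial binning),
#' detects beats and computes per-pixel dominant frequency, mean IBI, CaTD at
#' 20/50/70/90% and upstroke duration, together with mean +/- SD summaries
#' over defined pixels and a global dominant frequency from the mask-mean
#' trace.  Undefined pixels stay NA and are counted, never zero-filled.
#'
#' @param stack A [video_stack()].
#' @param mask An [build_mask()] result, a logical matrix, or NULL to build
#'   one with defaults.
#' @param window_s Optional `c(t0, t1)` restricting analysis to a protocol
#'   segment, seconds.
#' @param bin_factor Spatial binning factor applied first (default 2).
#' @param band_hz,resolution_hz Passed to [dominant_frequency()].  `NULL`
#'   (default) uses 0.2-8 Hz, with the lower edge raised to `2 / duration`
#'   for short acquisitions.
#' @param ... Passed to [detect_beats()].
#' @return An object of class `metric_maps`: matrices `df_hz`, `ibi_s`,
#'   `catd20_ms` .. `catd90_ms`, `upstroke_s`; `mask`; `summary` data frame
#'   (metric, mean, sd, n_defined, n_undefined); `global_df_hz`.
#' @export
metric_maps <- function(stack, mask = NULL, window_s = NULL, bin_factor = 2,
                        band_hz = NULL, resolution_hz = 0.02, ...) {
  stopifnot(inherits(stack, "video_stack"))
  if (bin_factor > 1) {
    if (!is.null(mask)) {
      m0 <- if (inherits(mask, "analysis_mask")) mask$mask else mask
      mask <- bin_mask(m0, bin_factor)
    }
    stack <- bin_stack(stack, bin_factor)
  }
  if (is.null(mask)) mask <- build_mask(stack)
  m <- if (inherits(mask, "analysis_mask")) mask$mask else mask
  if (!any(m)) stop("empty analysis mask")
  d <- dim(stack$frames)
  fs <- stack$frame_rate_hz
  X <- traces_matrix(stack)
  if (!is.null(window_s)) {
    fr <- which((seq_len(d[3]) - 1) / fs >= window_s[1] &
                (seq_len(d[3]) - 1) / fs < window_s[2])
    X <- X[fr, , drop = FALSE]
  }
  valid <- which(as.vector(m))
  if (is.null(band_hz))
    band_hz <- c(max(0.2, 2 / (nrow(X) / fs)), 8)
  cc <- condition_cols(X[, valid, drop = FALSE], fs,
                       polarity = stack$polarity %||% "auto")
  nmap <- function() matrix(NA_real_, d[1], d[2])
  maps <- list(df_hz = nmap(), ibi_s = nmap(), catd20_ms = nmap(),
               catd50_ms = nmap(), catd70_ms = nmap(), catd90_ms = nmap(),
               upstroke_s = nmap())
  # per-pixel dominant frequency in one FFT pass
  pg <- .periodogram_cols(cc$dff, fs, resolution_hz)
  inb <- pg$freq_hz >= band_hz[1] & pg$freq_hz <= band_hz[2]
  fband <- pg$freq_hz[inb]
  maps$df_hz[valid] <- fband[max.col(t(pg$power[inb, , drop = FALSE]),
                                     ties.method = "first")]
  tgrid <- (seq_len(nrow(X)) - 1) / fs
  for (k in seq_along(valid)) {
    tr <- structure(list(time_s = tgrid, dff = cc$dff[, k],
                         frame_rate_hz = fs, flipped = cc$flipped[k]),
                    class = "ca_trace")
    beats <- detect_beats(tr, ...)
    if (nrow(beats) == 0) next
    p <- valid[k]
    maps$ibi_s[p] <- ibi_series(beats)$mean_s
    maps$catd20_ms[p] <- if (all(is.na(beats$catd20_ms))) NA_real_
                         else mean(beats$catd20_ms, na.rm = TRUE)
    maps$catd50_ms[p] <- if (all(is.na(beats$catd50_ms))) NA_real_
                         else mean(beats$catd50_ms, na.rm = TRUE)
    maps$catd70_ms[p] <- if (all(is.na(beats$catd70_ms))) NA_real_
                         else mean(beats$catd70_ms, na.rm = TRUE)
    maps$catd90_ms[p] <- if (all(is.na(beats$catd90_ms))) NA_real_
                         else mean(beats$catd90_ms, na.rm = TRUE)
    maps$upstroke_s[p] <- if (all(is.na(beats$upstroke_s))) NA_real_
                          else mean(beats$upstroke_s, na.rm = TRUE)
  }
  summ <- do.call(rbind, lapply(names(maps), function(nm) {
    vals <- maps[[nm]][valid]
    data.frame(metric = nm, mean = mean(vals, na.rm = TRUE),
               sd = stats::sd(vals[!is.na(vals)]),
               n_defined = sum(!is.na(vals)),
               n_undefined = sum(is.na(vals)))
  }))
  gtr <- structure(list(time_s = tgrid, dff = rowMeans(cc$dff),
                        frame_rate_hz = fs, flipped = FALSE),
                   class = "ca_trace")
  global_df <- dominant_frequency(gtr, band_hz, resolution_hz)
  structure(c(maps, list(mask = m, summary = summ,
                         global_df_hz = global_df)),
            class = "metric_maps")
}

#' @export
print.metric_maps <- function(x, ...) {
  cat("metric_maps over", sum(x$mask), "valid pixels; global DF",
      sprintf("%.2f Hz\n", x$global_df_hz))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
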
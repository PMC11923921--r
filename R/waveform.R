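# Calcium-transient waveform model: smoothstep (cubic) rise to peak followed
# by single-exponential recovery toward the diastolic level.  All ground-truth
# transient durations used by the synthetic generator derive from this kernel
# in closed form.

# Fraction of the total smoothstep rise spent between the 10% and 90% levels.
# s(x) = 3x^2 - 2x^3 on [0,1]; x10 solves s(x) = 0.1 and by symmetry
# x90 = 1 - x10, so the 10-90% fraction is 1 - 2*x10.
.smoothstep_frac_10_90 <- local({
  x10 <- stats::uniroot(function(x) 3 * x^2 - 2 * x^3 - 0.1,
                        c(0, 0.5), tol = 1e-14)$root
  1 - 2 * x10
})

#' Calcium transient waveform parameters
#'
#' Bundles the kinetic parameters of a single calcium transient: the 10-90%
#' rise time of the depolarization limb, the exponential recovery time
#' constant, the fluorescence amplitude above the diastolic level, the
#' diastolic (resting) fluorescence, and the refractory period below which a
#' pacing stimulus fails to elicit a new transient.
#'
#' @param upstroke_duration_s 10-90% rise time of the transient, seconds.
#' @param decay_tau_s Exponential recovery time constant, seconds.
#' @param amplitude Transient amplitude above diastolic, arbitrary
#'   fluorescence units.
#' @param diastolic_level Resting fluorescence level, arbitrary units.
#' @param refractory_period_s Minimum interval since the last activation for a
#'   stimulus to capture, seconds.  Must be at least `upstroke_duration_s`.
#' @param rise_shape Shape of the rising limb: `"smoothstep"` (cubic, default),
#'   `"linear"`, or `"instant"` (step rise; `upstroke_duration_s` is then
#'   bounded only by the sampling interval).
#' @return An object of class `waveform_params`.
#' @examples
#' wp <- waveform_params(0.05, 0.3)
#' catd_analytic(wp, c(20, 50, 70, 90))
#' @export
waveform_params <- function(upstroke_duration_s, decay_tau_s,
                            amplitude = 1, diastolic_level = 1,
                            refractory_period_s = upstroke_duration_s,
                            rise_shape = c("smoothstep", "linear", "instant")) {
  rise_shape <- match.arg(rise_shape)
  vals <- c(upstroke_duration_s = upstroke_duration_s,
            decay_tau_s = decay_tau_s, amplitude = amplitude,
            diastolic_level = diastolic_level,
            refractory_period_s = refractory_period_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all waveform parameters must be finite and strictly positive")
  if (refractory_period_s < upstroke_duration_s)
    stop("refractory_period_s must be >= upstroke_duration_s")
  structure(list(upstroke_duration_s = upstroke_duration_s,
                 decay_tau_s = decay_tau_s,
                 amplitude = amplitude,
                 diastolic_level = diastolic_level,
                 refractory_period_s = refractory_period_s,
                 rise_shape = rise_shape),
            class = "waveform_params")
}

# Total activation-to-peak rise time implied by the 10-90% upstroke duration.
rise_total_s <- function(params) {
  switch(params$rise_shape,
         smoothstep = params$upstroke_duration_s / .smoothstep_frac_10_90,
         linear     = params$upstroke_duration_s / 0.8,
         instant    = 0)
}

# Offset of the maximum-derivative (activation-reference) time from rise
# onset.  Smoothstep: derivative peaks at mid-rise; linear/instant: onset.
activation_offset_s <- function(params) {
  if (params$rise_shape == "smoothstep") rise_total_s(params) / 2 else 0
}

# Normalized single-beat shape (0 at onset, 1 at peak, exponential after),
# evaluated at time dt since rise onset.  Vectorized; dt < 0 -> 0.
.kernel_shape <- function(dt, params) {
  tr <- rise_total_s(params)
  out <- numeric(length(dt))
  if (tr > 0) {
    rising <- dt >= 0 & dt < tr
    x <- dt[rising] / tr
    out[rising] <- switch(params$rise_shape,
                          smoothstep = 3 * x^2 - 2 * x^3,
                          linear = x)
  }
  dec <- dt >= tr
  out[dec] <- exp(-(dt[dec] - tr) / params$decay_tau_s)
  out
}

#' Evaluate the calcium-transient kernel on a time grid
#'
#' Returns the fluorescence trace of transients activated at `activations`
#' (rise onsets, seconds), evaluated at times `t`.  Overlapping transients are
#' combined by taking the pointwise maximum, so a new beat rises smoothly out
#' of the previous beat's recovery tail.
#'
#' @param params A [waveform_params()] object.
#' @param t Ascending numeric vector of times, seconds.
#' @param activations Numeric vector of rise-onset times, seconds.  Default a
#'   single beat at t = 0.
#' @return Numeric vector of fluorescence values
#'   (`diastolic_level + amplitude * shape`).
#' @export
waveform_kernel <- function(params, t, activations = 0) {
  stopifnot(inherits(params, "waveform_params"))
  if (length(t) == 0) return(numeric(0))
  if (is.unsorted(t, strictly = FALSE)) stop("t must be ascending")
  activations <- sort(activations)
  v <- .beat_train_shape(t, activations, params)
  params$diastolic_level + params$amplitude * v
}

# Max-of-kernels evaluation of a whole beat train.  Because the recovery is
# monotone decreasing, only the two most recent beats can attain the maximum
# at any time, so the evaluation is exact and O(length(t)).
.beat_train_shape <- function(t, activations, params) {
  if (length(activations) == 0) return(numeric(length(t)))
  j <- findInterval(t, activations)
  v <- numeric(length(t))
  cur <- j >= 1
  v[cur] <- .kernel_shape(t[cur] - activations[j[cur]], params)
  prev <- j >= 2
  if (any(prev)) {
    vp <- .kernel_shape(t[prev] - activations[j[prev] - 1L], params)
    v[prev] <- pmax(v[prev], vp)
  }
  v
}

#' Analytic calcium transient duration of a waveform
#'
#' Closed-form CaTD at repolarization percentage `p`: the time from the
#' activation reference to the recovery crossing of
#' `diastolic + (1 - p/100) * amplitude`.  The recovery is exponential, so the
#' crossing lies `decay_tau_s * log(100 / (100 - p))` after the peak.
#'
#' @param params A [waveform_params()] object.
#' @param p Repolarization percentage(s) in (0, 100).
#' @param reference `"max_derivative"` (default; the activation convention
#'   used by the measurement pipeline) or `"onset"` (rise onset).
#' @return CaTD in milliseconds, same length as `p`.
#' @export
catd_analytic <- function(params, p, reference = c("max_derivative", "onset")) {
  reference <- match.arg(reference)
  if (any(p <= 0 | p >= 100)) stop("p must lie in (0, 100)")
  tr <- rise_total_s(params)
  off <- if (reference == "max_derivative") activation_offset_s(params) else 0
  1000 * (tr - off + params$decay_tau_s * log(100 / (100 - p)))
}
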
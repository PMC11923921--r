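# Forward simulator of a perfused suspension culture: exponential cell
# growth and a single metabolite obeying the perfusion mass balance
# dC/dt = q * X(t) + D * (Cin - C), the model later inverted by
# specific_rates().  Unit conventions: C in mM, X in cells/mL, q in
# pmol * cell^-1 * day^-1, t in days (1 pmol/mL = 1e-6 mM).

# pmol per mL  ->  mM
.PMOL_PER_ML_TO_MM <- 1e-6

#' Perfusion series container
#'
#' @param t_day Sampling times, days (strictly ascending).
#' @param conc_mM Metabolite concentration in the culture (outlet), mM.
#' @param cells_per_ml Viable cell density, cells/mL (> 0).
#' @param cin_mM Feed concentration, mM.
#' @param dilution_per_day Dilution rate D, 1/day (>= 0).
#' @return An object of class `perfusion_series`.
#' @export
perfusion_series <- function(t_day, conc_mM, cells_per_ml, cin_mM,
                             dilution_per_day) {
  n <- length(t_day)
  if (length(conc_mM) != n || length(cells_per_ml) != n)
    stop("time, concentration and cell series must have equal length")
  if (n > 1 && any(diff(t_day) <= 0)) stop("t_day must be strictly ascending")
  if (any(cells_per_ml <= 0)) stop("cell densities must be positive")
  if (dilution_per_day < 0) stop("dilution rate must be >= 0")
  structure(list(t_day = t_day, conc_mM = conc_mM,
                 cells_per_ml = cells_per_ml, cin_mM = cin_mM,
                 dilution_per_day = dilution_per_day),
            class = "perfusion_series")
}

#' Simulate a perfused-culture metabolite trajectory
#'
#' Integrates `dC/dt = q X(t) * 1e-6 + D (Cin - C)` with
#' `X(t) = X0 exp(mu t)` by adaptive stepping (lsoda), samples at `t_grid`,
#' and optionally adds Gaussian measurement noise to the concentrations.
#'
#' @param q_true Specific rate, pmol per cell per day (production positive,
#'   consumption negative).
#' @param X0 Initial viable cell density, cells/mL.
#' @param mu Specific growth rate, 1/day.
#' @param D Dilution rate, 1/day.
#' @param Cin Feed concentration, mM.
#' @param C0 Initial culture concentration, mM.
#' @param t_grid Sampling times, days (ascending, starting at the first time).
#' @param noise_sd SD of additive Gaussian noise on sampled concentrations,
#'   mM (0 = none).
#' @param seed Seed for the measurement noise.
#' @return A [perfusion_series()] carrying the true parameters as attributes
#'   `q_true`, `mu`, `X0`.
#' @export
simulate_perfusion <- function(q_true, X0, mu, D, Cin, C0, t_grid,
                               noise_sd = 0, seed = 1L) {
  if (D < 0) stop("dilution rate must be >= 0")
  if (X0 <= 0) stop("X0 must be positive")
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be ascending with at least 2 points")
  deriv <- function(t, y, parms) {
    X <- X0 * exp(mu * t)
    list(q_true * X * .PMOL_PER_ML_TO_MM + D * (Cin - y[1]))
  }
  sol <- deSolve::ode(y = c(C = C0), times = t_grid, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  C <- sol[, "C"]
  if (any(C < 0)) {
    t_neg <- t_grid[which(C < 0)[1]]
    stop(sprintf("simulated concentration became negative at t = %g days",
                 t_neg))
  }
  if (noise_sd > 0)
    C <- C + with_seed(seed, stats::rnorm(length(C), sd = noise_sd))
  X <- X0 * exp(mu * t_grid)
  out <- perfusion_series(t_grid, as.numeric(C), X, cin_mM = Cin,
                          dilution_per_day = D)
  attr(out, "q_true") <- q_true
  attr(out, "mu") <- mu
  attr(out, "X0") <- X0
  out
}
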
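# Stirred-tank bioreactor process calculations: dissolved-oxygen setpoint
# conversion, constant power-per-volume agitation scale-up, perfusion
# mass-balance specific metabolic rates, and the expansion factor.
# Internal units are SI; interfaces use rpm, mM, cells/mL and days.

# Oxygen fraction of air, % v/v.  21.0 (not 20.95) reproduces the standard
# controller setpoint arithmetic (10% O2 = 47.6% air saturation) exactly.
.O2_IN_AIR_PCT <- 21.0

#' Convert an oxygen percentage to % air saturation
#'
#' Dissolved oxygen controllers are calibrated against medium equilibrated
#' with air, so a headspace oxygen fraction maps linearly to a DO setpoint:
#' `pct_o2 / 21 * 100` % air saturation (10% O2 -> 47.6%, 5% -> 23.8%,
#' 15% -> 71.4%).
#'
#' @param pct_o2 Oxygen concentration, % v/v (0 to `o2_in_air_pct` for
#'   hypoxic-to-normoxic setpoints; values above air are allowed for
#'   enriched headspaces).
#' @param o2_in_air_pct Oxygen fraction of air, % v/v (default 21.0).
#' @return DO setpoint, % air saturation (unrounded; round to one decimal
#'   for reporting).
#' @seealso [air_saturation_to_o2()] for the inverse.
#' @export
do_to_air_saturation <- function(pct_o2, o2_in_air_pct = .O2_IN_AIR_PCT) {
  if (any(pct_o2 < 0)) stop("oxygen percentage must be non-negative")
  pct_o2 / o2_in_air_pct * 100
}

#' Convert a DO setpoint in % air saturation back to % oxygen
#'
#' @param pct_air_sat DO, % air saturation (non-negative).
#' @param o2_in_air_pct Oxygen fraction of air, % v/v (default 21.0).
#' @return Oxygen concentration, % v/v.
#' @export
air_saturation_to_o2 <- function(pct_air_sat,
                                 o2_in_air_pct = .O2_IN_AIR_PCT) {
  if (any(pct_air_sat < 0)) stop("air saturation must be non-negative")
  pct_air_sat / 100 * o2_in_air_pct
}

#' Stirred-tank vessel / impeller specification
#'
#' @param Np Impeller power number, unitless.
#' @param rho Liquid density, kg/m^3.
#' @param Di Impeller diameter, m.
#' @param V Working volume, m^3.
#' @param N_rpm Agitation speed, rpm (optional for the scale-up target).
#' @return An object of class `scaleup_spec`.
#' @export
scaleup_spec <- function(Np, rho, Di, V, N_rpm = NULL) {
  vals <- c(Np = Np, rho = rho, Di = Di, V = V)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Np, rho, Di and V must be finite and strictly positive")
  if (!is.null(N_rpm) && N_rpm <= 0) stop("N_rpm must be positive")
  structure(list(Np = Np, rho = rho, Di = Di, V = V, N_rpm = N_rpm),
            class = "scaleup_spec")
}

#' Impeller power input per working volume
#'
#' `P/V = Np * rho * N^3 * Di^5 / V` with N in rev/s, W/m^3.
#'
#' @param spec A [scaleup_spec()] with `N_rpm` set.
#' @return P/V in W/m^3.
#' @export
power_per_volume <- function(spec) {
  stopifnot(inherits(spec, "scaleup_spec"))
  if (is.null(spec$N_rpm)) stop("spec has no agitation speed")
  N <- spec$N_rpm / 60
  spec$Np * spec$rho * N^3 * spec$Di^5 / spec$V
}

#' Constant-P/V agitation speed for a scale-up target
#'
#' Solves `(Np rho N^3 Di^5 / V)_source = (Np rho N^3 Di^5 / V)_target` for
#' the target speed: the cube root of the source power-per-volume rescaled by
#' the target geometry.  With identical impeller and fluid, an 8-fold volume
#' increase doubles the speed.
#'
#' @param source A [scaleup_spec()] with `N_rpm` set.
#' @param target A [scaleup_spec()] (its `N_rpm`, if any, is ignored).
#' @return A list: `N_rpm` (target speed, rpm), `pv_source_w_m3`,
#'   `pv_target_w_m3` (equal by construction).
#' @export
scaleup_speed <- function(source, target) {
  stopifnot(inherits(source, "scaleup_spec"), inherits(target, "scaleup_spec"))
  pv <- power_per_volume(source)
  N_target <- (pv * target$V / (target$Np * target$rho * target$Di^5))^(1 / 3)
  tgt <- target
  tgt$N_rpm <- N_target * 60
  list(N_rpm = tgt$N_rpm,
       pv_source_w_m3 = pv,
       pv_target_w_m3 = power_per_volume(tgt))
}

#' Specific metabolic rates from a perfusion series
#'
#' Inverts the perfusion mass balance over each consecutive sampling
#' interval:
#' `q = (dC/dt - D (Cin - Cout_bar)) / Xv_bar`
#' with `Cout_bar` the interval mean of the sampled culture concentration and
#' `Xv_bar` the interval mean of the viable cell density (arithmetic by
#' default, logarithmic optionally for exponentially growing cultures).
#' Production is positive, consumption negative.
#'
#' @param series A [perfusion_series()].
#' @param cell_mean `"arithmetic"` (default) or `"logarithmic"` interval
#'   mean of the cell density.
#' @return A data frame of class `specific_rate`: `t_start_day`, `t_end_day`,
#'   `q_pmol_cell_day`.
#' @export
specific_rates <- function(series,
                           cell_mean = c("arithmetic", "logarithmic")) {
  stopifnot(inherits(series, "perfusion_series"))
  cell_mean <- match.arg(cell_mean)
  n <- length(series$t_day)
  if (n < 2) stop("at least two samples are needed")
  i <- seq_len(n - 1)
  dt <- diff(series$t_day)
  dC <- diff(series$conc_mM)
  Cbar <- (series$conc_mM[i] + series$conc_mM[i + 1]) / 2
  X1 <- series$cells_per_ml[i]; X2 <- series$cells_per_ml[i + 1]
  Xbar <- if (cell_mean == "arithmetic") (X1 + X2) / 2
          else ifelse(X1 == X2, X1, (X2 - X1) / log(X2 / X1))
  if (any(Xbar == 0)) stop("interval mean cell density is zero")
  q_raw <- (dC / dt - series$dilution_per_day * (series$cin_mM - Cbar)) / Xbar
  # mM * mL / cell / day  ->  pmol / cell / day
  q <- q_raw / .PMOL_PER_ML_TO_MM
  structure(data.frame(t_start_day = series$t_day[i],
                       t_end_day = series$t_day[i + 1],
                       q_pmol_cell_day = q),
            class = c("specific_rate", "data.frame"))
}

#' Expansion factor of a cell-density series
#'
#' Ratio of the maximum viable-cell concentration to the concentration at
#' day 0 (the first sample).
#'
#' @param cells_per_ml Viable cell densities over the culture, cells/mL.
#' @return Unitless expansion factor.
#' @examples
#' expansion_factor(c(0.27e6, 0.5e6, 1.0e6))  # 3.7
#' @export
expansion_factor <- function(cells_per_ml) {
  if (length(cells_per_ml) == 0) stop("empty cell-density series")
  if (cells_per_ml[1] <= 0) stop("day-0 cell density must be positive")
  max(cells_per_ml) / cells_per_ml[1]
}
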
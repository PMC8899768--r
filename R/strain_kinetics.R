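# Per-compartment strain activity: Michaelis-Menten consumption modified by
# dynamic gastric acid damage, its lasting carryover downstream, oxygen
# inhibition, and extended colonic activity.

#' Gastric pH at time t after a meal
#'
#' @param t Time since the meal (min); vectorized.
#' @param curve A [gastric_ph_curve()] object.
#' @return pH values, monotone non-increasing in `t`.
#' @export
gastric_ph <- function(t, curve = gastric_ph_curve()) {
  stopifnot(inherits(curve, "gastric_ph_curve"), all(t >= 0))
  curve$ph_fasted + (curve$ph_fed - curve$ph_fasted) *
    2^(-(t / curve$half_time)^curve$shape)
}

#' Activity decay constant at a given pH
#'
#' Linear interpolation of the fitted per-pH exponential decay constants;
#' clamped to the nearest endpoint outside the fitted pH range.
#'
#' @param ph pH value(s) in `[0, 14]`.
#' @param table Data frame with columns `ph`, `k` (1/min).
#' @return Decay constant(s), 1/min.
#' @export
ph_decay_constant <- function(ph, table = default_ph_decay_table()) {
  if (any(ph < 0 | ph > 14)) stop("ph_decay_constant: pH outside [0, 14]")
  stopifnot(nrow(table) >= 2)
  stats::approx(table$ph, table$k, xout = ph, rule = 2)$y
}

#' Cumulative acid damage after time in the stomach
#'
#' Surviving activity fraction `exp(-integral of k(pH(s)) ds)` along the
#' gastric pH trajectory, computed by trapezoidal quadrature on a fine grid.
#' Equals 1 at t = 0 and is non-increasing.
#'
#' @param t_in_stomach Residence time(s) in the stomach (min).
#' @param curve A [gastric_ph_curve()] object.
#' @param table pH decay-constant table.
#' @param dt Quadrature step (min).
#' @return Activity fraction(s) in (0, 1].
#' @export
cumulative_acid_damage <- function(t_in_stomach,
                                   curve = gastric_ph_curve(),
                                   table = default_ph_decay_table(),
                                   dt = 0.25) {
  stopifnot(all(t_in_stomach >= 0))
  tmax <- max(t_in_stomach, dt)
  grid <- seq(0, tmax, by = dt)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  k <- ph_decay_constant(gastric_ph(grid, curve), table)
  cumint <- c(0, cumsum((k[-1] + k[-length(k)]) / 2 * diff(grid)))
  exp(-stats::approx(grid, cumint, xout = t_in_stomach)$y)
}

# Damage factor as a fast interpolating function on [0, tmax].
damage_function <- function(curve, table, tmax, dt = 0.25) {
  grid <- seq(0, tmax, by = dt)
  stats::approxfun(grid, cumulative_acid_damage(grid, curve, table, dt = dt),
                   rule = 2)
}

#' Downstream (SI/colon) activity factor for a gastric residence time
#'
#' The lasting acid damage accrued in the stomach, capped from above by the
#' activity permitted at intestinal pH (default 0.75 of maximum).
#'
#' @param gastric_residence Time(s) spent in the stomach (min).
#' @param params A [strain_params()] object.
#' @return Activity fraction(s) in (0, cap].
#' @export
downstream_activity_factor <- function(gastric_residence, params = strain_params()) {
  stopifnot(inherits(params, "strain_params"))
  pmin(
    cumulative_acid_damage(
      gastric_residence, params$gastric_ph_curve, params$ph_decay_table
    ),
    params$activity_cap_downstream
  )
}

#' Oxygen inhibition factor
#'
#' Normalized activity as a linear function of the ambient oxygen fraction,
#' from an ordinary least-squares line through the calibration points,
#' normalized to 1 at 21% oxygen and clipped to `[0, 1]`. Fractions above
#' 0.21 are clipped to 1.
#'
#' @param o2_fraction Oxygen fraction(s) in `[0, 1]`.
#' @param line A fitted line as returned by [fit_oxygen_line()].
#' @return Activity fraction(s) in `[0, 1]`.
#' @export
oxygen_inhibition <- function(o2_fraction, line = fit_oxygen_line()) {
  stopifnot(all(o2_fraction >= 0 & o2_fraction <= 1))
  raw <- line$intercept + line$slope * pmin(o2_fraction, 0.21)
  at21 <- line$intercept + line$slope * 0.21
  pmin(pmax(raw / at21, 0), 1)
}

#' Extended colonic activity factor
#'
#' Normalized per-cell consumption rate as a function of time held under
#' colonic conditions, by piecewise-linear interpolation of the calibration
#' curve with constant extrapolation beyond the last measured hold time.
#'
#' @param hold_time Time(s) under colonic conditions (min).
#' @param curve Data frame with columns `hold_h`, `activity`.
#' @return Normalized activity fraction(s); 1 at hold time 0.
#' @export
extended_colonic_activity <- function(hold_time,
                                      curve = default_colon_hold_curve()) {
  stopifnot(all(hold_time >= 0))
  stats::approx(curve$hold_h * 60, curve$activity, xout = hold_time,
                rule = 2)$y
}

# Per-cell maximal rate in mmol/min per 1e9 cells from umol/h per 1e9 cells.
vmax_mmol_min_per_gigacell <- function(vmax_umol_h) vmax_umol_h * 1e-3 / 60

# Scale factor anchoring the colonic per-cell rate of an undamaged cell
# (downstream factor = cap) at saturating substrate to the measured SCF rate.
scf_scale_factor <- function(params) {
  o2c <- oxygen_inhibition(params$compartment_o2[["colon"]], params$o2_line)
  params$scf_rate / (params$vmax * params$activity_cap_downstream * o2c)
}

#' Compartmental oxalate consumption rate
#'
#' Michaelis-Menten consumption `Vmax * S / (KM + S)` per cell, summed over
#' residence-time cohorts with their activity modifiers: the time-varying
#' gastric damage factor in the stomach, the per-cohort lasting (capped)
#' damage downstream, the compartmental oxygen factor, and (colon only) the
#' extended colonic activity rescaled to the simulated-colonic-fluid rate.
#'
#' @param compartment `"gastric"`, `"si"` or `"colon"`.
#' @param oxalate_amount Oxalate in the compartment (mmol).
#' @param chyme_volume Chyme volume (ml).
#' @param cfu Cells present, in units of 1e9 cells; a vector over cohorts for
#'   `"si"`/`"colon"`, a scalar for `"gastric"`.
#' @param params A [strain_params()] object.
#' @param time Simulation time (min); sets the gastric damage factor.
#' @param cohort_factors Per-cohort downstream activity factors (from
#'   [downstream_activity_factor()] at the cohort residence times).
#' @param hold_times Per-cohort colonic hold times (min), colon only.
#' @return Consumption rate, mmol/min.
#' @export
consumption_rate <- function(compartment = c("gastric", "si", "colon"),
                             oxalate_amount, chyme_volume, cfu,
                             params = strain_params(), time = 0,
                             cohort_factors = NULL, hold_times = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(params, "strain_params"))
  if (chyme_volume <= VOL_TOL || oxalate_amount <= 0 || sum(cfu) <= 0) {
    return(0)
  }
  s <- oxalate_amount / chyme_volume # mmol/ml == mol/l * 1e0 -> mM below
  s_mM <- s * 1000 # mmol/ml -> mmol/l (mM)
  mm <- s_mM / (params$km + s_mM)
  o2 <- oxygen_inhibition(params$compartment_o2[[compartment]], params$o2_line)
  vmax_cell <- vmax_mmol_min_per_gigacell(params$vmax)
  if (compartment == "gastric") {
    damage <- cumulative_acid_damage(
      time, params$gastric_ph_curve, params$ph_decay_table
    )
    return(vmax_cell * mm * sum(cfu) * damage * o2)
  }
  if (is.null(cohort_factors)) {
    cohort_factors <- rep(params$activity_cap_downstream, length(cfu))
  }
  stopifnot(length(cohort_factors) == length(cfu))
  if (compartment == "si") {
    return(vmax_cell * mm * o2 * sum(cfu * cohort_factors))
  }
  # colon
  if (is.null(hold_times)) hold_times <- rep(0, length(cfu))
  ext <- scf_scale_factor(params) *
    extended_colonic_activity(hold_times, params$colon_hold_curve)
  vmax_cell * mm * o2 * sum(cfu * cohort_factors * ext)
}

# Equal-probability residence cohorts for a dose: entry times into the SI and
# per-cohort downstream activity factors.
residence_cohorts <- function(transit, strain, dose_gigacells) {
  n <- strain$n_cohorts
  rd <- residence_time_distribution(transit)
  t_entry <- rd$quantile((seq_len(n) - 0.5) / n)
  data.frame(
    t_entry = t_entry,
    mass = rep(dose_gigacells / n, n),
    factor = downstream_activity_factor(t_entry, strain)
  )
}
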
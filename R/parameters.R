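# Parameter blocks and the provenance-tracked parameter table.
#
# Internal unit basis: minutes, millilitres, mmol, cells in units of 1e9
# ("gigacells"). Strain activity is stored in its conventional lab unit
# (umol oxalate / h / 1e9 cells) and converted on use.

#' Molar mass of oxalic acid (g/mol), free-acid basis
#'
#' Used for every mass <-> mole conversion in the package (dietary mg/day to
#' luminal mmol, urinary mmol/min to mg/day).
#' @export
OXALATE_MW <- 88.02

MIN_PER_DAY <- 1440
VOL_TOL <- 1e-9 # ml below which a compartment counts as empty

#' Gastrointestinal transit parameters
#'
#' Per-meal chyme volumes, emptying/transit times and first-order fluid
#' absorption constants of the three-compartment (stomach, small intestine,
#' colon) transit model. Gastric emptying follows a power-exponential volume
#' decline `2^(-(t/half_time)^shape)` switched to a linear drain at
#' `tau_linear` and terminated at `tau_gastric`; intestinal and colonic
#' emptying are constant over windows of width `tau_gastric` starting at
#' `tau_si` and `tau_si + tau_colon` respectively.
#'
#' @param total_gastric_emptying_volume Gastric chyme volume per meal (ml);
#'   food plus drink for a typical day divided by meals per day.
#' @param total_secretions_volume Fluid secreted into the small intestine per
#'   meal (ml).
#' @param total_si_emptying_volume Chyme volume emptied from the small
#'   intestine into the colon per meal (ml).
#' @param total_colon_emptying_volume Fecal volume emptied per meal (ml).
#' @param gastric_half_emptying_time Half gastric emptying time (min).
#' @param gastric_shape Shape parameter of the power exponential (> 1).
#' @param tau_gastric Time by which the stomach has fully emptied (min).
#' @param tau_linear Time of the switch from power-exponential to linear
#'   emptying (min); `NULL` selects it by flow continuity (the time at which
#'   the power-exponential rate equals the linear drain rate
#'   `V(tau_linear)/(tau_gastric - tau_linear)`).
#' @param tau_si Intestinal transit time: start of the SI emptying window
#'   (min).
#' @param tau_colon Colonic transit time: offset of the colonic emptying
#'   window after `tau_si` (min).
#' @param k_si_fluid_abs,k_colon_fluid_abs First-order fluid absorption rate
#'   constants (1/min) in SI and colon.
#' @return An object of class `transit_params`.
#' @export
transit_params <- function(total_gastric_emptying_volume = 700,
                           total_secretions_volume = 2333,
                           total_si_emptying_volume = 500,
                           total_colon_emptying_volume = 50,
                           gastric_half_emptying_time = 110,
                           gastric_shape = 1.81,
                           tau_gastric = 240,
                           tau_linear = NULL,
                           tau_si = 240,
                           tau_colon = 1920,
                           k_si_fluid_abs = 0.01,
                           k_colon_fluid_abs = 0.0013) {
  p <- list(
    total_gastric_emptying_volume = total_gastric_emptying_volume,
    total_secretions_volume = total_secretions_volume,
    total_si_emptying_volume = total_si_emptying_volume,
    total_colon_emptying_volume = total_colon_emptying_volume,
    gastric_half_emptying_time = gastric_half_emptying_time,
    gastric_shape = gastric_shape,
    tau_gastric = tau_gastric,
    tau_si = tau_si,
    tau_colon = tau_colon,
    k_si_fluid_abs = k_si_fluid_abs,
    k_colon_fluid_abs = k_colon_fluid_abs
  )
  vols <- c(
    "total_gastric_emptying_volume", "total_secretions_volume",
    "total_si_emptying_volume", "total_colon_emptying_volume"
  )
  for (nm in vols) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      stop("transit_params: '", nm, "' must be a positive volume (ml)")
    }
  }
  if (gastric_half_emptying_time <= 0) {
    stop("transit_params: 'gastric_half_emptying_time' must be > 0")
  }
  if (gastric_shape <= 1) {
    stop("transit_params: 'gastric_shape' must exceed 1")
  }
  if (tau_gastric <= gastric_half_emptying_time) {
    stop("transit_params: 'tau_gastric' must exceed the half emptying time")
  }
  if (k_si_fluid_abs < 0 || k_colon_fluid_abs < 0) {
    stop("transit_params: fluid absorption constants must be >= 0")
  }
  if (tau_si <= 0 || tau_colon <= 0) {
    stop("transit_params: transit times must be > 0")
  }
  if (is.null(tau_linear)) {
    tau_linear <- solve_tau_linear(
      gastric_half_emptying_time,
      gastric_shape, tau_gastric
    )
  }
  if (tau_linear <= 0 || tau_linear >= tau_gastric) {
    stop("transit_params: need 0 < tau_linear < tau_gastric")
  }
  p$tau_linear <- tau_linear
  structure(p, class = "transit_params")
}

# Continuity rule for the power-exponential -> linear switch: the largest
# time in (half_time, tau_gastric) at which the power-exponential emptying
# rate equals the linear drain rate of the remaining volume. Taking the root
# above the half time keeps the distribution median at the half time.
solve_tau_linear <- function(half_time, shape, tau_gastric) {
  g <- function(t) {
    log(2) * shape * t^(shape - 1) / half_time^shape - 1 / (tau_gastric - t)
  }
  lo <- half_time
  hi <- tau_gastric * (1 - 1e-6)
  if (g(lo) <= 0) {
    # emptying already slower than the drain at the half time; switch there
    return(half_time)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Strain activity parameters
#'
#' Michaelis-Menten kinetics of per-cell oxalate consumption together with
#' the environmental modifiers: a pH -> decay-constant table driving
#' cumulative acid damage in the stomach, a cap on downstream (SI/colon)
#' activity set by intestinal pH, a linear oxygen-inhibition model, and an
#' empirical extended-colonic-activity curve anchored to the simulated
#' colonic fluid rate.
#'
#' @param vmax Maximal per-cell consumption velocity (umol/h per 1e9 cells).
#' @param km Michaelis constant (mM).
#' @param activity_cap_downstream Upper limit on normalized activity in SI and
#'   colon regardless of gastric residence (default 0.75, from the
#'   instantaneous activity at intestinal pH 6.5).
#' @param ph_decay_table Data frame with columns `ph` and `k` (1/min):
#'   exponential activity-decay constants per pH, linearly interpolated.
#' @param o2_points Data frame with columns `o2_fraction` and `activity` used
#'   to fit the oxygen-inhibition line (normalized to 1 at 21% oxygen).
#' @param colon_hold_curve Data frame with columns `hold_h` and `activity`:
#'   normalized per-cell rate as a function of time under colonic conditions;
#'   constant extrapolation beyond the last point.
#' @param scf_rate Absolute per-cell rate in simulated colonic fluid
#'   (umol/h per 1e9 cells) used to rescale colonic activity.
#' @param compartment_o2 Named numeric vector of oxygen fractions for
#'   `gastric`, `si`, `colon`.
#' @param ph_curve A [gastric_ph_curve()] object describing gastric pH.
#' @param n_cohorts Number of equal-probability gastric residence cohorts
#'   used to discretize lasting acid damage downstream.
#' @return An object of class `strain_params` with precomputed modifier
#'   functions.
#' @export
strain_params <- function(vmax = 1.98,
                          km = 2,
                          activity_cap_downstream = 0.75,
                          ph_decay_table = default_ph_decay_table(),
                          o2_points = default_o2_points(),
                          colon_hold_curve = default_colon_hold_curve(),
                          scf_rate = 0.2,
                          compartment_o2 = c(gastric = 0.07, si = 0.04, colon = 0),
                          ph_curve = gastric_ph_curve(),
                          n_cohorts = 20) {
  if (vmax <= 0 || km <= 0) stop("strain_params: vmax and km must be > 0")
  if (activity_cap_downstream <= 0 || activity_cap_downstream > 1) {
    stop("strain_params: activity cap must lie in (0, 1]")
  }
  stopifnot(
    all(c("ph", "k") %in% names(ph_decay_table)),
    all(ph_decay_table$k >= 0),
    n_cohorts >= 1
  )
  o2_line <- fit_oxygen_line(o2_points)
  p <- structure(list(
    vmax = vmax,
    km = km,
    activity_cap_downstream = activity_cap_downstream,
    ph_decay_table = ph_decay_table[order(ph_decay_table$ph), ],
    o2_points = o2_points,
    o2_line = o2_line,
    colon_hold_curve = colon_hold_curve,
    scf_rate = scf_rate,
    compartment_o2 = compartment_o2,
    gastric_ph_curve = ph_curve,
    n_cohorts = as.integer(n_cohorts)
  ), class = "strain_params")
  p
}

#' Gastric pH time course after a solid meal
#'
#' pH relaxes from the fed to the fasted level by a power-exponential decay
#' sharing the functional form of gastric emptying:
#' `ph(t) = ph_fasted + (ph_fed - ph_fasted) * 2^(-(t/half_time)^shape)`.
#'
#' @param ph_fed pH immediately after the meal.
#' @param ph_fasted Asymptotic (fasted) pH, about 2.
#' @param half_time Time for half of the total pH decline (min).
#' @param shape Power-exponential shape parameter.
#' @export
gastric_ph_curve <- function(ph_fed = 6.7, ph_fasted = 2.0,
                             half_time = 110, shape = 1.81) {
  if (!(ph_fed > ph_fasted && ph_fasted > 0)) {
    stop("gastric_ph_curve: need ph_fed > ph_fasted > 0")
  }
  if (half_time <= 0 || shape <= 0) {
    stop("gastric_ph_curve: half_time and shape must be > 0")
  }
  structure(list(
    ph_fed = ph_fed, ph_fasted = ph_fasted,
    half_time = half_time, shape = shape
  ), class = "gastric_ph_curve")
}

#' Default per-pH activity decay constants
#'
#' Exponential decay constants (1/min) for activity loss under acid
#' exposure, reconstructed from the measured normalized activity after a
#' 120-min hold (`k = -ln(A)/120`) at pH 3-7, with `k` at pH 7 fixed to 0
#' and pH 2 extrapolated by the trend.
#' @return Data frame with columns `ph`, `k`.
#' @export
default_ph_decay_table <- function() {
  data.frame(
    ph = c(2, 3, 4, 5, 6, 7),
    k = c(0.06, -log(0.04) / 120, -log(0.24) / 120,
          -log(0.30) / 120, -log(0.52) / 120, 0)
  )
}

#' Measured normalized activity vs oxygen fraction
#'
#' The three calibration anchors of the linear oxygen-inhibition model.
#' @return Data frame with columns `o2_fraction`, `activity`.
#' @export
default_o2_points <- function() {
  data.frame(
    o2_fraction = c(0, 0.07, 0.21),
    activity = c(0.74, 0.79, 1.00)
  )
}

#' Default normalized colonic hold-activity curve
#'
#' Normalized per-cell rate vs time held under colonic conditions. The
#' measured rate was stable across a 48-h incubation, so the default curve
#' is flat at 1; the absolute level enters through `scf_rate`.
#' @return Data frame with columns `hold_h`, `activity`.
#' @export
default_colon_hold_curve <- function() {
  data.frame(
    hold_h = c(0, 6, 16, 24, 40, 48),
    activity = rep(1, 6)
  )
}

#' Oxalate absorption parameters
#'
#' The dietary absorption fraction model for healthy subjects (exponential in
#' daily intake, `f(d) = a*exp(-b*d) + c`), the enteric-hyperoxaluria
#' multiplier on that fraction, the small-intestinal share of absorption, and
#' (after calibration) the first-order oxalate absorption rate constants.
#'
#' @param f_abs_a,f_abs_b,f_abs_c Coefficients of the healthy absorption
#'   fraction `a*exp(-b*d) + c` with `d` the diet in mg/day.
#' @param eh_multiplier Fold-increase of absorption in EH patients relative
#'   to healthy subjects (baseline 4, plausible range 3-5).
#' @param f_si_abs Fraction of (healthy) absorption occurring in the small
#'   intestine.
#' @param k_si_oxalate_abs,k_colon_oxalate_abs First-order absorption rate
#'   constants (1/min); `NA` until calibrated.
#' @param population `"healthy"` or `"eh"`.
#' @export
absorption_params <- function(f_abs_a = 0.035,
                              f_abs_b = 0.004,
                              f_abs_c = 0.06,
                              eh_multiplier = 4,
                              f_si_abs = 0.6,
                              k_si_oxalate_abs = NA_real_,
                              k_colon_oxalate_abs = NA_real_,
                              population = c("healthy", "eh")) {
  population <- match.arg(population)
  if (f_abs_a < 0 || f_abs_b < 0 || f_abs_c < 0) {
    stop("absorption_params: f_abs coefficients must be >= 0")
  }
  if (eh_multiplier < 3 || eh_multiplier > 5) {
    stop("absorption_params: eh_multiplier must lie in [3, 5]")
  }
  if (f_si_abs < 0 || f_si_abs > 1) {
    stop("absorption_params: f_si_abs must lie in [0, 1]")
  }
  structure(list(
    f_abs_a = f_abs_a, f_abs_b = f_abs_b, f_abs_c = f_abs_c,
    eh_multiplier = eh_multiplier, f_si_abs = f_si_abs,
    k_si_oxalate_abs = k_si_oxalate_abs,
    k_colon_oxalate_abs = k_colon_oxalate_abs,
    population = population
  ), class = "absorption_params")
}

#' Systemic (plasma and urinary) parameters
#'
#' @param r_endogenous Endogenous oxalate production rate (mmol/min);
#'   default corresponds to 15 mg/day.
#' @param k_urinary First-order urinary excretion rate constant (1/min);
#'   default corresponds to 1/day.
#' @param n_daily_meals Meals (and doses) per day.
#' @export
systemic_params <- function(r_endogenous = 15 / OXALATE_MW / MIN_PER_DAY,
                            k_urinary = 1 / MIN_PER_DAY,
                            n_daily_meals = 3) {
  if (r_endogenous <= 0 || k_urinary <= 0 || n_daily_meals <= 0) {
    stop("systemic_params: all parameters must be > 0")
  }
  structure(list(
    r_endogenous = r_endogenous, k_urinary = k_urinary,
    n_daily_meals = n_daily_meals
  ), class = "systemic_params")
}

#' Assemble a full model object
#'
#' Bundles the four parameter blocks into a single model that scenario-level
#' functions consume.
#'
#' @param transit A [transit_params()] object.
#' @param strain A [strain_params()] object.
#' @param absorption An [absorption_params()] object.
#' @param systemic A [systemic_params()] object.
#' @return An object of class `iss_model`.
#' @export
iss_model <- function(transit = transit_params(),
                      strain = strain_params(),
                      absorption = absorption_params(),
                      systemic = systemic_params()) {
  stopifnot(
    inherits(transit, "transit_params"),
    inherits(strain, "strain_params"),
    inherits(absorption, "absorption_params"),
    inherits(systemic, "systemic_params")
  )
  structure(list(
    transit = transit, strain = strain,
    absorption = absorption, systemic = systemic
  ), class = "iss_model")
}

#' @export
print.iss_model <- function(x, ...) {
  cat("Gut/systemic oxalate simulation model\n")
  cat(sprintf(
    "  transit : gastric t1/2 %.0f min, shape %.2f, emptied by %.0f min\n",
    x$transit$gastric_half_emptying_time, x$transit$gastric_shape,
    x$transit$tau_gastric
  ))
  cat(sprintf(
    "            SI window %.0f-%.0f min, colon window %.0f-%.0f min\n",
    x$transit$tau_si, x$transit$tau_si + x$transit$tau_gastric,
    x$transit$tau_si + x$transit$tau_colon,
    x$transit$tau_si + x$transit$tau_colon + x$transit$tau_gastric
  ))
  cat(sprintf(
    "  strain  : Vmax %.3g umol/h/1e9 cells, KM %.3g mM, downstream cap %.2f\n",
    x$strain$vmax, x$strain$km, x$strain$activity_cap_downstream
  ))
  cat(sprintf(
    "  diet    : f_abs(d) = %.3g*exp(-%.3g d) + %.3g, EH multiplier %.1fx\n",
    x$absorption$f_abs_a, x$absorption$f_abs_b, x$absorption$f_abs_c,
    x$absorption$eh_multiplier
  ))
  cat(sprintf(
    "  systemic: endogenous %.1f mg/day, k_urinary %.3g /day, %d meals/day\n",
    x$systemic$r_endogenous * MIN_PER_DAY * OXALATE_MW,
    x$systemic$k_urinary * MIN_PER_DAY, x$systemic$n_daily_meals
  ))
  invisible(x)
}
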
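# Scenario driver: multi-day dosing with meals, percent UOx lowering,
# dietary sweeps, population variability and the extreme-values sensitivity
# analysis.

# Multiply the healthy absorption-fraction curve by a factor (inter-subject
# variability or confidence-band runs): scales both coefficients so that
# f(d) scales uniformly in d.
scale_absorption <- function(absorption, factor) {
  stopifnot(factor > 0)
  absorption$f_abs_a <- absorption$f_abs_a * factor
  absorption$f_abs_c <- absorption$f_abs_c * factor
  absorption
}

# Calibrate once for a (diet, population, scale) and integrate the
# strain-free meal plus one dosed meal per dose level.
meal_partitions <- function(model, diet_mg_day, doses, population,
                            absorption_scale = 1) {
  absorption <- model$absorption
  absorption$population <- population
  absorption <- scale_absorption(absorption, absorption_scale)
  sys <- model$systemic
  cal <- calibrate_absorption_constants(diet_mg_day, model$transit,
                                        absorption, sys)
  free <- integrate_meal(meal_spec(diet_mg_day / sys$n_daily_meals, 0),
                         model$transit, model$strain, cal, dt_out = 60)
  dosed <- lapply(doses[doses > 0], function(d) {
    integrate_meal(meal_spec(diet_mg_day / sys$n_daily_meals, d),
                   model$transit, model$strain, cal, dt_out = 60)
  })
  names(dosed) <- as.character(doses[doses > 0])
  list(calibration = cal, free = free, dosed = dosed)
}

#' Simulate a dosing scenario
#'
#' Runs one strain-free and (if dosed) one dosed meal simulation, converts
#' the per-meal absorbed oxalate into daily plasma influx, and chains the
#' closed-form urinary relaxation over the dosing days. The subject starts at
#' the steady state of `diet_init` (default: the scenario diet) without the
#' strain; dosing and/or the diet change begin at day 0.
#'
#' @param model An [iss_model()] object.
#' @param diet_mg_day Dietary oxalate during the scenario (mg/day).
#' @param dose_cfu Cells per dose (dosed with each of the
#'   `n_daily_meals` meals); 0 for an untreated control.
#' @param days Number of simulated days.
#' @param population `"healthy"` or `"eh"`.
#' @param absorption_scale Multiplicative factor on the healthy absorption
#'   fraction (subject variability or confidence-band runs).
#' @param diet_init Diet defining the initial steady state (mg/day); defaults
#'   to `diet_mg_day`.
#' @return An object of class `iss_sim`: data frame `uox` (`day`,
#'   `uox_mg_day`), the per-meal partitions, influxes, and scenario metadata.
#' @export
simulate_scenario <- function(model, diet_mg_day, dose_cfu = 0, days = 10,
                              population = c("healthy", "eh"),
                              absorption_scale = 1, diet_init = diet_mg_day) {
  stopifnot(inherits(model, "iss_model"), diet_mg_day > 0, days >= 1)
  population <- match.arg(population)
  sys <- model$systemic
  parts <- meal_partitions(model, diet_mg_day, dose_cfu, population,
                           absorption_scale)
  part_free <- parts$free
  if (diet_init == diet_mg_day) {
    part_init <- part_free
  } else {
    part_init <- meal_partitions(model, diet_init, numeric(0), population,
                                 absorption_scale)$free
  }
  part_dosed <- NULL
  m_abs_new <- part_free$m_ox_abs_total
  if (dose_cfu > 0) {
    part_dosed <- parts$dosed[[as.character(dose_cfu)]]
    m_abs_new <- part_dosed$m_ox_abs_total
  }
  influx_init <- plasma_influx(part_init$m_ox_abs_total, sys)
  influx_new <- plasma_influx(m_abs_new, sys)
  day <- 0:days
  rate <- urinary_excretion_timecourse(influx_init, influx_new, sys,
                                       day * MIN_PER_DAY)
  structure(list(
    uox = data.frame(day = day, uox_mg_day = uox_mg_per_day(rate)),
    uox_steady_state = uox_mg_per_day(influx_new),
    influx_init = influx_init, influx_new = influx_new,
    partition_control = part_free, partition_dosed = part_dosed,
    scenario = list(
      diet_mg_day = diet_mg_day, diet_init = diet_init, dose_cfu = dose_cfu,
      days = days, population = population,
      absorption_scale = absorption_scale
    )
  ), class = "iss_sim")
}

#' @export
print.iss_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Scenario: %s, %g mg/day oxalate, %.3g cells x%d/day, %d days\n",
    s$population, s$diet_mg_day, s$dose_cfu, 3, s$days
  ))
  n <- nrow(x$uox)
  show <- unique(c(1, 2, 3, 4, n))
  show <- show[show <= n]
  print(x$uox[show, ], row.names = FALSE)
  cat(sprintf("steady-state UOx: %.1f mg/day\n", x$uox_steady_state))
  invisible(x)
}

#' @export
plot.iss_sim <- function(x, ...) {
  plot(x$uox$day, x$uox$uox_mg_day,
    type = "b", pch = 16,
    xlab = "day", ylab = "urinary oxalate (mg/day)",
    main = sprintf(
      "%s, %g mg/day diet, %.2g cells TID",
      x$scenario$population, x$scenario$diet_mg_day, x$scenario$dose_cfu
    ), ...
  )
  invisible(x)
}

#' Percent UOx lowering of a treated vs control scenario
#'
#' @param treated,control `iss_sim` objects differing only in dose.
#' @param day Day at which to compare.
#' @return Percent lowering, `100 * (control - treated) / control`.
#' @export
percent_lowering <- function(treated, control, day) {
  stopifnot(inherits(treated, "iss_sim"), inherits(control, "iss_sim"))
  tu <- treated$uox$uox_mg_day[match(day, treated$uox$day)]
  cu <- control$uox$uox_mg_day[match(day, control$uox$day)]
  if (any(is.na(tu)) || any(is.na(cu))) stop("percent_lowering: day not simulated")
  if (any(cu == 0)) stop("percent_lowering: control UOx is zero")
  100 * (cu - tu) / cu
}

#' Dietary sweep of UOx lowering
#'
#' Percent lowering at a fixed day across a grid of dietary oxalate intakes,
#' for one or more dose levels, reporting the diet of maximal lowering per
#' dose.
#'
#' @param model An [iss_model()] object.
#' @param doses Cells per dose (vector).
#' @param diets Daily dietary oxalate grid (mg/day).
#' @param day Comparison day (default 5).
#' @param population Population simulated (default `"eh"`).
#' @return List with `curve` (data frame `diet_mg_day`, `dose_cfu`,
#'   `lowering_pct`) and `argmax` (data frame `dose_cfu`,
#'   `diet_at_max`, `max_lowering_pct`).
#' @export
dietary_sweep <- function(model, doses = c(1e11, 2e11, 5e11),
                          diets = seq(50, 500, by = 50), day = 5,
                          population = "eh") {
  stopifnot(all(diff(diets) > 0), all(diets > 0))
  sys <- model$systemic
  rows <- list()
  for (diet in diets) {
    parts <- meal_partitions(model, diet, doses, population)
    influx0 <- plasma_influx(parts$free$m_ox_abs_total, sys)
    for (dose in doses) {
      low <- if (dose == 0) 0 else {
        influx1 <- plasma_influx(
          parts$dosed[[as.character(dose)]]$m_ox_abs_total, sys
        )
        rate_d <- urinary_excretion_timecourse(influx0, influx1, sys,
                                               day * MIN_PER_DAY)
        100 * (influx0 - rate_d) / influx0
      }
      rows[[length(rows) + 1]] <- data.frame(
        diet_mg_day = diet, dose_cfu = dose, lowering_pct = low
      )
    }
  }
  curve <- do.call(rbind, rows)
  argmax <- do.call(rbind, lapply(split(curve, curve$dose_cfu), function(d) {
    i <- which.max(d$lowering_pct)
    data.frame(
      dose_cfu = d$dose_cfu[1], diet_at_max = d$diet_mg_day[i],
      max_lowering_pct = d$lowering_pct[i]
    )
  }))
  rownames(argmax) <- NULL
  list(curve = curve, argmax = argmax)
}

#' Population simulation with inter-subject variability
#'
#' Each subject draws a multiplicative lognormal factor (mean 1) on the
#' dietary absorption fraction; scenarios are re-run per subject and the
#' per-day mean and SD of UOx are reported.
#'
#' @param model An [iss_model()] object.
#' @param diet_mg_day Scenario diet (mg/day).
#' @param dose_cfu Cells per dose.
#' @param days Number of days.
#' @param population Simulated population.
#' @param n_subjects Cohort size (default 30).
#' @param cv Coefficient of variation of the absorption factor.
#' @param seed RNG seed.
#' @param diet_init Diet of the initial steady state.
#' @return List with `summary` (data frame `day`, `mean_uox`, `sd_uox`) and
#'   the per-subject matrix `uox` (days x subjects).
#' @export
population_simulate <- function(model, diet_mg_day, dose_cfu = 0, days = 3,
                                population = "healthy", n_subjects = 30,
                                cv = 0.12, seed = 1,
                                diet_init = diet_mg_day) {
  factors <- generate_population(n_subjects, cv = cv, seed = seed)$factor
  sims <- lapply(factors, function(f) {
    simulate_scenario(model, diet_mg_day, dose_cfu, days,
                      population = population, absorption_scale = f,
                      diet_init = diet_init)
  })
  uox <- vapply(sims, function(s) s$uox$uox_mg_day, numeric(days + 1))
  summary <- data.frame(
    day = 0:days,
    mean_uox = rowMeans(uox),
    sd_uox = apply(uox, 1, stats::sd)
  )
  list(summary = summary, uox = uox, factors = factors)
}

#' Default extreme-values sensitivity specifications
#'
#' Parameter ranges for the extreme-values analysis, taken once from the
#' physiology and kinetics literature ranges around the shipped baseline.
#'
#' @param model The baseline model (supplies baseline values).
#' @return Data frame with columns `parameter`, `baseline`, `min`, `max`.
#' @export
default_sensitivity_specs <- function(model = iss_model()) {
  tr <- model$transit
  si_frac <- tr$total_si_emptying_volume /
    (tr$total_gastric_emptying_volume + tr$total_secretions_volume)
  col_frac <- tr$total_colon_emptying_volume / tr$total_si_emptying_volume
  specs <- data.frame(
    parameter = c(
      "gastric_shape", "gastric_half_emptying_time",
      "si_chyme_volume_fraction", "colon_chyme_volume_fraction",
      "tau_si", "tau_colon", "eh_absorption_multiplier", "f_si_abs",
      "r_endogenous", "k_urinary", "vmax", "km"
    ),
    baseline = c(
      tr$gastric_shape, tr$gastric_half_emptying_time, si_frac, col_frac,
      tr$tau_si, tr$tau_colon, model$absorption$eh_multiplier,
      model$absorption$f_si_abs, model$systemic$r_endogenous,
      model$systemic$k_urinary, model$strain$vmax, model$strain$km
    ),
    min = c(1.4, 60, si_frac / 2, col_frac / 2, 120, 960, 3, 0.4,
            10 / OXALATE_MW / MIN_PER_DAY, 0.5 / MIN_PER_DAY, 1.0, 0.5),
    max = c(2.2, 170, si_frac * 2, col_frac * 2, 360, 2880, 5, 0.8,
            25 / OXALATE_MW / MIN_PER_DAY, 2 / MIN_PER_DAY, 3.0, 8)
  )
  stopifnot(all(specs$min <= specs$baseline & specs$baseline <= specs$max))
  specs
}

# Return a copy of the model with one sensitivity parameter set to `value`.
apply_sensitivity <- function(model, parameter, value) {
  tr <- model$transit
  rebuild_transit <- function(...) {
    args <- utils::modifyList(list(
      total_gastric_emptying_volume = tr$total_gastric_emptying_volume,
      total_secretions_volume = tr$total_secretions_volume,
      total_si_emptying_volume = tr$total_si_emptying_volume,
      total_colon_emptying_volume = tr$total_colon_emptying_volume,
      gastric_half_emptying_time = tr$gastric_half_emptying_time,
      gastric_shape = tr$gastric_shape,
      tau_gastric = tr$tau_gastric,
      tau_si = tr$tau_si, tau_colon = tr$tau_colon,
      k_si_fluid_abs = tr$k_si_fluid_abs,
      k_colon_fluid_abs = tr$k_colon_fluid_abs
    ), list(...))
    do.call(transit_params, args)
  }
  switch(parameter,
    gastric_shape = {
      model$transit <- rebuild_transit(gastric_shape = value)
    },
    gastric_half_emptying_time = {
      model$transit <- rebuild_transit(gastric_half_emptying_time = value)
    },
    si_chyme_volume_fraction = {
      v <- value * (tr$total_gastric_emptying_volume + tr$total_secretions_volume)
      # keep the colonic fraction fixed while rescaling the SI volume
      col_frac <- tr$total_colon_emptying_volume / tr$total_si_emptying_volume
      model$transit <- rebuild_transit(
        total_si_emptying_volume = v,
        total_colon_emptying_volume = col_frac * v
      )
    },
    colon_chyme_volume_fraction = {
      model$transit <- rebuild_transit(
        total_colon_emptying_volume = value * tr$total_si_emptying_volume
      )
    },
    tau_si = {
      model$transit <- rebuild_transit(tau_si = value)
    },
    tau_colon = {
      model$transit <- rebuild_transit(tau_colon = value)
    },
    eh_absorption_multiplier = {
      model$absorption$eh_multiplier <- value
    },
    f_si_abs = {
      model$absorption$f_si_abs <- value
    },
    r_endogenous = {
      model$systemic$r_endogenous <- value
    },
    k_urinary = {
      model$systemic$k_urinary <- value
    },
    vmax = {
      model$strain$vmax <- value
    },
    km = {
      model$strain$km <- value
    },
    stop("unknown sensitivity parameter: ", parameter)
  )
  model
}

#' Extreme-values sensitivity analysis
#'
#' Re-simulates the baseline efficacy scenario (EH, 200 mg/day, 5e11 cells
#' TID, day-10 lowering) under the minimum and maximum of each parameter
#' range, one parameter at a time.
#'
#' @param model Baseline [iss_model()].
#' @param specs Sensitivity ranges, see [default_sensitivity_specs()].
#' @param diet_mg_day,dose_cfu,days,population Baseline scenario settings.
#' @return Data frame with one baseline row plus one row per
#'   (parameter, extreme): `parameter`, `extreme`, `value`, `lowering_pct`,
#'   `error` (NA unless that row failed).
#' @export
extreme_values_analysis <- function(model, specs = default_sensitivity_specs(model),
                                    diet_mg_day = 200, dose_cfu = 5e11,
                                    days = 10, population = "eh") {
  run_lowering <- function(m) {
    parts <- meal_partitions(m, diet_mg_day, dose_cfu, population)
    sys <- m$systemic
    influx0 <- plasma_influx(parts$free$m_ox_abs_total, sys)
    influx1 <- plasma_influx(
      parts$dosed[[as.character(dose_cfu)]]$m_ox_abs_total, sys
    )
    rate_d <- urinary_excretion_timecourse(influx0, influx1, sys,
                                           days * MIN_PER_DAY)
    100 * (influx0 - rate_d) / influx0
  }
  rows <- list(data.frame(
    parameter = "baseline", extreme = "baseline", value = NA_real_,
    lowering_pct = run_lowering(model), error = NA_character_
  ))
  for (i in seq_len(nrow(specs))) {
    for (extreme in c("min", "max")) {
      value <- specs[[extreme]][i]
      res <- try({
        m <- apply_sensitivity(model, specs$parameter[i], value)
        run_lowering(m)
      }, silent = TRUE)
      rows[[length(rows) + 1]] <- if (inherits(res, "try-error")) {
        data.frame(
          parameter = specs$parameter[i], extreme = extreme, value = value,
          lowering_pct = NA_real_,
          error = conditionMessage(attr(res, "condition"))
        )
      } else {
        data.frame(
          parameter = specs$parameter[i], extreme = extreme, value = value,
          lowering_pct = res, error = NA_character_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
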
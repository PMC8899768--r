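# Per-meal luminal oxalate mass balance coupled to chyme transit and strain
# kinetics. One meal is simulated in isolation on a 48-h window; the dosing
# schedule enters through the systemic model.

#' Specify a meal
#'
#' @param dietary_oxalate_mg Oxalate content of the meal (mg).
#' @param dose_cfu Bacterial cells co-administered with the meal (cells).
#' @return An object of class `meal_spec`. Oxalate is converted to mmol at
#'   88.02 g/mol (free-acid basis).
#' @export
meal_spec <- function(dietary_oxalate_mg, dose_cfu = 0) {
  stopifnot(dietary_oxalate_mg >= 0, dose_cfu >= 0)
  structure(list(
    dietary_oxalate_mg = dietary_oxalate_mg,
    oxalate_mmol = dietary_oxalate_mg / OXALATE_MW,
    dose_cfu = dose_cfu,
    dose_gigacells = dose_cfu / 1e9
  ), class = "meal_spec")
}

#' Oxalate emptying rate out of a compartment
#'
#' The product of the compartment's chyme emptying rate and the oxalate
#' concentration (amount over chyme volume); zero when the volume guard
#' triggers.
#'
#' @param compartment `"gastric"`, `"si"` or `"colon"`.
#' @param t Time (min).
#' @param oxalate Oxalate amount in the compartment (mmol).
#' @param volume Chyme volume in the compartment (ml).
#' @param p A [transit_params()] object.
#' @return Emptying rate, mmol/min.
#' @export
oxalate_emptying_rate <- function(compartment = c("gastric", "si", "colon"),
                                  t, oxalate, volume, p) {
  compartment <- match.arg(compartment)
  if (volume <= VOL_TOL) return(0)
  r <- switch(compartment,
    gastric = gastric_emptying_rate(t, p),
    si = window_emptying_rate(t, p, "si"),
    colon = window_emptying_rate(t, p, "colon")
  )
  r * oxalate / volume
}

#' First-order oxalate absorption rate
#'
#' First-order in oxalate amount (not concentration); gastric absorption is
#' not modeled.
#'
#' @param oxalate Oxalate amount (mmol).
#' @param k_abs Absorption rate constant (1/min).
#' @return Absorption rate, mmol/min.
#' @export
oxalate_absorption_rate <- function(oxalate, k_abs) {
  stopifnot(k_abs >= 0)
  k_abs * oxalate
}

#' Integrate one meal
#'
#' Solves the coupled chyme / oxalate / cell balances for a single meal over
#' the simulation window, returning the absorbed / consumed / fecal oxalate
#' partition and the dense state series. The dosed cell population is
#' discretized into equal-probability gastric residence cohorts, each
#' carrying its lasting acid-damage factor into the small intestine and
#' colon.
#'
#' @param meal A [meal_spec()] object.
#' @param transit A [transit_params()] object.
#' @param strain A [strain_params()] object.
#' @param absorption An [absorption_params()] object with calibrated
#'   absorption constants (`k_si_oxalate_abs`, `k_colon_oxalate_abs`).
#' @param horizon Simulation window (min), default 48 h.
#' @param dt_out Output grid spacing (min).
#' @param balance_tol Relative oxalate mass-balance violation that triggers a
#'   hard error.
#' @return An object of class `meal_sim`: list with the partition totals
#'   `m_ox_abs_si`, `m_ox_abs_colon`, `m_ox_abs_total`, `consumed`, `fecal`,
#'   `residual` (mmol), the meal, and the state `series` data frame.
#' @export
integrate_meal <- function(meal, transit, strain = strain_params(),
                           absorption, horizon = 2880, dt_out = 10,
                           balance_tol = 0.005) {
  stopifnot(
    inherits(meal, "meal_spec"), inherits(transit, "transit_params"),
    inherits(strain, "strain_params"), inherits(absorption, "absorption_params")
  )
  k_si <- absorption$k_si_oxalate_abs
  k_col <- absorption$k_colon_oxalate_abs
  if (is.na(k_si) || is.na(k_col)) {
    stop("integrate_meal: absorption constants not calibrated; ",
         "run calibrate_absorption_constants() first")
  }
  dosed <- meal$dose_gigacells > 0
  n <- if (dosed) strain$n_cohorts else 0
  cohorts <- if (dosed) residence_cohorts(transit, strain, meal$dose_gigacells)
  damage_fn <- damage_function(
    strain$gastric_ph_curve, strain$ph_decay_table, transit$tau_gastric
  )
  o2 <- vapply(
    c("gastric", "si", "colon"),
    function(cmp) oxygen_inhibition(strain$compartment_o2[[cmp]], strain$o2_line),
    numeric(1)
  )
  vmax_cell <- vmax_mmol_min_per_gigacell(strain$vmax)
  km <- strain$km
  scf_scale <- scf_scale_factor(strain)
  hold_fn <- stats::approxfun(
    strain$colon_hold_curve$hold_h * 60, strain$colon_hold_curve$activity,
    rule = 2
  )
  v0 <- transit$total_gastric_emptying_volume
  colon_open <- transit$tau_si # earliest colon entry

  mm_factor <- function(ox, vol) {
    if (vol <= VOL_TOL || ox <= 0) return(0)
    s <- ox / vol * 1000 # mM
    s / (km + s)
  }

  idx_si <- if (dosed) 10 + seq_len(n)
  idx_col <- if (dosed) 10 + n + seq_len(n)
  idx_exc <- if (dosed) 10 + 2 * n + seq_len(n)

  rhs <- function(t, y, parms) {
    v_g <- max(y[1], 0); v_si <- max(y[2], 0); v_col <- max(y[3], 0)
    ox_g <- max(y[4], 0); ox_si <- max(y[5], 0); ox_col <- max(y[6], 0)
    r_g <- gastric_emptying_rate(t, transit)
    r_sec <- secretion_rate(t, transit)
    w_si <- window_emptying_rate(t, transit, "si")
    w_col <- window_emptying_rate(t, transit, "colon")
    r_si <- drain_flux(w_si, v_si, v_si)
    r_col <- drain_flux(w_col, v_col, v_col)

    # consumption
    cons_g <- cons_si <- cons_col <- 0
    d_cfu <- NULL
    if (dosed) {
      cfu_si <- pmax(y[idx_si], 0)
      cfu_col <- pmax(y[idx_col], 0)
      cfu_g_tot <- meal$dose_gigacells * (if (v_g > VOL_TOL) v_g / v0 else 0)
      cons_g <- vmax_cell * mm_factor(ox_g, v_g) * cfu_g_tot *
        damage_fn(min(t, transit$tau_gastric)) * o2[["gastric"]]
      cons_si <- vmax_cell * mm_factor(ox_si, v_si) * o2[["si"]] *
        sum(cfu_si * cohorts$factor)
      hold <- pmax(0, t - pmax(cohorts$t_entry, colon_open))
      cons_col <- vmax_cell * mm_factor(ox_col, v_col) * o2[["colon"]] *
        scf_scale * sum(cfu_col * cohorts$factor * hold_fn(hold))
      f_si_cfu <- drain_flux(w_si, 1, v_si) * cfu_si
      f_col_cfu <- drain_flux(w_col, 1, v_col) * cfu_col
      d_cfu <- c(-f_si_cfu, f_si_cfu - f_col_cfu, f_col_cfu)
    }
    # cap consumption so it cannot overdraw the compartment within a step
    cons_g <- min(cons_g, ox_g * 1)
    cons_si <- min(cons_si, ox_si * 1)
    cons_col <- min(cons_col, ox_col * 1)

    a_si <- k_si * ox_si
    a_col <- k_col * ox_col
    e_g <- drain_flux(r_g, ox_g, v_g, eps = 1e-6)
    e_si <- drain_flux(w_si, ox_si, v_si)
    e_col <- drain_flux(w_col, ox_col, v_col)

    dy <- c(
      -r_g,
      r_g + r_sec - transit$k_si_fluid_abs * v_si - r_si,
      r_si - transit$k_colon_fluid_abs * v_col - r_col,
      -e_g - cons_g,
      e_g - cons_si - a_si - e_si,
      e_si - cons_col - a_col - e_col,
      e_col,                 # fecal
      a_si,                  # absorbed SI
      a_col,                 # absorbed colon
      cons_g + cons_si + cons_col # consumed
    )
    list(c(dy, d_cfu))
  }

  y0 <- c(
    v_gastric = v0, v_si = 0, v_colon = 0,
    ox_gastric = meal$oxalate_mmol, ox_si = 0, ox_colon = 0,
    ox_fecal = 0, ox_abs_si = 0, ox_abs_colon = 0, ox_consumed = 0
  )
  injections <- list()
  if (dosed) {
    y0 <- c(y0, stats::setNames(rep(0, 3 * n), c(
      paste0("cfu_si_", seq_len(n)), paste0("cfu_col_", seq_len(n)),
      paste0("cfu_exc_", seq_len(n))
    )))
    # cohort entry times are distinct quantiles of a continuous distribution
    for (i in seq_len(n)) {
      injections[[as.character(cohorts$t_entry[i])]] <- local({
        j <- i
        function(y) {
          y[idx_si[j]] <- y[idx_si[j]] + cohorts$mass[j]
          y
        }
      })
    }
  }
  out <- integrate_piecewise(
    rhs, y0, horizon,
    breakpoints = transit_breakpoints(transit, horizon),
    injections = injections, dt_out = dt_out
  )
  series <- as.data.frame(out)
  names(series)[1] <- "time"
  fin <- series[nrow(series), ]
  residual <- max(fin$ox_gastric, 0) + max(fin$ox_si, 0) + max(fin$ox_colon, 0)
  total_out <- fin$ox_fecal + fin$ox_abs_si + fin$ox_abs_colon +
    fin$ox_consumed + residual
  if (meal$oxalate_mmol > 0) {
    rel_err <- abs(total_out - meal$oxalate_mmol) / meal$oxalate_mmol
    if (rel_err > balance_tol) {
      stop(sprintf(
        "integrate_meal: oxalate mass balance violated by %.3f%%", 100 * rel_err
      ))
    }
  }
  structure(list(
    meal = meal,
    m_ox_abs_si = fin$ox_abs_si,
    m_ox_abs_colon = fin$ox_abs_colon,
    m_ox_abs_total = fin$ox_abs_si + fin$ox_abs_colon,
    consumed = fin$ox_consumed,
    fecal = fin$ox_fecal,
    residual = residual,
    series = series
  ), class = "meal_sim")
}

#' @export
print.meal_sim <- function(x, ...) {
  m <- x$meal$oxalate_mmol
  cat(sprintf(
    "Per-meal oxalate partition (meal %.3f mmol = %.1f mg, dose %.3g cells):\n",
    m, x$meal$dietary_oxalate_mg, x$meal$dose_cfu
  ))
  part <- c(
    absorbed_si = x$m_ox_abs_si, absorbed_colon = x$m_ox_abs_colon,
    consumed = x$consumed, fecal = x$fecal, residual = x$residual
  )
  pct <- if (m > 0) 100 * part / m else part * NA
  for (nm in names(part)) {
    cat(sprintf("  %-15s %.4f mmol (%5.1f%%)\n", nm, part[[nm]], pct[[nm]]))
  }
  invisible(x)
}
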
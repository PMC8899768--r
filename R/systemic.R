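# Plasma oxalate balance and urinary excretion: first-order clearance with a
# closed-form exponential approach between steady states.

#' Plasma oxalate influx rate
#'
#' Per-meal gut absorption times meals per day (as a daily mean rate) plus
#' endogenous production.
#'
#' @param m_abs_per_meal Absorbed oxalate per meal (mmol).
#' @param sys A [systemic_params()] object.
#' @return Influx rate, mmol/min.
#' @export
plasma_influx <- function(m_abs_per_meal, sys = systemic_params()) {
  stopifnot(all(m_abs_per_meal >= 0))
  m_abs_per_meal * sys$n_daily_meals / MIN_PER_DAY + sys$r_endogenous
}

#' Urinary excretion time course between steady states
#'
#' At steady state the urinary excretion rate equals the plasma influx; after
#' a step change in influx the excretion rate relaxes exponentially with rate
#' `k_urinary`:
#' `r(t) = influx_new + (influx_init - influx_new) * exp(-k_urinary * t)`.
#'
#' @param influx_init Initial steady-state influx (mmol/min).
#' @param influx_new New influx (mmol/min).
#' @param sys A [systemic_params()] object.
#' @param t Time(s) since the change (min).
#' @return Urinary excretion rate(s), mmol/min.
#' @export
urinary_excretion_timecourse <- function(influx_init, influx_new,
                                         sys = systemic_params(), t) {
  stopifnot(all(t >= 0))
  influx_new + (influx_init - influx_new) * exp(-sys$k_urinary * t)
}

#' Convert a urinary excretion rate to mg/day
#'
#' @param rate_mmol_min Excretion rate (mmol/min).
#' @return Urinary oxalate, mg/day.
#' @export
uox_mg_per_day <- function(rate_mmol_min) {
  stopifnot(all(rate_mmol_min >= 0))
  rate_mmol_min * MIN_PER_DAY * OXALATE_MW
}

#' Inverse of [uox_mg_per_day()]
#' @param uox_mg_day Urinary oxalate (mg/day).
#' @return Excretion rate, mmol/min.
#' @export
uox_to_rate <- function(uox_mg_day) {
  uox_mg_day / (MIN_PER_DAY * OXALATE_MW)
}

# Chain the closed-form relaxation across piecewise-constant influx segments.
# segments: data.frame(start_day, influx); returns function(day) -> rate.
chain_influx_segments <- function(r_init, segments, sys) {
  segments <- segments[order(segments$start_day), , drop = FALSE]
  function(day) {
    vapply(day, function(d) {
      r <- r_init
      for (i in seq_len(nrow(segments))) {
        s <- segments$start_day[i]
        if (d <= s) break
        e <- if (i < nrow(segments)) min(segments$start_day[i + 1], d) else d
        r <- urinary_excretion_timecourse(
          r, segments$influx[i], sys, (e - s) * MIN_PER_DAY
        )
      }
      r
    }, numeric(1))
  }
}
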
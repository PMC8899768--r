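# Chyme-volume and bacterial-cell transit through stomach, small intestine
# and colon, and the gastric residence-time distribution.

#' Gastric chyme emptying rate
#'
#' Piecewise emptying flow (ml/min): the time derivative of the
#' power-exponential volume decline up to `tau_linear`, a constant linear
#' drain `V(tau_linear)/(tau_gastric - tau_linear)` up to `tau_gastric`, and
#' zero thereafter.
#'
#' @param t Time since the meal (min); vectorized.
#' @param p A [transit_params()] object.
#' @return Emptying rate in ml/min (>= 0).
#' @export
gastric_emptying_rate <- function(t, p) {
  stopifnot(inherits(p, "transit_params"), all(t >= 0))
  v0 <- p$total_gastric_emptying_volume
  th <- p$gastric_half_emptying_time
  b <- p$gastric_shape
  tl <- p$tau_linear
  tg <- p$tau_gastric
  r_lin <- v0 * 2^(-(tl / th)^b) / (tg - tl)
  r <- ifelse(
    t >= tg, 0,
    ifelse(
      t >= tl, r_lin,
      v0 * b * log(2) * t^(b - 1) / th^b * 2^(-(t / th)^b)
    )
  )
  pmax(r, 0)
}

#' Remaining gastric chyme volume
#'
#' Closed-form gastric volume under the piecewise emptying rule; reaches 0
#' at `tau_gastric`.
#'
#' @inheritParams gastric_emptying_rate
#' @return Volume in ml.
#' @export
gastric_volume <- function(t, p) {
  stopifnot(inherits(p, "transit_params"), all(t >= 0))
  v0 <- p$total_gastric_emptying_volume
  th <- p$gastric_half_emptying_time
  b <- p$gastric_shape
  tl <- p$tau_linear
  tg <- p$tau_gastric
  v_tl <- v0 * 2^(-(tl / th)^b)
  ifelse(
    t >= tg, 0,
    ifelse(
      t >= tl, v_tl * (tg - t) / (tg - tl),
      v0 * 2^(-(t / th)^b)
    )
  )
}

#' Fluid secretion rate into the small intestine
#'
#' Proportional to the gastric emptying rate by the ratio of total secretions
#' volume to total gastric emptying volume.
#'
#' @inheritParams gastric_emptying_rate
#' @export
secretion_rate <- function(t, p) {
  stopifnot(inherits(p, "transit_params"))
  if (p$total_gastric_emptying_volume <= 0) {
    stop("secretion_rate: total_gastric_emptying_volume must be > 0")
  }
  gastric_emptying_rate(t, p) *
    p$total_secretions_volume / p$total_gastric_emptying_volume
}

#' Windowed SI / colonic chyme emptying rate
#'
#' Constant emptying of the total compartment volume over a window of width
#' `tau_gastric`, starting at `tau_si` (SI) or `tau_si + tau_colon` (colon);
#' zero outside the window.
#'
#' @inheritParams gastric_emptying_rate
#' @param compartment `"si"` or `"colon"`.
#' @export
window_emptying_rate <- function(t, p, compartment = c("si", "colon")) {
  stopifnot(inherits(p, "transit_params"), all(t >= 0))
  compartment <- match.arg(compartment)
  if (compartment == "si") {
    start <- p$tau_si
    vol <- p$total_si_emptying_volume
  } else {
    start <- p$tau_si + p$tau_colon
    vol <- p$total_colon_emptying_volume
  }
  ifelse(t >= start & t < start + p$tau_gastric, vol / p$tau_gastric, 0)
}

# Smoothed proportional drain: flux of quantity x (volume itself, oxalate or
# cells) out of a compartment of volume v under chyme emptying rate r. The
# regularization volume eps makes the right-hand side continuous as the
# compartment empties (a hard switch at v = 0 stalls the stiff solver) while
# keeping the flux within a fraction eps/(v+eps) of the exact r*x/v.
drain_flux <- function(r, x, v, eps = 0.1) {
  r * max(x, 0) / (max(v, 0) + eps)
}

# Breakpoints of the piecewise transit right-hand side; integration restarts
# at each to avoid stepping over discontinuities.
transit_breakpoints <- function(p, horizon) {
  b <- c(
    0, p$tau_linear, p$tau_gastric, p$tau_si, p$tau_si + p$tau_gastric,
    p$tau_si + p$tau_colon, p$tau_si + p$tau_colon + p$tau_gastric, horizon
  )
  sort(unique(b[b <= horizon]))
}

# Integrate an ODE system piecewise between breakpoints with optional state
# injections (list of time -> function(state) -> state). Returns the bound
# deSolve output matrix.
integrate_piecewise <- function(rhs, y0, horizon, breakpoints,
                                injections = list(), dt_out = 5,
                                rtol = 1e-8, atol = 1e-10) {
  brk <- sort(unique(c(breakpoints, as.numeric(names(injections)), horizon)))
  brk <- brk[brk >= 0 & brk <= horizon]
  if (brk[1] > 0) brk <- c(0, brk)
  out <- NULL
  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]
    t1 <- brk[i + 1]
    inj <- injections[[as.character(t0)]]
    if (!is.null(inj)) y <- inj(y)
    if (t1 - t0 < 1e-12) next
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    seg <- deSolve::lsoda(y, times, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(seg, "istate")[1] < 0) {
      stop(sprintf(
        "ODE solver failed in segment [%.1f, %.1f] min", t0, t1
      ))
    }
    y <- seg[nrow(seg), -1]
    out <- if (is.null(out)) seg else rbind(out[-nrow(out), , drop = FALSE], seg)
  }
  out
}

#' Integrate chyme-volume transit
#'
#' Solves the three-compartment chyme volume balances (gastric emptying,
#' secretions, windowed SI/colon emptying, first-order fluid absorption in SI
#' and colon) over the simulation horizon.
#'
#' @param p A [transit_params()] object.
#' @param horizon Simulation horizon (min); must cover
#'   `tau_si + tau_colon + tau_gastric` (default 48 h).
#' @param dt_out Output grid spacing (min).
#' @return A data frame of class `chyme_state`: `time`, `v_gastric`, `v_si`,
#'   `v_colon`, plus cumulative `fl_abs_si`, `fl_abs_colon`, `fl_fecal`.
#' @export
integrate_transit <- function(p, horizon = 2880, dt_out = 5) {
  stopifnot(inherits(p, "transit_params"))
  if (horizon < p$tau_si + p$tau_colon + p$tau_gastric) {
    stop("integrate_transit: horizon must cover tau_si + tau_colon + tau_gastric")
  }
  rhs <- function(t, y, parms) {
    v_si <- max(y[["v_si"]], 0)
    v_col <- max(y[["v_colon"]], 0)
    r_g <- gastric_emptying_rate(t, p)
    r_sec <- secretion_rate(t, p)
    r_si <- drain_flux(window_emptying_rate(t, p, "si"), v_si, v_si)
    r_col <- drain_flux(window_emptying_rate(t, p, "colon"), v_col, v_col)
    a_si <- p$k_si_fluid_abs * v_si
    a_col <- p$k_colon_fluid_abs * v_col
    list(c(
      v_gastric = -r_g,
      v_si = r_g + r_sec - a_si - r_si,
      v_colon = r_si - a_col - r_col,
      fl_abs_si = a_si,
      fl_abs_colon = a_col,
      fl_fecal = r_col
    ))
  }
  y0 <- c(
    v_gastric = p$total_gastric_emptying_volume, v_si = 0, v_colon = 0,
    fl_abs_si = 0, fl_abs_colon = 0, fl_fecal = 0
  )
  out <- integrate_piecewise(rhs, y0, horizon, transit_breakpoints(p, horizon),
                             dt_out = dt_out)
  res <- as.data.frame(out)
  names(res)[1] <- "time"
  # clip solver-tolerance negatives
  vol_cols <- c("v_gastric", "v_si", "v_colon")
  res[vol_cols] <- lapply(res[vol_cols], pmax, 0)
  class(res) <- c("chyme_state", class(res))
  res
}

#' Integrate bacterial-cell transit
#'
#' Cells empty from each compartment in proportion to the chyme emptying rate
#' and the cell concentration (cells per ml of chyme); no growth or death, so
#' total cells are conserved.
#'
#' @inheritParams integrate_transit
#' @param dose Number of cells administered at t = 0 (any unit; outputs share
#'   it).
#' @return A data frame of class `cfu_state`: `time`, `cfu_gastric`,
#'   `cfu_si`, `cfu_colon`, `cfu_excreted`.
#' @export
integrate_cfu <- function(p, dose, horizon = 2880, dt_out = 5) {
  stopifnot(inherits(p, "transit_params"), dose >= 0)
  if (horizon < p$tau_si + p$tau_colon + p$tau_gastric) {
    stop("integrate_cfu: horizon must cover tau_si + tau_colon + tau_gastric")
  }
  rhs <- function(t, y, parms) {
    v_si <- max(y[["v_si"]], 0)
    v_col <- max(y[["v_colon"]], 0)
    v_g <- max(y[["v_gastric"]], 0)
    r_g <- gastric_emptying_rate(t, p)
    r_sec <- secretion_rate(t, p)
    w_si <- window_emptying_rate(t, p, "si")
    w_col <- window_emptying_rate(t, p, "colon")
    r_si <- drain_flux(w_si, v_si, v_si)
    r_col <- drain_flux(w_col, v_col, v_col)
    f_g <- drain_flux(r_g, y[["cfu_gastric"]], v_g, eps = 1e-6)
    f_si <- drain_flux(w_si, y[["cfu_si"]], v_si)
    f_col <- drain_flux(w_col, y[["cfu_colon"]], v_col)
    list(c(
      v_gastric = -r_g,
      v_si = r_g + r_sec - p$k_si_fluid_abs * v_si - r_si,
      v_colon = r_si - p$k_colon_fluid_abs * v_col - r_col,
      cfu_gastric = -f_g,
      cfu_si = f_g - f_si,
      cfu_colon = f_si - f_col,
      cfu_excreted = f_col
    ))
  }
  y0 <- c(
    v_gastric = p$total_gastric_emptying_volume, v_si = 0, v_colon = 0,
    cfu_gastric = dose, cfu_si = 0, cfu_colon = 0, cfu_excreted = 0
  )
  out <- integrate_piecewise(rhs, y0, horizon, transit_breakpoints(p, horizon),
                             dt_out = dt_out)
  res <- as.data.frame(out)
  names(res)[1] <- "time"
  cfu_cols <- c("cfu_gastric", "cfu_si", "cfu_colon", "cfu_excreted")
  res[cfu_cols] <- lapply(res[cfu_cols], pmax, 0)
  class(res) <- c("cfu_state", class(res))
  res[c("time", cfu_cols)]
}

#' Gastric residence-time distribution
#'
#' The probability distribution of the time a dosed cell spends in the
#' stomach, derived from the emptying curve (cells transit with chyme):
#' density proportional to the emptying rate, truncated at `tau_gastric`.
#' The median equals the half gastric emptying time whenever
#' `tau_linear` exceeds it.
#'
#' @param p A [transit_params()] object.
#' @return An object of class `residence_dist` with elements `density(t)`,
#'   `cdf(t)`, `quantile(q)`, `median` and `support`.
#' @export
residence_time_distribution <- function(p) {
  stopifnot(inherits(p, "transit_params"))
  v0 <- p$total_gastric_emptying_volume
  tg <- p$tau_gastric
  dens <- function(t) {
    ifelse(t < 0 | t > tg, 0, gastric_emptying_rate(t, p) / v0)
  }
  cdf <- function(t) {
    ifelse(t <= 0, 0, ifelse(t >= tg, 1, 1 - gastric_volume(t, p) / v0))
  }
  th <- p$gastric_half_emptying_time
  b <- p$gastric_shape
  tl <- p$tau_linear
  f_tl <- 1 - 2^(-(tl / th)^b)
  qf <- function(q) {
    stopifnot(all(q >= 0 & q <= 1))
    ifelse(
      q <= f_tl,
      th * (-log2(1 - pmin(q, 1 - 1e-15)))^(1 / b),
      tl + (q - f_tl) / (1 - f_tl) * (tg - tl)
    )
  }
  structure(list(
    density = dens, cdf = cdf, quantile = qf,
    median = qf(0.5), support = c(0, tg)
  ), class = "residence_dist")
}

#' @export
print.residence_dist <- function(x, ...) {
  cat(sprintf(
    "Gastric residence-time distribution on [%.0f, %.0f] min; median %.1f min\n",
    x$support[1], x$support[2], x$median
  ))
  q <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  print(stats::setNames(round(x$quantile(q), 1), paste0("q", q * 100)))
  invisible(x)
}
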
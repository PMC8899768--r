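# Least-squares fits for the calibration sub-models: per-pH exponential
# activity decay, the oxygen line, Michaelis-Menten constants from rate
# measurements, and the dietary-absorption exponential.

#' Fit per-pH exponential activity decay constants
#'
#' For each pH level, fits `A(t) = exp(-k t)` to normalized activity by a
#' log-linear least-squares fit through the origin (the data are normalized,
#' so `A(0) = 1` is imposed), with `k` constrained non-negative. Activities
#' at or below a floor are clipped before taking logs.
#'
#' @param data Data frame with columns `ph`, `exposure_min`,
#'   `normalized_activity` (replicates as repeated rows).
#' @param floor Lower clip on activity before the log transform.
#' @return A pH decay table: data frame with columns `ph`, `k` (1/min) and
#'   `rss` (residual sum of squares on the log scale).
#' @export
fit_ph_decay <- function(data, floor = 1e-6) {
  stopifnot(all(c("ph", "exposure_min", "normalized_activity") %in% names(data)))
  out <- lapply(split(data, data$ph), function(d) {
    if (length(unique(d$exposure_min)) < 2) {
      stop("fit_ph_decay: need >= 2 exposure times per pH level (pH ",
           d$ph[1], ")")
    }
    if (all(d$normalized_activity <= 0)) {
      warning("fit_ph_decay: all-zero activities at pH ", d$ph[1],
              "; decay constant set to upper bound")
      return(data.frame(ph = d$ph[1], k = -log(floor) / min(d$exposure_min),
                        rss = NA_real_))
    }
    y <- log(pmax(d$normalized_activity, floor))
    t <- d$exposure_min
    k <- max(0, -sum(t * y) / sum(t * t))
    data.frame(ph = d$ph[1], k = k, rss = sum((y + k * t)^2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$ph), ]
}

#' Fit the oxygen-inhibition line
#'
#' Ordinary least squares of normalized activity on oxygen fraction.
#'
#' @param points Data frame with columns `o2_fraction`, `activity`.
#' @return List with `slope`, `intercept` and the fitted `points`.
#' @export
fit_oxygen_line <- function(points = default_o2_points()) {
  stopifnot(
    all(c("o2_fraction", "activity") %in% names(points)),
    nrow(points) >= 2
  )
  if (length(unique(points$o2_fraction)) < 2) {
    stop("fit_oxygen_line: degenerate oxygen fractions")
  }
  fit <- stats::lm(activity ~ o2_fraction, data = points)
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    points = points
  )
}

#' Estimate Michaelis-Menten constants from rate measurements
#'
#' Nonlinear least squares of `v = Vmax * S / (KM + S)` on
#' (concentration, per-cell rate) records. With a single saturating
#' measurement the Michaelis constant is not identifiable and is fixed to
#' `km_default` with a flag.
#'
#' @param rate_data Data frame with columns `conc_mM`, `rate` (per-cell rate,
#'   umol/h per 1e9 cells).
#' @param km_default Fallback Michaelis constant (mM) when KM is not
#'   identifiable.
#' @return List with `vmax`, `km`, `km_assumed` flag, `rss`, `converged`.
#' @export
estimate_vmax_km <- function(rate_data, km_default = 2) {
  stopifnot(all(c("conc_mM", "rate") %in% names(rate_data)))
  if (length(unique(rate_data$conc_mM)) == 1) {
    return(list(
      vmax = mean(rate_data$rate), km = km_default, km_assumed = TRUE,
      rss = sum((rate_data$rate - mean(rate_data$rate))^2), converged = TRUE
    ))
  }
  v0 <- max(rate_data$rate)
  k0 <- max(min(rate_data$conc_mM), v0 * stats::median(rate_data$conc_mM) /
              max(stats::median(rate_data$rate), 1e-12) -
              stats::median(rate_data$conc_mM))
  fit <- try(stats::nls(
    rate ~ vmax * conc_mM / (km + conc_mM),
    data = rate_data,
    start = list(vmax = v0, km = max(k0, 1e-3)),
    algorithm = "port", lower = c(vmax = 1e-12, km = 1e-9),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("estimate_vmax_km: nonlinear fit failed: ", attr(fit, "condition")$message)
  }
  cf <- stats::coef(fit)
  list(
    vmax = unname(cf["vmax"]), km = unname(cf["km"]), km_assumed = FALSE,
    rss = sum(stats::residuals(fit)^2), converged = fit$convInfo$isConv
  )
}

#' Fit the dietary absorption-fraction exponential
#'
#' Least-squares fit of `f(d) = a * exp(-b * d) + c` to
#' (diet, absorbed fraction) observations with `a, b >= 0`.
#'
#' @param points Data frame with columns `diet_mg_day`, `f_abs`.
#' @return List with `a`, `b`, `c`, `rss`, `converged`.
#' @export
fit_fabs_exponential <- function(points) {
  stopifnot(
    all(c("diet_mg_day", "f_abs") %in% names(points)),
    nrow(points) >= 3
  )
  y <- points$f_abs
  d <- points$diet_mg_day
  if (stats::sd(y) < 1e-12) {
    return(list(a = 0, b = 0, c = mean(y), rss = 0, converged = TRUE))
  }
  c0 <- max(min(y) * 0.9, 1e-6)
  a0 <- max(max(y) - c0, 1e-6)
  # crude slope-based initial decay rate
  b0 <- max(1e-5, log(max((y[1] - c0) / max(y[length(y)] - c0, 1e-9), 1.01)) /
              max(d[length(d)] - d[1], 1))
  fit <- try(stats::nls(
    f_abs ~ a * exp(-b * diet_mg_day) + c,
    data = points,
    start = list(a = a0, b = b0, c = c0),
    algorithm = "port", lower = c(a = 0, b = 0, c = 0),
    control = stats::nls.control(maxiter = 500, warnOnly = TRUE)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop(
      "fit_fabs_exponential: fit failed (starting values a=", signif(a0, 3),
      ", b=", signif(b0, 3), ", c=", signif(c0, 3), "): ",
      attr(fit, "condition")$message
    )
  }
  cf <- stats::coef(fit)
  list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
    rss = sum(stats::residuals(fit)^2), converged = fit$convInfo$isConv
  )
}
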
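# Synthetic calibration datasets with known ground truth, emulating the
# in vitro protocols statistically so every fitting stage is testable
# offline.

#' Generate a synthetic pH-hold activity dataset
#'
#' Emulates the acid-hold experiment: cells held at each pH, aliquots pulled
#' at a grid of exposure times, activity normalized to the unexposed control.
#' Activities are `exp(-k_pH * t) * (1 + eps)` with multiplicative Gaussian
#' noise, truncated at 0.
#'
#' @param truth pH decay table (columns `ph`, `k`) serving as ground truth.
#' @param times Exposure times (min).
#' @param replicates Replicates per (pH, time).
#' @param noise_sd SD of the multiplicative noise.
#' @param seed RNG seed.
#' @return Data frame with columns `ph`, `exposure_min`,
#'   `normalized_activity`, `replicate`; attribute `truth`.
#' @export
generate_ph_hold <- function(truth = default_ph_decay_table(),
                             times = c(5, 30, 60, 90, 120),
                             replicates = 3, noise_sd = 0.03, seed = 1) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  set.seed(seed)
  grid <- expand.grid(
    replicate = seq_len(replicates), exposure_min = times, ph = truth$ph
  )
  k <- truth$k[match(grid$ph, truth$ph)]
  mu <- exp(-k * grid$exposure_min)
  act <- pmax(mu * (1 + stats::rnorm(nrow(grid), 0, noise_sd)), 0)
  out <- data.frame(
    ph = grid$ph, exposure_min = grid$exposure_min,
    normalized_activity = act, replicate = grid$replicate
  )
  attr(out, "truth") <- truth
  out
}

#' Generate synthetic per-cell consumption rates across the GI simulation
#'
#' Stage-labeled per-cell rates anchored at the measured values in simulated
#' gastric (SGF), intestinal (SIF) and colonic (SCF) fluids, with Gaussian
#' noise at the stated per-stage SDs.
#'
#' @param anchors Data frame with columns `stage`, `time_h`, `rate`, `sd`
#'   (umol/h per 1e9 cells).
#' @param replicates Replicates per anchor.
#' @param noise Scale on the per-stage SDs (0 disables noise).
#' @param seed RNG seed.
#' @return Data frame with columns `stage`, `time_h`, `rate`, `replicate`.
#' @export
generate_ivs_rates <- function(anchors = default_ivs_anchors(),
                               replicates = 3, noise = 1, seed = 1) {
  stopifnot(noise >= 0)
  set.seed(seed)
  grid <- anchors[rep(seq_len(nrow(anchors)), each = replicates), ]
  grid$replicate <- rep(seq_len(replicates), nrow(anchors))
  grid$rate <- pmax(
    grid$rate + stats::rnorm(nrow(grid), 0, noise * grid$sd), 0
  )
  rownames(grid) <- NULL
  grid[c("stage", "time_h", "rate", "replicate")]
}

#' Measured per-cell rate anchors of the in vitro GI simulation
#'
#' @return Data frame of the printed stage rates (umol/h per 1e9 cells) and
#'   their SDs.
#' @export
default_ivs_anchors <- function() {
  data.frame(
    stage = c("SGF", "SGF", "SIF", "SCF"),
    time_h = c(1, 2, 2, 0),
    rate = c(1.35, 1.52, 0.88, 0.2),
    sd = c(0.04, 0.08, 0.04, 0.14)
  )
}

#' Generate a simulated subject population
#'
#' Subjects carry a multiplicative lognormal factor (mean 1) on the dietary
#' absorption fraction.
#'
#' @param n Number of subjects.
#' @param cv Coefficient of variation of the factor.
#' @param seed RNG seed.
#' @return Data frame with columns `subject`, `factor`.
#' @export
generate_population <- function(n, cv = 0.12, seed = 1) {
  stopifnot(n >= 1, cv >= 0)
  set.seed(seed)
  if (cv == 0) {
    factor <- rep(1, n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    factor <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(subject = seq_len(n), factor = factor)
}

#' Generate synthetic dietary-absorption observations
#'
#' Absorbed fractions `a*exp(-b*d) + c` over a grid of daily intakes with
#' additive Gaussian noise; supports recovery testing of
#' [fit_fabs_exponential()].
#'
#' @param a,b,c True coefficients.
#' @param diets Daily intake grid (mg/day).
#' @param noise_sd Additive noise SD on the fraction.
#' @param seed RNG seed.
#' @return Data frame with columns `diet_mg_day`, `f_abs`.
#' @export
generate_fabs_points <- function(a = 0.035, b = 0.004, c = 0.06,
                                 diets = seq(10, 1000, by = 30),
                                 noise_sd = 0.001, seed = 1) {
  set.seed(seed)
  f <- a * exp(-b * diets) + c
  data.frame(
    diet_mg_day = diets,
    f_abs = pmax(f + stats::rnorm(length(diets), 0, noise_sd), 0)
  )
}

#' Generate synthetic Michaelis-Menten rate data
#'
#' @param vmax,km True constants.
#' @param conc_mM Substrate concentration grid (mM).
#' @param noise_sd Additive noise SD on the rate.
#' @param seed RNG seed.
#' @return Data frame with columns `conc_mM`, `rate`.
#' @export
generate_mm_rates <- function(vmax = 1.98, km = 2,
                              conc_mM = c(0.25, 0.5, 1, 2, 4, 8, 16),
                              noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  v <- vmax * conc_mM / (km + conc_mM)
  data.frame(
    conc_mM = conc_mM,
    rate = pmax(v + stats::rnorm(length(conc_mM), 0, noise_sd), 0)
  )
}
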
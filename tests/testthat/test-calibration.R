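test_that("pH decay fits recover known constants exactly without noise", {
  truth <- default_ph_decay_table()
  data <- generate_ph_hold(truth, noise_sd = 0, seed = 3)
  fit <- fit_ph_decay(data)
  expect_equal(fit$k, truth$k, tolerance = 1e-10)
})

test_that("pH decay fits recover constants within 5% at default noise", {
  truth <- default_ph_decay_table()
  data <- generate_ph_hold(truth, seed = 101)
  fit <- fit_ph_decay(data)
  nonzero <- truth$k > 0
  expect_true(all(
    abs(fit$k[nonzero] - truth$k[nonzero]) / truth$k[nonzero] < 0.05
  ))
  # pH 7 series stays near 100% activity, so its constant is ~0
  expect_lt(fit$k[fit$ph == 7], 1e-3)
})

test_that("log-linear decay fit agrees with a direct nonlinear fit", {
  truth <- data.frame(ph = 4, k = 0.012)
  data <- generate_ph_hold(truth, noise_sd = 0.02, seed = 5)
  fit <- fit_ph_decay(data)
  # independent oracle: direct nonlinear least squares on the linear scale
  nls_fit <- stats::nls(
    normalized_activity ~ exp(-k * exposure_min),
    data = data, start = list(k = 0.005)
  )
  expect_equal(fit$k, unname(coef(nls_fit)["k"]), tolerance = 0.05)
})

test_that("pH decay fit is invariant to record order", {
  data <- generate_ph_hold(seed = 9)
  shuffled <- data[sample(nrow(data)), ]
  expect_equal(fit_ph_decay(data)$k, fit_ph_decay(shuffled)$k)
})

test_that("oxygen line fit matches the printed anchors and OLS", {
  line <- fit_oxygen_line()
  # two-point input reproduces the interpolating line
  two <- fit_oxygen_line(data.frame(o2_fraction = c(0, 0.2),
                                    activity = c(0.5, 1.0)))
  expect_equal(two$slope, 2.5)
  expect_equal(two$intercept, 0.5)
  # the fitted line minimizes SSE against perturbed alternatives
  pts <- default_o2_points()
  sse <- function(a, b) sum((pts$activity - a - b * pts$o2_fraction)^2)
  best <- sse(line$intercept, line$slope)
  for (d in c(-0.02, 0.02)) {
    expect_gt(sse(line$intercept + d, line$slope), best)
    expect_gt(sse(line$intercept, line$slope + d), best)
  }
  expect_error(
    fit_oxygen_line(data.frame(o2_fraction = c(0.1, 0.1),
                               activity = c(0.5, 0.6))),
    "degenerate"
  )
})

test_that("Michaelis-Menten estimation recovers truth and flags saturation", {
  clean <- generate_mm_rates(vmax = 1.98, km = 2, noise_sd = 0, seed = 1)
  fit <- estimate_vmax_km(clean)
  expect_equal(fit$vmax, 1.98, tolerance = 1e-6)
  expect_equal(fit$km, 2, tolerance = 1e-5)
  expect_false(fit$km_assumed)

  noisy <- generate_mm_rates(vmax = 1.98, km = 2, seed = 21)
  fit_n <- estimate_vmax_km(noisy)
  expect_lt(abs(fit_n$vmax - 1.98) / 1.98, 0.10)
  expect_lt(abs(fit_n$km - 2) / 2, 0.10)

  single <- data.frame(conc_mM = 10, rate = 1.35)
  fit_s <- estimate_vmax_km(single)
  expect_equal(fit_s$vmax, 1.35)
  expect_true(fit_s$km_assumed)
})

test_that("dietary-absorption exponential fit recovers its coefficients", {
  clean <- generate_fabs_points(noise_sd = 0, seed = 1)
  fit <- fit_fabs_exponential(clean)
  expect_equal(fit$a, 0.035, tolerance = 1e-4)
  expect_equal(fit$b, 0.004, tolerance = 1e-4)
  expect_equal(fit$c, 0.06, tolerance = 1e-4)

  noisy <- generate_fabs_points(seed = 31)
  fit_n <- fit_fabs_exponential(noisy)
  expect_lt(abs(fit_n$a - 0.035) / 0.035, 0.10)
  expect_lt(abs(fit_n$b - 0.004) / 0.004, 0.10)
  expect_lt(abs(fit_n$c - 0.06) / 0.06, 0.10)

  flat <- data.frame(diet_mg_day = c(100, 200, 300), f_abs = rep(0.07, 3))
  fit_f <- fit_fabs_exponential(flat)
  expect_equal(fit_f$a * fit_f$b, 0, tolerance = 1e-8)
  expect_equal(fit_f$a * exp(-fit_f$b * 200) + fit_f$c, 0.07,
               tolerance = 1e-6)
})
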
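test_that("oxalate emptying and absorption rate primitives behave as defined", {
  p <- transit_params()
  expect_equal(oxalate_emptying_rate("gastric", 60, 0, 500, p), 0)
  # uniform concentration c times the chyme rate
  c0 <- 0.5 / 500
  expect_equal(
    oxalate_emptying_rate("gastric", 60, 0.5, 500, p),
    gastric_emptying_rate(60, p) * c0
  )
  expect_equal(oxalate_emptying_rate("si", p$tau_si + 10, 0.5, 400, p),
               window_emptying_rate(p$tau_si + 10, p, "si") * 0.5 / 400)
  expect_equal(oxalate_absorption_rate(0.4, 0), 0)
  expect_equal(oxalate_absorption_rate(0.8, 1e-4),
               2 * oxalate_absorption_rate(0.4, 1e-4))
})

test_that("strain-free meal reproduces the calibrated absorption fraction", {
  m <- default_model()
  cal <- cached_calibration(200)
  meal <- meal_spec(200 / 3, 0)
  sim <- integrate_meal(meal, m$transit, m$strain, cal, dt_out = 60)
  f <- dietary_absorption_fraction(200, cal, "healthy")
  expect_equal(sim$m_ox_abs_total / meal$oxalate_mmol, f, tolerance = 0.01)
  expect_equal(sim$m_ox_abs_total, sim$m_ox_abs_si + sim$m_ox_abs_colon)
  expect_equal(sim$consumed, 0)
})

test_that("oxalate mass balance closes for undosed and dosed meals", {
  m <- default_model()
  cal <- cached_calibration(200)
  for (dose in c(0, 2e11)) {
    sim <- integrate_meal(meal_spec(200 / 3, dose), m$transit, m$strain, cal,
                          dt_out = 60)
    total <- sim$m_ox_abs_total + sim$consumed + sim$fecal + sim$residual
    expect_equal(total, sim$meal$oxalate_mmol, tolerance = 1e-3)
  }
})

test_that("without absorption or strain, everything is excreted", {
  m <- default_model()
  a <- m$absorption
  a$k_si_oxalate_abs <- 0
  a$k_colon_oxalate_abs <- 0
  meal <- meal_spec(200 / 3, 0)
  sim <- integrate_meal(meal, m$transit, m$strain, a, dt_out = 60)
  expect_equal(sim$m_ox_abs_total, 0)
  expect_equal(sim$fecal + sim$residual, meal$oxalate_mmol, tolerance = 1e-3)
  # nearly all of it leaves as feces under default transit
  expect_gt(sim$fecal / meal$oxalate_mmol, 0.9)
})

test_that("dosing strictly reduces absorbed oxalate", {
  m <- default_model()
  cal <- cached_calibration(200)
  free <- integrate_meal(meal_spec(200 / 3, 0), m$transit, m$strain, cal,
                         dt_out = 60)
  low <- integrate_meal(meal_spec(200 / 3, 1e11), m$transit, m$strain, cal,
                        dt_out = 60)
  high <- integrate_meal(meal_spec(200 / 3, 5e11), m$transit, m$strain, cal,
                         dt_out = 60)
  expect_lt(low$m_ox_abs_total, free$m_ox_abs_total)
  expect_lt(high$m_ox_abs_total, low$m_ox_abs_total)
  expect_gt(low$consumed, 0)
  expect_gt(high$consumed, low$consumed)
})

test_that("relaxing inhibition modifiers only increases consumption", {
  m <- default_model()
  cal <- cached_calibration(200)
  base <- integrate_meal(meal_spec(200 / 3, 1e11), m$transit, m$strain, cal,
                         dt_out = 60)
  uninhibited <- strain_params(
    vmax = m$strain$vmax, km = m$strain$km,
    activity_cap_downstream = 1,
    ph_decay_table = data.frame(ph = c(2, 7), k = c(0, 0)),
    o2_points = data.frame(o2_fraction = c(0, 0.21), activity = c(1, 1)),
    scf_rate = m$strain$vmax # no colonic rescaling
  )
  free_run <- integrate_meal(meal_spec(200 / 3, 1e11), m$transit, uninhibited,
                             cal, dt_out = 60)
  expect_gt(free_run$consumed, base$consumed)
})

test_that("uncalibrated absorption constants are rejected", {
  m <- default_model()
  expect_error(
    integrate_meal(meal_spec(60, 0), m$transit, m$strain, m$absorption),
    "not calibrated"
  )
})
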
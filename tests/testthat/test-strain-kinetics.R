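test_that("gastric pH relaxes from fed to fasted with the stated half-time", {
  cv <- gastric_ph_curve()
  expect_equal(gastric_ph(0, cv), cv$ph_fed)
  expect_equal(gastric_ph(cv$half_time, cv), (cv$ph_fed + cv$ph_fasted) / 2)
  expect_equal(gastric_ph(1e6, cv), cv$ph_fasted, tolerance = 1e-8)
  t <- seq(0, 600, by = 5)
  expect_true(all(diff(gastric_ph(t, cv)) <= 0))
})

test_that("pH decay constants interpolate linearly and clamp at the ends", {
  tab <- default_ph_decay_table()
  # exact at the knots
  expect_equal(ph_decay_constant(tab$ph, tab), tab$k)
  # arithmetic mean between adjacent knots
  expect_equal(
    ph_decay_constant(4.5, tab),
    (tab$k[tab$ph == 4] + tab$k[tab$ph == 5]) / 2
  )
  expect_equal(ph_decay_constant(1.0, tab), tab$k[tab$ph == 2])
  expect_equal(ph_decay_constant(7.0, tab), 0)
  expect_equal(ph_decay_constant(8.5, tab), 0)
  expect_error(ph_decay_constant(-1, tab), "outside")
})

test_that("cumulative acid damage matches the closed form at constant pH", {
  expect_equal(cumulative_acid_damage(0), 1)
  # constant-pH trajectory: damage is exp(-k(pH) * t)
  flat <- gastric_ph_curve(ph_fed = 4.0, ph_fasted = 3.9999999,
                           half_time = 1e9, shape = 1.81)
  tab <- default_ph_decay_table()
  k4 <- ph_decay_constant(4, tab)
  for (tt in c(30, 60, 120)) {
    expect_equal(
      cumulative_acid_damage(tt, flat, tab), exp(-k4 * tt),
      tolerance = 1e-6
    )
  }
  # pH 7 hold: essentially no damage
  neutral <- gastric_ph_curve(ph_fed = 7.0, ph_fasted = 6.9999999,
                              half_time = 1e9, shape = 1.81)
  expect_equal(cumulative_acid_damage(120, neutral, tab), 1, tolerance = 1e-6)
})

test_that("acid damage composes multiplicatively along a trajectory", {
  cv <- gastric_ph_curve()
  tab <- default_ph_decay_table()
  d_all <- cumulative_acid_damage(180, cv, tab)
  d1 <- cumulative_acid_damage(60, cv, tab)
  # damage over [60, 180] from the integral difference
  d2 <- d_all / d1
  # recompute [60,180] segment by fine quadrature of k(pH(s))
  s <- seq(60, 180, by = 0.05)
  k <- ph_decay_constant(gastric_ph(s, cv), tab)
  seg <- exp(-sum((k[-1] + k[-length(k)]) / 2 * diff(s)))
  expect_equal(d2, seg, tolerance = 1e-5)
  # monotone non-increasing in residence time
  tt <- seq(0, 240, by = 10)
  expect_true(all(diff(cumulative_acid_damage(tt, cv, tab)) <= 0))
})

test_that("downstream activity is the damage factor under a 75% cap", {
  sp <- strain_params()
  expect_equal(downstream_activity_factor(0, sp), 0.75)
  d240 <- downstream_activity_factor(240, sp)
  expect_lt(d240, 0.75)
  expect_gt(d240, 0)
  sp_nocap <- strain_params(activity_cap_downstream = 1)
  t <- c(0, 60, 120, 240)
  expect_equal(
    downstream_activity_factor(t, sp_nocap),
    cumulative_acid_damage(t, sp$gastric_ph_curve, sp$ph_decay_table),
    tolerance = 1e-12
  )
})

test_that("oxygen inhibition is the normalized least-squares line", {
  pts <- default_o2_points()
  line <- fit_oxygen_line(pts)
  # OLS oracle via lm in the test itself
  ref <- stats::lm(activity ~ o2_fraction, data = pts)
  expect_equal(line$slope, unname(coef(ref)[2]))
  expect_equal(oxygen_inhibition(0.21, line), 1)
  at105 <- unname(predict(ref, data.frame(o2_fraction = 0.105)) /
                    predict(ref, data.frame(o2_fraction = 0.21)))
  expect_equal(oxygen_inhibition(0.105, line), at105, tolerance = 1e-10)
  # clipping
  expect_equal(oxygen_inhibition(1, line), 1)
  expect_true(all(oxygen_inhibition(seq(0, 1, 0.05), line) <= 1))
})

test_that("extended colonic activity interpolates and extrapolates flat", {
  curve <- data.frame(hold_h = c(0, 6, 16, 24, 40, 48),
                      activity = c(1, 0.9, 0.8, 0.8, 0.7, 0.7))
  expect_equal(extended_colonic_activity(0, curve), 1)
  expect_equal(extended_colonic_activity(6 * 60, curve), 0.9)
  expect_equal(extended_colonic_activity(11 * 60, curve), 0.85)
  expect_equal(extended_colonic_activity(72 * 60, curve), 0.7)
})

test_that("consumption follows Michaelis-Menten with the modifier stack", {
  sp <- strain_params()
  # S = KM: half of the modifier-adjusted maximal rate (SI, cap binding)
  vol <- 100
  ox_at_km <- sp$km * vol / 1000 # mmol giving S = KM
  r <- consumption_rate("si", ox_at_km, vol, cfu = 10, params = sp,
                        cohort_factors = 0.75)
  o2_si <- oxygen_inhibition(sp$compartment_o2[["si"]], sp$o2_line)
  expect_equal(r, 0.5 * sp$vmax * 1e-3 / 60 * 10 * 0.75 * o2_si,
               tolerance = 1e-12)
  expect_equal(consumption_rate("si", ox_at_km, vol, cfu = 0, params = sp), 0)
  expect_equal(consumption_rate("si", 0, vol, cfu = 10, params = sp), 0)
  # monotone in substrate, cells and vmax
  r2 <- consumption_rate("si", 2 * ox_at_km, vol, 10, sp, cohort_factors = 0.75)
  expect_gt(r2, r)
  r3 <- consumption_rate("si", ox_at_km, vol, 20, sp,
                         cohort_factors = rep(0.75, 1))
  expect_gt(r3, r)
  # bounded by vmax * cfu * cap
  smax <- consumption_rate("si", 1e4, vol, 10, sp, cohort_factors = 0.75)
  expect_lt(smax, sp$vmax * 1e-3 / 60 * 10 * 0.75 + 1e-12)
})

test_that("fresh-cell gastric rate at saturating substrate is of the measured order", {
  sp <- strain_params()
  # 10 mM, 1e9 cells, early in the meal (little acid damage yet)
  vol <- 100
  ox <- 10 * vol / 1000
  r <- consumption_rate("gastric", ox, vol, cfu = 1, params = sp, time = 5)
  r_umol_h <- r * 60 * 1e3 # mmol/min -> umol/h for 1e9 cells
  expect_gt(r_umol_h, 1.0)
  expect_lt(r_umol_h, 1.8)
})

test_that("colonic per-cell rate is anchored to the simulated colonic fluid rate", {
  sp <- strain_params()
  vol <- 100
  ox <- 1e4 # saturating
  r <- consumption_rate("colon", ox, vol, cfu = 1, params = sp,
                        cohort_factors = 0.75, hold_times = 0)
  expect_equal(r * 60 * 1e3, sp$scf_rate, tolerance = 1e-4)
})
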
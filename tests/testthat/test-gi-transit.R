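test_that("gastric emptying rate integrates to the stated volumes", {
  p <- transit_params()
  expect_equal(gastric_emptying_rate(0, p), 0)
  # half the volume empties by the half emptying time (tau_linear > t1/2)
  half <- stats::integrate(function(t) gastric_emptying_rate(t, p),
                           0, p$gastric_half_emptying_time,
                           rel.tol = 1e-10)$value
  expect_equal(half, 0.5 * p$total_gastric_emptying_volume, tolerance = 1e-6)
  # the whole volume empties by tau_gastric; compare against quadrature of
  # the same piecewise rate on a 10x finer grid (midpoint rule oracle)
  grid <- seq(0, p$tau_gastric, length.out = 24001)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  quad <- sum(gastric_emptying_rate(mid, p) * diff(grid))
  expect_equal(quad, p$total_gastric_emptying_volume, tolerance = 1e-5)
  total <- stats::integrate(function(t) gastric_emptying_rate(t, p),
                            0, p$tau_gastric, rel.tol = 1e-10,
                            subdivisions = 500)$value
  expect_equal(total, quad, tolerance = 1e-5)
})

test_that("emptying rate is continuous at the power-exponential/linear switch", {
  p <- transit_params()
  eps <- 1e-6
  expect_equal(
    gastric_emptying_rate(p$tau_linear - eps, p),
    gastric_emptying_rate(p$tau_linear + eps, p),
    tolerance = 1e-6
  )
  expect_equal(gastric_emptying_rate(p$tau_gastric, p), 0)
})

test_that("secretion rate is proportional to gastric emptying", {
  p <- transit_params()
  t <- c(10, 50, 110, 200, 250)
  expect_equal(
    secretion_rate(t, p),
    gastric_emptying_rate(t, p) * p$total_secretions_volume /
      p$total_gastric_emptying_volume
  )
  expect_equal(secretion_rate(p$tau_gastric + 1, p), 0)
  total <- stats::integrate(function(t) secretion_rate(t, p), 0, p$tau_gastric,
                            rel.tol = 1e-10, subdivisions = 500)$value
  expect_equal(total, p$total_secretions_volume, tolerance = 1e-6)
})

test_that("windowed emptying rates cover exactly their windows", {
  p <- transit_params()
  expect_equal(window_emptying_rate(p$tau_si / 2, p, "si"), 0)
  expect_equal(
    window_emptying_rate(p$tau_si + 1, p, "si"),
    p$total_si_emptying_volume / p$tau_gastric
  )
  expect_equal(window_emptying_rate(p$tau_si + p$tau_gastric, p, "si"), 0)
  # colon window starts tau_colon after the SI window
  expect_equal(window_emptying_rate(p$tau_si + p$tau_colon - 1, p, "colon"), 0)
  expect_gt(window_emptying_rate(p$tau_si + p$tau_colon + 1, p, "colon"), 0)
  # constant x width equals the total volume
  expect_equal(
    window_emptying_rate(p$tau_si + 1, p, "si") * p$tau_gastric,
    p$total_si_emptying_volume
  )
})

test_that("chyme volume balance closes on randomized parameter sets", {
  set.seed(42)
  for (i in 1:4) {
    p <- random_transit_params()
    horizon <- p$tau_si + p$tau_colon + p$tau_gastric + 600
    ch <- integrate_transit(p, horizon = horizon)
    fin <- ch[nrow(ch), ]
    total_in <- p$total_gastric_emptying_volume + p$total_secretions_volume
    total_out <- fin$fl_abs_si + fin$fl_abs_colon + fin$fl_fecal +
      fin$v_gastric + fin$v_si + fin$v_colon
    expect_equal(total_out, total_in, tolerance = 1e-3)
    # gastric volume is non-increasing and ~0 from tau_gastric onward
    vg <- ch$v_gastric
    expect_true(all(diff(vg) <= 1e-8))
    expect_lt(max(abs(vg[ch$time >= p$tau_gastric])), 1e-4)
    # SI drains after its window closes
    expect_lt(fin$v_si, 1)
  }
})

test_that("cells are conserved and track the chyme", {
  p <- transit_params()
  cf <- integrate_cfu(p, dose = 1)
  tot <- cf$cfu_gastric + cf$cfu_si + cf$cfu_colon + cf$cfu_excreted
  expect_true(all(abs(tot - 1) < 1e-3))
  fin <- cf[nrow(cf), ]
  expect_equal(fin$cfu_excreted, 1, tolerance = 1e-3)
  # gastric cell fraction equals the gastric volume fraction (cells and
  # volume leave proportionally); oracle is the closed-form volume curve
  pick <- cf$time %in% c(30, 60, 120, 180)
  expect_equal(
    cf$cfu_gastric[pick],
    gastric_volume(cf$time[pick], p) / p$total_gastric_emptying_volume,
    tolerance = 1e-4
  )
  # zero dose stays zero
  cf0 <- integrate_cfu(p, dose = 0)
  expect_true(all(abs(as.matrix(cf0[, -1])) < 1e-12))
})

test_that("residence-time distribution has the documented median and support", {
  p <- transit_params()
  rd <- residence_time_distribution(p)
  expect_equal(rd$median, 110)
  expect_equal(rd$quantile(1), 240)
  expect_equal(rd$quantile(0), 0)
  expect_equal(
    stats::integrate(rd$density, 0, 240, subdivisions = 500)$value, 1,
    tolerance = 1e-4
  )
  # quantile inverts the cdf
  q <- c(0.05, 0.25, 0.5, 0.9, 0.99)
  expect_equal(rd$cdf(rd$quantile(q)), q, tolerance = 1e-8)
})

test_that("invalid transit parameters are rejected", {
  expect_error(transit_params(gastric_shape = 0.9), "exceed 1")
  expect_error(transit_params(gastric_half_emptying_time = -1), "> 0")
  expect_error(transit_params(total_gastric_emptying_volume = 0), "positive")
})
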
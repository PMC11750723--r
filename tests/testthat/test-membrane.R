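calibrated <- calibrate_to_anchor(cable_params())

test_that("truncated lattice sum equals the geometric closed form", {
  for (x in c(0.5, 1, 5)) {
    expect_equal(spatial_summation_factor(x, 1), oracle_g(x, 1),
                 tolerance = 1e-10)
  }
  # isolated-particle limit
  expect_equal(spatial_summation_factor(50, 1), 1, tolerance = 1e-10)
  expect_error(spatial_summation_factor(0, 1), class = "menmod_invalid_input")
})

test_that("spatial summation is strictly decreasing in spacing", {
  d <- seq(0.05, 5, length.out = 100)
  g <- spatial_summation_factor(d, 0.5)
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= 1))
})

test_that("half-cycle increment is exactly proportional to v0", {
  with_seed(21, {
    for (i in 1:50) {
      v0 <- runif(1, 1, 100)
      s <- runif(1, 0.1, 10)
      d <- runif(1, 0.05, 2)
      expect_equal(delta_v_per_half_cycle(s * v0, d, calibrated),
                   s * delta_v_per_half_cycle(v0, d, calibrated),
                   tolerance = 1e-12)
    }
  })
  expect_equal(delta_v_per_half_cycle(0, 0.25, calibrated), 0)
})

test_that("anchor calibration fixes kappa*g to the printed arithmetic", {
  cal <- attr(calibrated, "calibration")
  expect_equal(cal$kg_product, 15000 / (2 * 150 * 2 * 24.5), tolerance = 1e-12)
  expect_equal(cal$kg_product, 1.0204, tolerance = 1e-4)
  # the calibrated lambda reproduces the product through the lattice sum
  expect_equal(
    calibrated$kappa * spatial_summation_factor(0.25, calibrated$lambda_eff),
    cal$kg_product, tolerance = 1e-9)
})

test_that("calibration round-trips a synthetic anchor", {
  lambda_true <- 0.4
  g_true <- oracle_g(0.6, lambda_true)
  # choose the anchor v0 that makes the product consistent with g_true
  v0_anchor <- 15000 / (2 * 100 * 3 * g_true)
  cal <- calibrate_to_anchor(cable_params(), v0 = v0_anchor, d = 0.6,
                             f = 100, epoch = 3)
  expect_equal(attr(cal, "calibration")$kg_product, g_true, tolerance = 1e-9)
  expect_equal(cal$lambda_eff, lambda_true, tolerance = 1e-9)
})

test_that("infeasible anchors raise a calibration error", {
  # v0 so large that the required summation factor drops below 1
  expect_error(calibrate_to_anchor(cable_params(), v0 = 1000),
               class = "menmod_calibration_error")
})

test_that("zero drive gives a flat trajectory at rest", {
  tr <- simulate_membrane(drive_params(v0 = 0, d = 0.25), calibrated)
  expect_false(attr(tr, "crossed"))
  expect_true(all(tr$voltage_mV == -70))
})

test_that("perfect integrator matches the linear closed form at event times", {
  drive <- drive_params(v0 = 10, d = 0.5, f_amf = 100, epoch_duration = 1.5)
  tr <- simulate_membrane(drive, calibrated)
  dv <- delta_v_per_half_cycle(10, 0.5, calibrated) / 1000
  events <- tr$time_s > 0 & tr$time_s < 1.5
  k <- round(tr$time_s[events] * 2 * 100 + 0.5)
  expect_equal(tr$voltage_mV[events], -70 + k * dv, tolerance = 1e-12)
  # trajectory is non-decreasing during the epoch
  expect_true(all(diff(tr$voltage_mV) >= 0))
})

test_that("anchor drive crosses threshold at the end of the 2 s epoch", {
  tr <- simulate_membrane(drive_params(v0 = 24.5, d = 0.25), calibrated)
  expect_true(attr(tr, "crossed"))
  expect_equal(attr(tr, "crossing_time"), 2, tolerance = 1 / (2 * 150))
})

test_that("finite leak lowers the trajectory and dense output respects dt", {
  leaky <- cable_params(lambda_eff = calibrated$lambda_eff, tau_int = 0.05)
  drive <- drive_params(v0 = 24.5, d = 0.25, epoch_duration = 0.5)
  tr_leak <- simulate_membrane(drive, leaky)
  tr_lossless <- simulate_membrane(drive, calibrated)
  expect_lt(max(tr_leak$voltage_mV), max(tr_lossless$voltage_mV))
  expect_error(simulate_membrane(drive, calibrated, dt = 1),
               class = "menmod_config_error")
  tr_dense <- simulate_membrane(drive, calibrated, dt = 1e-3)
  expect_gt(nrow(tr_dense), nrow(tr_lossless))
})

test_that("time to threshold is bounded for strong drives and decreases with frequency", {
  # a 1 mV particle crosses within the first few half-cycles
  dv <- delta_v_per_half_cycle(1000, 0.25, calibrated) / 1000
  bound <- ceiling(15 / dv) / (2 * 150)
  t_strong <- time_to_threshold(1000, 0.25, 150, calibrated)
  expect_lte(t_strong, bound + 1e-9)
  # with the coefficient's frequency scaling, higher f is never slower
  fm <- me_model(freq_exponent = 1)
  f_grid <- seq(50, 500, length.out = 10)
  tstar <- vapply(f_grid, function(f) {
    time_to_threshold(24.5, 0.25, f, calibrated, horizon = 60,
                      freq_model = fm, f_ref = 150)
  }, numeric(1))
  # non-increasing up to the half-period discreteness of event times
  expect_true(all(diff(tstar) <= 1 / (2 * f_grid[-1]) + 1e-12))
})

test_that("time to threshold matches the perfect-integrator closed form", {
  with_seed(22, {
    for (i in 1:20) {
      v0 <- runif(1, 20, 80)
      d <- runif(1, 0.1, 1)
      f <- sample(c(50, 100, 150, 300), 1)
      dv <- delta_v_per_half_cycle(v0, d, calibrated) / 1000
      closed <- 15 / (2 * f * dv)
      got <- time_to_threshold(v0, d, f, calibrated, horizon = 60)
      expect_lte(abs(got - closed), 1 / (2 * f) + 1e-12)
    }
  })
})

test_that("threshold v0 reproduces the 24.5 uV anchor and the closed form", {
  expect_lt(abs(threshold_v0(0.25, 150, 2, calibrated) - 24.5), 0.05)
  with_seed(23, {
    for (i in 1:20) {
      d <- runif(1, 0.1, 2)
      f <- sample(c(50, 100, 150, 250), 1)
      epoch <- runif(1, 0.5, 4)
      g <- spatial_summation_factor(d, calibrated$lambda_eff)
      n_events <- floor(2 * f * epoch + 0.5)
      closed <- 15000 / (n_events * calibrated$kappa * g)
      got <- threshold_v0(d, f, epoch, calibrated)
      expect_lt(abs(got - closed), 0.06)
    }
  })
  # doubling the epoch halves the threshold (up to event-count discreteness)
  expect_lt(abs(threshold_v0(0.25, 150, 4, calibrated) -
                threshold_v0(0.25, 150, 2, calibrated) / 2), 0.08)
})

test_that("threshold v0 has a positive floor over physical spacings", {
  # the lattice sum diverges as d -> 0, so the floor is asserted over
  # spacings no smaller than the particle diameter (0.25 cell radii at the
  # anchor geometry); below that, only the g-ratio bound is meaningful
  anchor <- 24.5
  g_anchor <- spatial_summation_factor(0.25, calibrated$lambda_eff)
  for (d in c(0.25, 0.5, 1, 5, 10)) {
    v <- threshold_v0(d, 150, 2, calibrated)
    expect_gt(v, 0.5 * anchor)
  }
  for (d in c(0.01, 0.05, 0.25, 1, 5, 10)) {
    v <- threshold_v0(d, 150, 2, calibrated)
    g_d <- spatial_summation_factor(d, calibrated$lambda_eff)
    expect_gte(v + 0.05, anchor * g_anchor / g_d)
  }
})

test_that("bracket failures are reported with their values", {
  expect_error(threshold_v0(0.25, 150, 2, calibrated, bracket = c(1e4, 1e5)),
               class = "menmod_bracket_error")
})

test_that("uncalibrated cables are refused by summation operations", {
  expect_error(delta_v_per_half_cycle(10, 0.25, cable_params()),
               class = "menmod_uncalibrated")
})

test_that("sweep grids are long format with one row per condition", {
  sw <- sweep_time_to_threshold(calibrated, v0 = c(20, 40), d = c(0.25, 1),
                                f = 150)
  expect_equal(nrow(sw), 4)
  expect_true(all(c("v0_uV", "d_a", "f_Hz", "time_to_threshold_s") %in% names(sw)))
})
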
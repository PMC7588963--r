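test_that("MDT of a mono-exponential decline matches the analytic crossing", {
  tau <- 150 # min
  c0 <- 30
  fake <- tibble::tibble(time_min = seq(0, 3000, by = 1),
                         c_ven = c0 * exp(-seq(0, 3000, by = 1) / tau))
  for (limit in c(5.4, 0.14, 0.018)) {
    expect_equal(maximum_detection_time(fake, limit, session_min = 0),
                 tau * log(c0 / limit) / 60, tolerance = 1e-9)
  }
  # identically below the limit -> 0
  expect_equal(maximum_detection_time(fake, 100, session_min = 0), 0)
  # still above the limit at the final sample -> horizon error
  expect_error(maximum_detection_time(fake, 1e-12, session_min = 0),
               class = "dfemdt_error_horizon")
})

test_that("an ensemble of one reproduces a direct simulation", {
  ens <- run_ensemble("Y", n = 1, seed = 4, post_horizon_h = 24)
  row <- ens$subjects[1, ]
  params <- scale_physiology(row$bmi, 1.70, 10)
  starts <- seq(0, 120 - 1e-9, by = row$cycle_min)
  prof <- tibble::tibble(start_min = starts,
                         end_min = starts + row$inhalation_s / 60,
                         c_mg_l = pure_gas_concentration(1e6))
  prof <- structure(prof, class = c("dfe_profile", class(prof)),
                    session_min = 120)
  traj <- simulate_pbpk(params, prof, t_end = 120 + 24 * 60,
                        out_times = ens$time_min, quantities = "venous")
  expect_equal(ens$c_ven[, 1], traj$c_ven, tolerance = 1e-12)
  expect_equal(ens$c_ven[1, 1], 0) # zero initial state
  expect_true(all(ens$c_ven >= 0))
})

test_that("ensembles are deterministic given the seed", {
  a <- run_ensemble("Y", n = 4, seed = 21, post_horizon_h = 20)
  b <- run_ensemble("Y", n = 4, seed = 21, post_horizon_h = 20)
  expect_identical(summarize_mdt(a, limits = 5.4), summarize_mdt(b, limits = 5.4))
  expect_identical(a$c_ven, b$c_ven)
})

test_that("MDT summaries are ordered and monotone in the detection limit", {
  ens <- cached_ensemble("Y", n = 40)
  tab <- summarize_mdt(ens, limits = c(0.018, 0.14, 1.0, 5.4))
  expect_true(all(tab$p5_h <= tab$median_h & tab$median_h <= tab$p95_h))
  expect_true(all(diff(tab$median_h) < 0)) # larger limit, shorter MDT
  # per subject too
  m <- mdt_matrix(ens, c(0.018, 0.14, 1.0, 5.4))
  expect_true(all(m[, 1] >= m[, 2] & m[, 2] >= m[, 3] & m[, 3] >= m[, 4]))
  # a custom limit lands strictly between its neighbours
  expect_true(tab$median_h[3] < tab$median_h[2] &&
                tab$median_h[3] > tab$median_h[4])
})

test_that("identical subjects collapse the percentile range to zero", {
  spec <- population_spec(bmi_sd = 1e-9)
  sc <- exposure_scenario(ppm = 1e6, session_h = 2,
                          inhalation_s = c(10, 10), cycle_min = c(3.5, 3.5))
  ens <- run_ensemble(sc, n = 5, spec = spec, seed = 8)
  tab <- summarize_mdt(ens, limits = 0.14)
  expect_equal(tab$p5_h, tab$median_h, tolerance = 1e-6)
  expect_equal(tab$p95_h, tab$median_h, tolerance = 1e-6)
})

test_that("MDT grows with BMI for a fixed central huffing pattern", {
  sc <- exposure_scenario("Y")
  prof <- inhaled_concentration_profile(central_pattern(sc), sc)
  mdts <- vapply(c(18.5, 24.2, 30), function(b) {
    traj <- simulate_pbpk(scale_physiology(b), prof, quantities = "venous")
    maximum_detection_time(traj, 0.14)
  }, numeric(1))
  expect_true(all(diff(mdts) > 0))
  # the underweight subject also clears faster in the terminal sense
  expect_lt(washout_time_constant(scale_physiology(18.5), "fat"),
            washout_time_constant(scale_physiology(24.2), "fat"))
})

test_that("percentile curves: ensemble of one gives identical percentiles, smoothing preserves constants", {
  ens <- run_ensemble("Y", n = 1, seed = 2, post_horizon_h = 12)
  pc <- percentile_curves(ens)
  wide <- tidyr::pivot_wider(pc, names_from = "percentile",
                             values_from = "c_ven")
  expect_equal(wide$p5, wide$p50)
  expect_equal(wide$p95, wide$p50)
  # constant trajectories pass through the smoother unchanged
  const <- ens
  const$c_ven[] <- 3.3
  pcc <- percentile_curves(const, smooth_window_min = 5)
  expect_true(all(abs(pcc$c_ven - 3.3) < 1e-12))
})
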
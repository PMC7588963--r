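test_that("derivatives vanish at zero state and at the analytic steady state", {
  sm <- standard_man()
  expect_equal(pbpk_derivatives(rep(0, 5), sm, 0), rep(0, 5))
  # first contact: all inhaled mass enters the lung pool
  d <- pbpk_derivatives(rep(0, 5), sm, 100)
  expect_equal(d, c(sm$q_alv * 100, 0, 0, 0, 0))
  # equilibrium: alveolar air matches inhaled air, every tissue at pc_i * C_art
  c_inh <- 50
  c_art <- c_inh * sm$pc_blood_air
  amounts <- c(
    sm$v_lung * sm$pc_lung * c_art,
    sm$v_vrg * sm$pc_vrg * c_art,
    sm$v_fat * sm$pc_fat * c_art,
    sm$v_muscle * sm$pc_muscle * c_art,
    sm$v_liver * sm$pc_liver * c_art
  )
  expect_equal(pbpk_derivatives(amounts, sm, c_inh), rep(0, 5),
               tolerance = 1e-10)
  expect_error(pbpk_derivatives(rep(0, 5), sm, -1),
               class = "dfemdt_error_exposure")
})

test_that("zero exposure gives an identically zero trajectory", {
  traj <- simulate_pbpk(standard_man(), constant_exposure(0, 60), t_end = 120)
  expect_true(all(traj$c_ven == 0))
  expect_true(all(traj$c_art == 0))
  expect_equal(mass_balance_error(traj), 0)
})

test_that("constant exposure approaches the analytic steady state", {
  sm <- standard_man()
  c_inh <- 10
  traj <- simulate_pbpk(sm, constant_exposure(c_inh, 3000), t_end = 3000,
                        out_times = 3000)
  expect_equal(traj$c_ven[1], c_inh * sm$pc_blood_air, tolerance = 1e-3)
})

test_that("kinetics are linear in the inhaled concentration", {
  sm <- standard_man()
  sc <- exposure_scenario("Y")
  pat <- central_pattern(sc)
  k <- 7.3
  out <- seq(0, 240, by = 2)
  t1 <- simulate_pbpk(sm, inhaled_concentration_profile(pat, c_mg_l = 100),
                      t_end = 240, out_times = out)
  tk <- simulate_pbpk(sm, inhaled_concentration_profile(pat, c_mg_l = 100 * k),
                      t_end = 240, out_times = out)
  expect_equal(tk$c_ven, k * t1$c_ven, tolerance = 1e-12)
  expect_equal(tk$c_fat, k * t1$c_fat, tolerance = 1e-12)
})

test_that("all concentrations are non-negative along realistic trajectories", {
  traj <- cached_central_y()
  expect_true(all(traj$time_min == sort(traj$time_min)))
  expect_true(all(traj$c_ven >= 0))
  expect_true(all(traj$c_fat >= 0))
  expect_true(all(traj$c_alv_air >= 0))
})

test_that("venous concentration is the flow-weighted mean of tissue outflows", {
  sm <- standard_man()
  traj <- cached_central_y()
  i <- which(traj$time_min == 240) # well after session end
  q <- c(sm$q_vrg, sm$q_fat, sm$q_muscle, sm$q_liver)
  outflow <- c(traj$c_vrg[i] / sm$pc_vrg, traj$c_fat[i] / sm$pc_fat,
               traj$c_muscle[i] / sm$pc_muscle, traj$c_liver[i] / sm$pc_liver)
  expect_equal(traj$c_ven[i], sum(q * outflow) / sum(q), tolerance = 1e-10)
})

test_that("RK4 agrees with the closed-form propagator within 0.1%", {
  sm <- standard_man()
  sc <- exposure_scenario("Y")
  prof <- inhaled_concentration_profile(central_pattern(sc), sc)
  out <- c(seq(5, 120, by = 5), seq(150, 360, by = 30))
  cf <- simulate_pbpk(sm, prof, t_end = 360, out_times = out)
  rk <- simulate_pbpk(sm, prof, t_end = 360, out_times = out, solver = "rk4")
  rel <- abs(rk$c_ven - cf$c_ven) / cf$c_ven
  expect_lt(max(rel), 1e-3)
})

test_that("mass is conserved: exact in closed form, <1e-3 for RK4, order-4 convergence", {
  sm <- standard_man()
  sc <- exposure_scenario("Y")
  prof <- inhaled_concentration_profile(central_pattern(sc), sc)
  cf <- cached_central_y()
  expect_lt(mass_balance_error(cf), 1e-6)

  short <- inhaled_concentration_profile(huff_pattern(10, 3.5, 0.25), sc)
  rk_h <- simulate_pbpk(sm, short, t_end = 30, out_times = 30, solver = "rk4",
                        rk4_session_step_s = 6, rk4_post_step_s = 30)
  rk_h2 <- simulate_pbpk(sm, short, t_end = 30, out_times = 30, solver = "rk4",
                         rk4_session_step_s = 3, rk4_post_step_s = 15)
  expect_lt(mass_balance_error(rk_h), 1e-3)
  ref <- simulate_pbpk(sm, short, t_end = 30, out_times = 30)
  err_h <- abs(rk_h$c_ven - ref$c_ven)
  err_h2 <- abs(rk_h2$c_ven - ref$c_ven)
  expect_gt(err_h / err_h2, 8)   # fourth-order: ratio ~ 2^4
  expect_lt(err_h / err_h2, 32)
})

test_that("post-exposure decline ends in a fat-governed terminal phase", {
  sm <- standard_man()
  traj <- cached_central_y()
  post <- dplyr::filter(tidy(traj), time_min > 120 + 12 * 60,
                        time_min < 120 + 20 * 60)
  slope <- unname(coef(lm(log(c_ven) ~ time_min, post))[2])
  tau <- -1 / slope
  expect_lt(abs(tau - washout_time_constant(sm, "fat")) /
              washout_time_constant(sm, "fat"), 0.15)
  # three phases: venous drops fast in the first minutes, then slower
  c_end <- traj$c_ven[traj$time_min == 120]
  c_5 <- traj$c_ven[traj$time_min == 125]
  c_60 <- traj$c_ven[traj$time_min == 180]
  expect_lt(c_5 / c_end, 0.5)        # fast phase: >2-fold in 5 min
  expect_gt(c_60 / c_5, exp(-55 / washout_time_constant(sm, "vrg")))
})

test_that("session concentrations fluctuate several-fold around the average", {
  traj <- cached_central_y()
  sess <- dplyr::filter(tidy(traj), time_min > 10, time_min <= 120)
  expect_gt(max(sess$c_ven) / min(sess$c_ven), 3)
  avg <- session_average(traj)
  expect_gt(avg, 40)
  expect_lt(avg, 200)
})

test_that("simulation input validation", {
  sm <- standard_man()
  expect_error(simulate_pbpk(sm, constant_exposure(10, 10), t_end = -5),
               class = "dfemdt_error_solver")
})
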
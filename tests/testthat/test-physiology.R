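test_that("body weight follows BMI times height squared", {
  expect_equal(body_weight_from_bmi(24.2, 1.70), 69.938, tolerance = 1e-12)
  expect_equal(round(body_weight_from_bmi(24.2, 1.70)), 70) # the standard man
  expect_equal(body_weight_from_bmi(16.5, 1.70), 47.685, tolerance = 1e-12)
  x <- c(18.5, 25, 33.3)
  expect_equal(body_weight_from_bmi(x, 1.0), x) # unit-height identity
  expect_error(body_weight_from_bmi(-1, 1.7), class = "dfemdt_error_anthropometry")
  expect_error(body_weight_from_bmi(24, 0), class = "dfemdt_error_anthropometry")
})

test_that("standard man reproduces the reference parameter table", {
  sm <- standard_man()
  expect_equal(sm$v_lung, table1$v[["lung"]])
  expect_equal(sm$v_vrg, table1$v[["vrg"]])
  expect_equal(sm$v_fat, table1$v[["fat"]])
  expect_equal(sm$v_muscle, table1$v[["muscle"]])
  expect_equal(sm$v_liver, table1$v[["liver"]])
  expect_equal(sm$q_alv, table1$q[["alv"]])
  expect_equal(sm$q_co, table1$q[["co"]])
  expect_equal(sm$q_vrg, table1$q[["vrg"]])
  expect_equal(sm$q_fat, table1$q[["fat"]])
  expect_equal(sm$q_muscle, table1$q[["muscle"]])
  expect_equal(sm$q_liver, table1$q[["liver"]])
  expect_equal(sm$pc_blood_air, table1$pc[["blood_air"]])
  expect_equal(sm$pc_lung, table1$pc[["lung"]])
  expect_equal(sm$pc_vrg, table1$pc[["vrg"]])
  expect_equal(sm$pc_fat, table1$pc[["fat"]])
  expect_equal(sm$pc_muscle, table1$pc[["muscle"]])
  expect_equal(sm$pc_liver, table1$pc[["liver"]])
  # tissue flows sum to cardiac output within 0.5%
  q_sum <- sm$q_vrg + sm$q_fat + sm$q_muscle + sm$q_liver
  expect_equal(q_sum, 6.33)
  expect_lt(abs(q_sum - sm$q_co) / sm$q_co, 0.005)
})

test_that("scaled physiology is anchored exactly at the standard man", {
  sc <- scale_physiology(24.2, 1.70, 10)
  sm <- standard_man()
  for (f in c("v_lung", "v_vrg", "v_fat", "v_muscle", "v_liver",
              "q_alv", "q_co", "q_vrg", "q_fat", "q_muscle", "q_liver",
              "pc_blood_air", "pc_lung", "pc_vrg", "pc_fat", "pc_muscle",
              "pc_liver")) {
    expect_equal(sc[[f]], sm[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("fat volume and fat time constant grow with BMI; flows stay conserved", {
  bmis <- seq(16.5, 40, length.out = 25)
  phys <- lapply(bmis, scale_physiology)
  v_fat <- vapply(phys, `[[`, 0, "v_fat")
  tau_fat <- vapply(phys, washout_time_constant, 0, compartment = "fat")
  expect_true(all(diff(v_fat) > 0))
  expect_true(all(diff(tau_fat) > 0))
  expect_lt(scale_physiology(18.5)$v_fat, 15.43)
  expect_gt(scale_physiology(30)$v_fat, 15.43)
  for (p in phys) {
    q_sum <- p$q_vrg + p$q_fat + p$q_muscle + p$q_liver
    expect_lt(abs(q_sum - p$q_co) / p$q_co, 0.005)
  }
})

test_that("washout time constants match the printed kinetics", {
  sm <- standard_man()
  expect_equal(round(washout_time_constant(sm, "fat") / 60, 1), 3.0)
  expect_equal(round(washout_time_constant(sm, "vrg"), 1), 0.8)
  expect_equal(round(washout_time_constant(sm, "liver"), 1), 0.8)
  expect_equal(washout_time_constant(sm, "vrg"), 2.09 * 1.24 / 3.20)
  # the muscle constant is reported as computed (V*P/Q), ~20.3 min
  expect_equal(washout_time_constant(sm, "muscle"), 17.45 * 1.34 / 1.15)
  expect_error(washout_time_constant(sm, "spleen"),
               class = "dfemdt_error_compartment")
})

test_that("out-of-range BMI and workload are rejected", {
  expect_error(scale_physiology(8, 1.7, 10), class = "dfemdt_error_bmi_range")
  expect_error(scale_physiology(65, 1.7, 10), class = "dfemdt_error_bmi_range")
  expect_error(scale_physiology(24.2, 1.7, -5),
               class = "dfemdt_error_anthropometry")
})

test_that("workload raises ventilation and cardiac output linearly", {
  p10 <- scale_physiology(24.2, 1.70, 10)
  p60 <- scale_physiology(24.2, 1.70, 60)
  expect_equal(p60$q_alv - p10$q_alv, 5)
  expect_equal(p60$q_co - p10$q_co, 5)
  expect_equal(p60$q_muscle - p10$q_muscle, 5) # the increment goes to muscle
  expect_equal(p60$q_fat, p10$q_fat)
})
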
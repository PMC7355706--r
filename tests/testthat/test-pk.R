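test_that("pooling the shipped twelve-study table reproduces the published means", {
  studies <- loratadine_pk_studies()
  expect_equal(nrow(studies), 12L)
  pooled <- pool_pk_parameters(studies)
  expect_equal(round(pooled$ka, 3), 0.846)
  expect_equal(round(pooled$k10, 3), 0.271)
  expect_equal(round(pooled$k12, 3), 0.546)
  expect_equal(round(pooled$k21, 3), 0.054)
  expect_equal(round(pooled$v_over_f), 1198)
  # derived clearance
  expect_equal(pooled$cl, pooled$k10 * pooled$v_over_f)
})

test_that("pooling is the arithmetic per-field mean", {
  one <- data.frame(study_id = "a", ka_per_h = 0.4, k10_per_h = 0.1,
                    k12_per_h = 0.2, k21_per_h = 0.05, v_over_f_L = 100)
  single <- pool_pk_parameters(one)
  expect_equal(single$ka, 0.4)
  expect_equal(single$v_over_f, 100)
  two <- rbind(one, transform(one, ka_per_h = 0.6))
  expect_equal(pool_pk_parameters(two)$ka, 0.5)
  expect_error(pool_pk_parameters(one[0, ]), "at least one row")
  expect_error(pool_pk_parameters(one[, -2]), "missing")
})

test_that("rate conversion between 1/h and 1/min round-trips exactly", {
  k <- c(0.846, 0.271, 1e-5, 12)
  expect_identical(rate_convert(rate_convert(k, "per_h", "per_min"),
                                "per_min", "per_h"), k)
  expect_equal(rate_convert(0.846, "per_h", "per_min"), 0.846 / 60)
})

test_that("zero luminal input yields zero plasma", {
  pk <- pk_parameters(0.846, 0.271, 0.546, 0.054, 1198)
  lum <- data.frame(time_min = 0:120, amount_ug = 0)
  prof <- simulate_plasma(lum, pk, horizon = 120)
  expect_true(all(prof$conc_ug_per_ml == 0))
  expect_true(all(prof$peripheral_ug == 0))
})

test_that("with k12 = k21 = 0 the system reduces to the Bateman function", {
  ka <- 0.846
  k10 <- 0.271
  pk <- pk_parameters(ka, k10, 0, 0, 1198)
  ka_m <- ka / 60
  k10_m <- k10 / 60
  a0 <- 5000
  tt <- seq(0, 360, by = 0.05)
  lum <- data.frame(time_min = tt, amount_ug = a0 * exp(-ka_m * tt))
  prof <- simulate_plasma(lum, pk, horizon = 360)
  bateman <- a0 * ka_m / (ka_m - k10_m) *
    (exp(-k10_m * prof$time_min) - exp(-ka_m * prof$time_min))
  expect_lt(max(abs(prof$central_ug - bateman)) / max(bateman), 1e-6)
})

test_that("constant forcing approaches the one-compartment steady state", {
  pk <- pk_parameters(0.846, 0.271, 0, 0, 1198)
  a <- 2000
  lum <- data.frame(time_min = c(0, 4000), amount_ug = a)
  prof <- simulate_plasma(lum, pk, horizon = 4000, by = 10)
  expect_equal(prof$central_ug[nrow(prof)],
               (0.846 / 60) * a / (0.271 / 60), tolerance = 1e-5)
})

test_that("plasma response is linear in the luminal input", {
  pre <- condition_preset(1)
  traj <- simulate_gis(drug_preset(), pre$condition, pre$params)
  pk <- pool_pk_parameters(loratadine_pk_studies())
  lum <- luminal_dissolved(traj, horizon = 360,
                           absorption_rate_per_min = pk$ka / 60)
  p1 <- simulate_plasma(lum, pk, horizon = 360)
  lum2 <- dplyr::mutate(lum, amount_ug = 2 * amount_ug)
  p2 <- simulate_plasma(lum2, pk, horizon = 360)
  expect_lt(max(abs(p2$conc_ug_per_ml - 2 * p1$conc_ug_per_ml)) /
              max(p1$conc_ug_per_ml), 1e-6)
  # superposition of two different inputs
  lum3 <- dplyr::mutate(lum, amount_ug = 500 + 0.3 * amount_ug)
  p3 <- simulate_plasma(lum3, pk, horizon = 360)
  base <- simulate_plasma(dplyr::mutate(lum, amount_ug = 500), pk, 360)
  expect_lt(max(abs(p3$central_ug - (base$central_ug +
                                       0.3 * p1$central_ug))) /
              max(p3$central_ug), 1e-6)
})

test_that("PK mass accounting closes: absorbed = central + peripheral + eliminated", {
  pre <- condition_preset(3)
  traj <- simulate_gis(drug_preset(), pre$condition, pre$params)
  pk <- pool_pk_parameters(loratadine_pk_studies())
  lum <- luminal_dissolved(traj, horizon = 360,
                           absorption_rate_per_min = pk$ka / 60)
  prof <- simulate_plasma(lum, pk, horizon = 360)
  lhs <- prof$cum_absorbed_ug
  rhs <- prof$central_ug + prof$peripheral_ug + prof$cum_eliminated_ug
  expect_lt(max(abs(lhs - rhs)) / max(lhs), 1e-6)
})

test_that("simulate_plasma validates its inputs", {
  pk <- pk_parameters(0.8, 0.2, 0.5, 0.05, 1000)
  expect_error(simulate_plasma(data.frame(time_min = 0:10, x = 1), pk, 10),
               "amount_ug")
  expect_error(
    simulate_plasma(data.frame(time_min = 0:10, amount_ug = 1), pk,
                    horizon = 60),
    "exceeds the luminal series")
  expect_error(pk_parameters(-0.1, 0.2, 0.5, 0.05, 1000), "non-negative")
  expect_error(pk_parameters(0.8, 0.2, 0.5, 0.05, 0), "positive")
})

test_that("exposure metrics implement Cmax/Tmax and the trapezoid AUC", {
  flat <- data.frame(time_min = 0:10, conc_ug_per_ml = 2)
  m <- exposure_metrics(flat, 0, 10)
  expect_equal(m$auc_ug_min_per_ml, 2 * 10)
  expect_equal(m$cmax_ug_per_ml, 2)

  tri <- data.frame(time_min = 0:10,
                    conc_ug_per_ml = c(0:5, 4:0))
  m2 <- exposure_metrics(tri, 0, 10)
  expect_equal(m2$auc_ug_min_per_ml, 5 * 10 / 2)
  expect_equal(m2$cmax_ug_per_ml, 5)
  expect_equal(m2$tmax_min, 5)

  # window ends interpolated onto the grid
  m3 <- exposure_metrics(flat, 0.5, 9.5)
  expect_equal(m3$auc_ug_min_per_ml, 2 * 9)

  # additivity over adjacent windows
  pre <- condition_preset(1)
  traj <- simulate_gis(drug_preset(), pre$condition, pre$params)
  pk <- pool_pk_parameters(loratadine_pk_studies())
  lum <- luminal_dissolved(traj, horizon = 360,
                           absorption_rate_per_min = pk$ka / 60)
  prof <- simulate_plasma(lum, pk, horizon = 360)
  a_full <- exposure_metrics(prof, 5, 360)$auc_ug_min_per_ml
  a_split <- exposure_metrics(prof, 5, 97)$auc_ug_min_per_ml +
    exposure_metrics(prof, 97, 360)$auc_ug_min_per_ml
  expect_equal(a_split, a_full, tolerance = 1e-12)

  expect_error(exposure_metrics(flat, 5, 5), "smaller")
  expect_error(exposure_metrics(flat, -1, 5), "within")
})

test_that("equivalence comparison and fold changes match hand arithmetic", {
  a <- data.frame(cmax_ug_per_ml = 0.0017, auc_ug_min_per_ml = 0.35)
  b <- data.frame(cmax_ug_per_ml = 0.0019, auc_ug_min_per_ml = 0.30)
  be <- bioequivalence_compare(a, b)
  expect_equal(be$pct_diff[be$metric == "auc"], 100 * 0.05 / 0.30)
  expect_true(attr(be, "equivalent"))

  same <- bioequivalence_compare(a, a)
  expect_equal(same$pct_diff, c(0, 0))
  expect_true(all(same$pass))

  far <- bioequivalence_compare(
    data.frame(cmax_ug_per_ml = 0.002, auc_ug_min_per_ml = 0.40), b)
  expect_equal(far$pct_diff[far$metric == "auc"], 100 / 3, tolerance = 1e-10)
  expect_false(attr(far, "equivalent"))
  expect_error(
    bioequivalence_compare(a, transform(b, auc_ug_min_per_ml = 0)),
    "positive")

  fc <- scenario_fold_change(a, b)
  expect_equal(fc$fold_change[fc$metric == "auc"], 0.35 / 0.30)
  expect_equal(scenario_fold_change(a, a)$fold_change, c(1, 1))
  # doubling the input doubles both metrics under linear PK
  pk <- pk_parameters(0.846, 0.271, 0.546, 0.054, 1198)
  lum <- data.frame(time_min = 0:360,
                    amount_ug = 1000 * exp(-0.01 * (0:360)))
  m1 <- exposure_metrics(simulate_plasma(lum, pk, 360), 5, 360)
  m2 <- exposure_metrics(
    simulate_plasma(dplyr::mutate(lum, amount_ug = 2 * amount_ug), pk, 360),
    5, 360)
  expect_equal(scenario_fold_change(m2, m1)$fold_change, c(2, 2),
               tolerance = 1e-6)
})
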
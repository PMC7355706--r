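test_that("gastric emptying rate is ln(2)/t_half", {
  expect_equal(gastric_emptying_rate(15), log(2) / 15)
  expect_equal(gastric_emptying_rate(30), log(2) / 30)
  expect_error(gastric_emptying_rate(0), "positive")
  # half-life definition: fraction of fluid remaining at t_half is 1/2
  cond <- condition_config("hl", gastric_residual_floor = 0, k_sec_s = 0,
                           k_sec_d = 0, t_half_gastric = 15)
  traj <- simulate_gis(drug_preset(), cond, zero_kinetics_params(),
                       times = c(0, 15))
  v <- wide_volumes(traj)
  expect_equal(v$stomach[2] / v$stomach[1], 0.5, tolerance = 1e-7)
})

test_that("dissolution and precipitation fluxes follow their driving forces", {
  expect_equal(dissolution_flux(1e-3, 1e4, 50, 0), 500)
  expect_equal(dissolution_flux(1e-3, 1e4, 50, 50), 0)   # saturated
  expect_equal(dissolution_flux(1e-3, 0, 50, 0), 0)      # no solid left
  expect_error(dissolution_flux(-1, 1, 1, 1), "non-negative")

  expect_equal(precipitation_flux(0.1, 2200, 40, 50), 0.1 * 200)
  expect_equal(precipitation_flux(0.1, 1000, 40, 50), 0)  # sub-saturated
  expect_equal(precipitation_flux(0, 9000, 40, 50), 0)
  expect_error(precipitation_flux(0.1, 1, 1, 0), "positive")
})

test_that("with all kinetics zero the dose stays as gastric solid", {
  pre <- condition_preset(1)
  traj <- simulate_gis(drug_preset(), pre$condition, zero_kinetics_params(),
                       times = seq(0, 60, 5))
  df <- tibble::as_tibble(traj)
  expect_true(all(df$dissolved_ug == 0))
  expect_true(all(df$precipitated_ug == 0))
  tm <- total_drug_mass(traj)
  expect_equal(tm$total_ug, rep(10000, nrow(tm)), tolerance = 1e-8)
  # frac = 0: no particle ever leaves the stomach
  expect_true(all(df$solid_ug[df$compartment != "stomach"] == 0))
})

test_that("gastric volume matches the linear-ODE closed forms", {
  # no secretion, no floor: pure exponential decay
  cond0 <- no_floor_condition(t_half = 15, k_sec_s = 0)
  traj0 <- simulate_gis(drug_preset(), cond0, zero_kinetics_params(),
                        times = seq(0, 60, 2.5))
  v0 <- wide_volumes(traj0)
  expect_equal(v0$stomach, 300 * 2^(-v0$time_min / 15), tolerance = 1e-6)

  # with secretion: V(t) = (V0 - k/kge) e^(-kge t) + k/kge -> k/kge
  cond1 <- no_floor_condition(t_half = 15, k_sec_s = 1)
  cond1$duration <- 400
  traj1 <- simulate_gis(drug_preset(), cond1, zero_kinetics_params(),
                        times = seq(0, 400, 10))
  v1 <- wide_volumes(traj1)
  kge <- log(2) / 15
  analytic <- (300 - 1 / kge) * exp(-kge * v1$time_min) + 1 / kge
  expect_equal(v1$stomach, analytic, tolerance = 1e-6)
  expect_equal(v1$stomach[nrow(v1)], 21.6404, tolerance = 1e-4)
})

test_that("the residual floor pins the gastric volume once reached", {
  cond <- condition_config("floor", gastric_residual_floor = 5, k_sec_s = 0,
                           k_sec_d = 0, t_half_gastric = 5, duration = 120)
  traj <- simulate_gis(drug_preset(), cond, zero_kinetics_params(),
                       times = seq(0, 120, 5))
  v <- wide_volumes(traj)
  expect_equal(v$stomach[nrow(v)], 5, tolerance = 1e-4)
  expect_true(all(v$stomach >= 5 - 1e-6))
})

test_that("mass and volume are conserved across all shipped presets", {
  for (n in 1:4) {
    pre <- condition_preset(n)
    traj <- simulate_gis(drug_preset(), pre$condition, pre$params)
    tm <- total_drug_mass(traj)
    expect_lt(max(abs(tm$total_ug - 10000)) / 10000, 1e-6)
    v <- wide_volumes(traj)
    total <- v$stomach + v$duodenum + v$jejunum
    expected <- 350 + (pre$condition$k_sec_s + pre$condition$k_sec_d) *
      v$time_min
    expect_lt(max(abs(total - expected) / expected), 1e-6)
    # duodenal chamber held at its constant working volume
    expect_true(all(v$duodenum == 50))
  }
})

test_that("slower emptying weakly lowers the peak duodenal inflow rate", {
  peak_inflow <- function(t_half) {
    cond <- no_floor_condition(t_half = t_half)
    traj <- simulate_gis(drug_preset(), cond, zero_kinetics_params(),
                         times = seq(0, 60, 1))
    v <- wide_volumes(traj)
    max(gastric_emptying_rate(t_half) * v$stomach)
  }
  expect_lte(peak_inflow(30), peak_inflow(15))
})

test_that("faster duodenal precipitation weakly lowers duodenal dissolved AUC", {
  pre <- condition_preset(1)
  auc_d <- function(k_pre_d) {
    p <- pre$params
    params <- transit_parameters(p$z_s, p$z_d, p$z_j, p$frac,
                                 k_pre_d, p$k_pre_j, p$z_unit_scale)
    traj <- simulate_gis(drug_preset(), pre$condition, params,
                         times = seq(0, 60, 1))
    d <- dplyr::filter(tibble::as_tibble(traj), compartment == "duodenum")
    pracma::trapz(d$time_min, d$dissolved_ug)
  }
  aucs <- vapply(c(0.01, 0.1, 0.5), auc_d, numeric(1))
  expect_true(all(diff(aucs) <= 1e-9))
})

test_that("without precipitation the intestinal dissolved mass never falls", {
  pre <- condition_preset(1)
  p <- pre$params
  params <- transit_parameters(p$z_s, p$z_d, p$z_j, p$frac,
                               k_pre_d = 0, k_pre_j = 0,
                               z_unit_scale = p$z_unit_scale)
  traj <- simulate_gis(drug_preset(), pre$condition, params,
                       times = seq(0, 60, 1))
  dj <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tibble::as_tibble(traj),
                                  compartment != "stomach"), time_min),
    dissolved = sum(dissolved_ug), .groups = "drop")
  expect_true(all(diff(dj$dissolved) >= -1e-9))
})

test_that("concentration series follow the declared conventions", {
  pre <- condition_preset(1)
  traj <- simulate_gis(drug_preset(), pre$condition, pre$params,
                       times = seq(0, 60, 5))
  # initially empty jejunum reports zero concentration by convention
  jej <- concentration_series(traj, "jejunum")
  expect_equal(jej$conc_ug_per_ml[jej$time_min == 0], 0)
  expect_error(concentration_series(traj, "ileum"), "compartment")

  # instantaneous dissolution of the dose in 300 mL gives dose/volume;
  # without secretion, dissolved amount and volume decay together so the
  # gastric concentration stays at 10000/300
  fast <- transit_parameters(1e-6, 0, 0, frac = 0, k_pre_d = 0, k_pre_j = 0,
                             z_unit_scale = 1e6)
  cond <- condition_config("instant", gastric_residual_floor = 0,
                           k_sec_s = 0, k_sec_d = 0, t_half_gastric = 15)
  tr2 <- simulate_gis(drug_preset(), cond, fast, times = seq(1, 30, 1))
  g <- concentration_series(tr2, "stomach")
  expect_equal(g$conc_ug_per_ml[g$time_min >= 5],
               rep(10000 / 300, sum(g$time_min >= 5)), tolerance = 1e-3)
})

test_that("a conservative dissolved tracer is never concentrated downstream", {
  # huge solubility everywhere, instant dissolution, no precipitation:
  # duodenal concentration can only be diluted relative to gastric inflow
  tracer <- drug_properties(
    "tracer", dose_ug = 10000, pka = 5.3, s0_ug_per_ml = 1,
    solubility_overrides = data.frame(ph = c(0, 14), s_ug_per_ml = 1e9))
  fast <- transit_parameters(1e-3, 1e-3, 1e-3, frac = 1, k_pre_d = 0,
                             k_pre_j = 0, z_unit_scale = 1e6)
  pre <- condition_preset(1)
  traj <- simulate_gis(tracer, pre$condition, fast, times = seq(0, 60, 1))
  g <- concentration_series(traj, "stomach")
  d <- concentration_series(traj, "duodenum")
  expect_lte(max(d$conc_ug_per_ml), max(g$conc_ug_per_ml) * (1 + 1e-8))
})

test_that("DS series flag supersaturation after gastric-to-intestinal transfer", {
  pre <- condition_preset(1)
  p <- pre$params
  no_pre <- transit_parameters(p$z_s, p$z_d, p$z_j, p$frac, 0, 0,
                               p$z_unit_scale)
  traj <- simulate_gis(drug_preset(), pre$condition, no_pre,
                       times = seq(0, 60, 1))
  ds_d <- ds_series(traj, "duodenum")
  conc_d <- concentration_series(traj, "duodenum")
  sol_d <- solubility_at_ph(drug_preset(),
                            ph_at(pre$condition$duodenal_ph_profile,
                                  ds_d$time_min))
  # pointwise identity with the physchem primitive
  expect_equal(ds_d$ds, conc_d$conc_ug_per_ml / sol_d, tolerance = 1e-10)
  # acidic gastric solution entering a neutral chamber supersaturates it
  expect_gt(max(ds_d$ds), 1)
  expect_error(ds_series(traj, "colon"), "compartment")
})

test_that("trajectory export is tidy and the luminal series is consistent", {
  pre <- condition_preset(1)
  traj <- simulate_gis(drug_preset(), pre$condition, pre$params,
                       times = seq(0, 60, 5))
  lum <- luminal_dissolved(traj, by = 5)
  df <- tibble::as_tibble(traj)
  dj <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(df, compartment != "stomach"), time_min),
    amt = sum(dissolved_ug), .groups = "drop")
  expect_equal(lum$amount_ug, dj$amt, tolerance = 1e-10)
  # extension decays and never goes negative
  ext <- luminal_dissolved(traj, horizon = 360,
                           absorption_rate_per_min = 0.014)
  expect_true(all(ext$amount_ug >= 0))
  expect_lt(ext$amount_ug[ext$time_min == 360],
            max(ext$amount_ug))
  ledg <- transfer_ledgers(traj)
  expect_true(all(diff(ledg$emptied_dissolved_ug) >= 0))
  expect_true(all(diff(ledg$dj_solid_ug) >= 0))
})
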
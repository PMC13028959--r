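test_that("zero-dose scenario stays at baseline", {
  sc <- scenario(doses = list(), t_end_h = 24, output_dt_h = 1)
  tc <- simulate_scenario(sc)
  expect_equal(max(abs(tc$dap_plasma_ngml)), 0)
  expect_equal(max(abs(tc$uge_g)), 0)
  expect_equal(tc$rtg_mM, rep(sc$pd$RTG0, nrow(tc)))
  expect_equal(mass_balance(tc), 0)
})

test_that("simulation is deterministic and tolerance-robust", {
  sc <- ref_scenario(t_end_h = 48)
  tc1 <- simulate_scenario(sc)
  tc2 <- simulate_scenario(sc)
  expect_identical(tc1$dap_plasma_ngml, tc2$dap_plasma_ngml)
  # halving the tolerances moves Cmax and AUC by < 0.1%
  tc3 <- simulate_scenario(sc, rtol = 5e-9, atol = 5e-11)
  pk1 <- pk_params(tc1, "dap"); pk3 <- pk_params(tc3, "dap")
  expect_equal(pk1$cmax, pk3$cmax, tolerance = 1e-3)
  expect_equal(pk1$auc_0_t, pk3$auc_0_t, tolerance = 1e-3)
})

test_that("dose events are atomic regardless of grid resolution", {
  mk <- function(dt) {
    sc <- scenario(doses = list(dose_event(0, 10), dose_event(13.37, 10)),
                   t_end_h = 72, output_dt_h = dt)
    simulate_scenario(sc)
  }
  coarse <- mk(2); fine <- mk(0.25)
  expect_equal(max(attr(coarse, "admin_umol")),
               2 * 10 / drug_parameters()$MW_DAP * 1000)
  expect_lt(mass_balance(coarse), 1e-6)
  expect_lt(mass_balance(fine), 1e-6)
  # terminal cumulative amounts agree across grids
  expect_equal(coarse$dap_urine_mg[nrow(coarse)],
               fine$dap_urine_mg[nrow(fine)], tolerance = 1e-6)
})

test_that("multi-dose profile superposes shifted single-dose profiles", {
  single <- simulate_scenario(ref_scenario(t_end_h = 72, output_dt_h = 0.25))
  double <- simulate_scenario(
    scenario(doses = list(dose_event(0, 10), dose_event(24, 10)),
             t_end_h = 72, output_dt_h = 0.25))
  t2 <- double$time_h[double$time_h >= 24 & double$time_h <= 48]
  obs <- double$dap_plasma_ngml[match(t2, double$time_h)]
  pred <- single$dap_plasma_ngml[match(t2, single$time_h)] +
    single$dap_plasma_ngml[match(t2 - 24, single$time_h)]
  expect_equal(obs, pred, tolerance = 0.02)
})

test_that("parameter scans hold everything else fixed and order as expected", {
  base <- ref_scenario(t_end_h = 72, output_dt_h = 0.25)
  # absorption activity: Cmax strictly increasing, AUC nearly flat
  res <- parameter_scan(base, "physiology.f_absorption", c(0.3, 1, 3))
  expect_true(all(diff(res$summary$cmax_dap) > 0))
  expect_lt(diff(range(res$summary$auc_dap)) / min(res$summary$auc_dap), 0.05)
  expect_error(parameter_scan(base, "drug.not_a_param", 1:2), "unknown")
})

test_that("study runner matches plain simulation and orders study arms", {
  cfg <- list(arms = list(
    list(label = "fasted", dose_mg = 10, prandial = "fasted", t_end_h = 48),
    list(label = "fed", dose_mg = 10, prandial = "fed", t_end_h = 48)))
  res <- run_study(cfg)
  expect_named(res, c("fasted", "fed"))
  pk_fast <- pk_params(res$fasted, "dap")
  pk_fed <- pk_params(res$fed, "dap")
  expect_lt(pk_fed$cmax, pk_fast$cmax)
  expect_gt(pk_fed$tmax, pk_fast$tmax)
  # a single-arm config is exactly a plain scenario
  solo <- run_study(list(arms = list(list(label = "a", dose_mg = 10,
                                          t_end_h = 48))))$a
  direct <- simulate_scenario(ref_scenario(t_end_h = 48))
  expect_equal(solo$dap_plasma_ngml, direct$dap_plasma_ngml)
  # malformed arm names the offender
  expect_error(run_study(list(arms = list(list(label = "bad_arm")))),
               "bad_arm")
})

test_that("scenario validation rejects inconsistent inputs", {
  expect_error(dose_event(-1, 10), "non-negative")
  expect_error(dose_event(0, -5), "non-negative")
  expect_error(scenario(doses = list(dose_event(48, 10)), t_end_h = 24),
               "last dose")
})
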
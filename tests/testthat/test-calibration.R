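test_that("cost function implements the weighted residual formula", {
  # one point, n = 10, sigma = 2, residual 1: F = 1/2 * (10/2) * 1 = 2.5
  expect_equal(cost_function(c(ka = drug_parameters()$ka),
                             one_point_dataset(), rtol = 1e-8), 2.5, tolerance = 1e-6)
  # doubling n doubles the contribution
  expect_equal(cost_function(c(ka = drug_parameters()$ka),
                             one_point_dataset(n = 20), rtol = 1e-8), 5, tolerance = 1e-6)
})

test_that("cost is permutation-invariant and decreases toward the data", {
  ds <- generate_study(recovery_spec(cv = 0.2, seed = 3))
  par0 <- unlist(recovery_truth)
  f0 <- cost_function(par0, ds)
  perm <- sample(nrow(ds))
  ds_perm <- study_dataset(as.data.frame(ds)[perm, ],
                           attr(ds, "scenarios"))
  expect_equal(cost_function(par0, ds_perm), f0, tolerance = 1e-9)
  # moving one parameter off the truth increases the cost
  par_off <- par0; par_off["ka"] <- par0["ka"] * 1.5
  expect_gt(cost_function(par_off, ds), f0)
})

test_that("missing SDs fall back to the series median sigma", {
  sc <- ref_scenario(t_end_h = 24, output_dt_h = 0.5)
  tc <- simulate_scenario(sc)
  tt <- c(2, 4, 8)
  pred <- tc$dap_plasma_ngml[match(tt, tc$time_h)]
  df <- data.frame(scenario_id = "s1", observable = "dap_plasma_ngml",
                   time_h = tt, mean = pred - 1, sd = c(2, NA, 4), n = 1)
  ds <- study_dataset(df, list(s1 = sc))
  # sigma for the NA point is median(2, 4) = 3
  expect_equal(cost_function(c(ka = sc$drug$ka), ds, rtol = 1e-8),
               0.5 * (1 / 2 + 1 / 3 + 1 / 4), tolerance = 1e-6)
})

test_that("goodness of fit matches hand-computed values", {
  # zero-dose scenario: predictions are identically zero
  sc <- scenario(doses = list(), t_end_h = 24, output_dt_h = 1,
                 label = "blank")
  obs <- c(1, 2, 3)
  ds <- study_dataset(
    data.frame(scenario_id = "b", observable = "dap_plasma_ngml",
               time_h = c(4, 8, 12), mean = obs, sd = 1, n = 1),
    scenarios = list(b = sc))
  gof <- goodness_of_fit(c(ka = 1), ds)
  # SS_res = 1 + 4 + 9 = 14, SS_tot = 2: R2 = 1 - 7 = -6
  expect_equal(gof$r2[gof$scenario_id == "b"], -6)
  expect_equal(gof$rmse[gof$scenario_id == "b"], sqrt(14 / 3))
  # perfect fit
  sc2 <- ref_scenario(t_end_h = 24, output_dt_h = 0.5)
  tc2 <- simulate_scenario(sc2)
  tt <- c(2, 4, 8)
  ds3 <- study_dataset(
    data.frame(scenario_id = "s1", observable = "dap_plasma_ngml",
               time_h = tt, mean = tc2$dap_plasma_ngml[match(tt, tc2$time_h)],
               sd = 1, n = 1),
    scenarios = list(s1 = sc2))
  gof3 <- goodness_of_fit(c(ka = sc2$drug$ka), ds3)
  expect_equal(gof3$r2[1], 1, tolerance = 1e-6)
  expect_equal(gof3$rmse[1], 0, tolerance = 1e-3)
  # zero-variance series flags R2 as undefined
  ds4 <- study_dataset(
    data.frame(scenario_id = "b", observable = "dap_plasma_ngml",
               time_h = c(4, 8), mean = c(2, 2), sd = 1, n = 1),
    scenarios = list(b = sc))
  expect_warning(gof4 <- goodness_of_fit(c(ka = 1), ds4), "zero-variance")
  expect_true(is.na(gof4$r2[1]))
})

test_that("multistart fitting is seed-deterministic", {
  ds <- generate_study(recovery_spec(cv = 0, seed = 7))
  f1 <- multistart_fit(ds, stage = "PK", n_starts = 2, seed = 99,
                       maxiter = 5)
  f2 <- multistart_fit(ds, stage = "PK", n_starts = 2, seed = 99,
                       maxiter = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$run_costs, f2$run_costs)
  expect_identical(f1$starts, f2$starts)
  expect_equal(f1$cost, min(f1$run_costs))
  # parameters respect the bounds
  b <- f1$bounds
  for (nm in names(f1$par)) {
    expect_gte(f1$par[[nm]], b[[nm]][1])
    expect_lte(f1$par[[nm]], b[[nm]][2])
  }
})

test_that("dataset validation catches structural problems", {
  sc <- ref_scenario(t_end_h = 24, output_dt_h = 1)
  expect_error(study_dataset(data.frame(a = 1), list(s1 = sc)), "lacks")
  df <- data.frame(scenario_id = "zz", observable = "dap_plasma_ngml",
                   time_h = 1, mean = 1, sd = 1, n = 1)
  expect_error(study_dataset(df, list(s1 = sc)), "zz")
  df2 <- df; df2$scenario_id <- "s1"; df2$time_h <- 99
  expect_error(study_dataset(df2, list(s1 = sc)), "horizon")
})
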
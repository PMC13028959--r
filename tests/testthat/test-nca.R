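test_that("AUC reproduces closed forms", {
  # rectangle
  expect_equal(nca_auc(seq(0, 10), rep(2, 11))$auc_0_t, 20)
  # mono-exponential: AUCinf = C0/k
  t <- seq(0, 48, 0.5)
  a <- nca_auc(t, 100 * exp(-0.1 * t))
  expect_equal(a$auc_inf, 1000, tolerance = 0.01)
  expect_equal(a$lambda_z, 0.1, tolerance = 1e-3)
  # all-zero profile
  z <- nca_auc(t, rep(0, length(t)))
  expect_equal(z$auc_0_t, 0)
  expect_equal(z$auc_inf, 0)
  expect_error(nca_auc(c(0, 1), c(1, 1)), ">= 3")
  expect_error(nca_auc(c(0, 1, 1), c(1, 1, 1)), "increasing")
})

test_that("AUC is additive over contiguous sub-intervals", {
  t <- seq(0, 24, 0.25)
  conc <- 80 * (exp(-0.08 * t) - exp(-1.1 * t))
  full <- nca_auc(t, conc)$auc_0_t
  cut <- 41  # t = 10 h
  left <- nca_auc(t[1:cut], conc[1:cut])$auc_0_t
  right <- nca_auc(t[cut:length(t)], conc[cut:length(t)])$auc_0_t
  expect_equal(left + right, full, tolerance = 1e-10)
})

test_that("half-life recovers known rate constants", {
  t <- seq(0, 72, 1)
  expect_equal(nca_half_life(t, 50 * exp(-0.0533 * t)), log(2) / 0.0533,
               tolerance = 0.005)
  expect_equal(nca_half_life(t, 10 * exp(-log(2) * t)), 1, tolerance = 1e-6)
  # biexponential with >= 10-fold separated phases: terminal phase wins
  conc <- 100 * exp(-1.0 * t) + 10 * exp(-0.05 * t)
  expect_equal(nca_half_life(t, conc), log(2) / 0.05, tolerance = 0.05)
  expect_error(nca_half_life(c(0, 1, 2, 3), c(1, 2, 3, 4)), "terminal")
})

test_that("excretion fractions follow the dose split", {
  fr <- excretion_fractions(ref_tc())
  expect_lt(abs(fr$frac_feces - 16), 0.5)
  expect_lt(fr$frac_urine_unchanged, 2)
  # no fecal split when the whole dose is absorbable
  sc <- scenario(drug = drug_parameters(F_gut = 1),
                 doses = list(dose_event(0, 10)), t_end_h = 24,
                 output_dt_h = 0.5)
  expect_equal(excretion_fractions(simulate_scenario(sc))$frac_feces, 0)
  expect_error(excretion_fractions(ref_tc(), dose_mg = 0), "undefined")
})

test_that("bioavailability of identical profiles is 100%", {
  pk <- list(auc_inf = 500, dose_mg = 10)
  expect_equal(bioavailability(pk, pk), 100)
  expect_error(bioavailability(list(auc_inf = NA, dose_mg = 10), pk),
               "unavailable")
})

test_that("half-life is dose-invariant under near-linear kinetics", {
  th <- sapply(c(2.5, 10, 20), function(d) {
    pk_params(simulate_scenario(ref_scenario(dose_mg = d, t_end_h = 96,
                                             output_dt_h = 0.5)), "dap")$thalf
  })
  expect_lt(diff(range(th)) / min(th), 0.05)
})
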
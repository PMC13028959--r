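test_that("zero-CV fixtures reproduce the noiseless model exactly", {
  ds <- generate_study(recovery_spec(cv = 0, seed = 7))
  expect_true(all(ds$sd == 0))
  tc <- simulate_scenario(attr(ds, "scenarios")$dose_10mg)
  sub <- ds[ds$scenario_id == "dose_10mg" &
              ds$observable == "dap_plasma_ngml", ]
  expect_equal(sub$mean, tc$dap_plasma_ngml[match(sub$time_h, tc$time_h)])
})

test_that("fixture generation is seed-reproducible", {
  d1 <- generate_study(recovery_spec(cv = 0.2, seed = 5))
  d2 <- generate_study(recovery_spec(cv = 0.2, seed = 5))
  d3 <- generate_study(recovery_spec(cv = 0.2, seed = 6))
  expect_identical(d1$mean, d2$mean)
  expect_identical(d1$sd, d2$sd)
  expect_false(identical(d1$mean, d3$mean))
  # noisy draws give strictly positive SDs where the signal is nonzero
  expect_true(all(d1$sd[d1$mean > 0] > 0))
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_study(recovery_spec(cv = 0.2, seed = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("reported means scatter like cv/sqrt(n) across regenerations", {
  spec0 <- fixture_spec(
    arms = list(list(label = "a", dose_mg = 10, t_end_h = 8)),
    observables = "dap_plasma_ngml", times = c(2, 4, 8),
    n_subjects = 12, cv = 0.2, seed = 1, label = "mc")
  truth <- generate_study(
    fixture_spec(arms = spec0$arms, observables = "dap_plasma_ngml",
                 times = c(2, 4, 8), n_subjects = 12, cv = 0,
                 seed = 1, label = "mc"))$mean
  reps <- 300
  means <- sapply(seq_len(reps), function(k) {
    spec0$seed <- 1000 + k
    generate_study(spec0)$mean
  })
  emp_cv <- apply(means, 1, sd) / truth
  # mean of n=12 lognormal deviates with CV 0.2: CV ~ 0.2/sqrt(12) = 0.0577
  expect_equal(mean(emp_cv), 0.2 / sqrt(12), tolerance = 0.15)
})

test_that("fixture suite writes the five canonical datasets", {
  dir <- withr::local_tempdir()
  paths <- fixture_suite(dir, seed = 100, n_subjects = 6)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.exists(sub("\\.csv$", ".json", paths))))
  dr <- utils::read.csv(paths[["dose_ranging"]])
  expect_setequal(unique(dr$scenario_id),
                  sprintf("dose_%smg", c(2.5, 10, 20, 50, 100, 250, 500)))
  ri <- utils::read.csv(paths[["renal_impairment"]])
  expect_setequal(unique(ri$scenario_id),
                  paste0("renal_", c("normal", "mild", "moderate", "severe")))
  # sidecar reconstructs a fit-ready dataset
  ds <- read_study_dataset(paths[["fed_fasted"]])
  expect_s3_class(ds, "dapa_dataset")
  expect_named(attr(ds, "scenarios"), c("fasted", "fed"))
  expect_equal(attr(ds, "scenarios")$fed$physiology$f_absorption, 0.3)
})

test_that("fixture validation rejects bad noise and group sizes", {
  expect_error(fixture_spec(arms = list(list(dose_mg = 10)), cv = -0.1),
               "non-negative")
  expect_error(fixture_spec(arms = list(list(dose_mg = 10)), n_subjects = 0),
               ">= 1")
})
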
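# Seeded synthetic-study generator: emulates curated clinical datasets
# (per-arm dosing protocol, group size n, sampling grid, noisy mean +/- SD
# time courses) so calibration and study emulation are testable offline.

.default_cv <- c(dap_plasma_ngml = 0.20, d3g_plasma_ngml = 0.20,
                 dap_urine_mg = 0.30, d3g_urine_mg = 0.30,
                 dap_feces_mg = 0.30, uge_g = 0.30)

#' Specification of a synthetic study
#'
#' @param arms List of arm configurations in the [run_study()] format
#'   (label, dosing, physiology overrides).
#' @param observables Timecourse columns to report.
#' @param times Sampling grid, h (> 0; t = 0 is used as the dosing origin).
#' @param n_subjects Group size per arm (>= 1).
#' @param cv Coefficient of variation of the lognormal residual noise;
#'   either a single value or a named vector per observable. `cv = 0`
#'   reproduces the noiseless model output.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param drug,pd Named lists of true parameter values overriding the
#'   reference parameterization (the "truth" for recovery tests).
#' @param label Study label.
#' @return Object of class `dapa_fixture_spec`.
#' @export
fixture_spec <- function(arms, observables = c("dap_plasma_ngml",
                                               "d3g_plasma_ngml",
                                               "dap_urine_mg",
                                               "d3g_urine_mg"),
                         times = c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48),
                         n_subjects = 12, cv = .default_cv, seed = 1,
                         drug = list(), pd = list(), label = "synthetic_study") {
  if (any(cv < 0)) stop("`cv` must be non-negative", call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (any(times <= 0)) stop("sampling `times` must be positive", call. = FALSE)
  if (length(cv) == 1L && is.null(names(cv)))
    cv <- stats::setNames(rep(cv, length(observables)), observables)
  missing_cv <- setdiff(observables, names(cv))
  if (length(missing_cv))
    cv[missing_cv] <- .default_cv[missing_cv]
  structure(list(arms = arms, observables = observables,
                 times = sort(unique(times)), n_subjects = n_subjects,
                 cv = cv, seed = seed, drug = drug, pd = pd, label = label),
            class = "dapa_fixture_spec")
}

#' Generate a synthetic study dataset
#'
#' Simulates the true model for every arm and draws `n_subjects`
#' multiplicative lognormal deviates per time point (mean-preserving:
#' `sdlog = sqrt(log(1 + cv^2))`, `meanlog = log(truth) - sdlog^2 / 2`),
#' reporting per-point mean, SD and n. With `cv = 0` the reported means
#' equal the noiseless model output and all SDs are 0.
#'
#' @param spec A [fixture_spec()].
#' @return A `dapa_dataset` whose attributes carry the arm scenarios, the
#'   true parameters (`truth`) and the seed.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "dapa_fixture_spec"))
  labels <- vapply(seq_along(spec$arms), function(i)
    spec$arms[[i]]$label %||% sprintf("arm%d", i), character(1))
  scenarios <- stats::setNames(lapply(seq_along(spec$arms), function(i) {
    arm <- spec$arms[[i]]
    arm$drug <- utils::modifyList(as.list(arm$drug %||% list()), spec$drug)
    arm$pd <- utils::modifyList(as.list(arm$pd %||% list()), spec$pd)
    arm$t_end_h <- max(spec$times, arm$t_end_h %||% 0)
    arm$output_grid <- sort(unique(c(0, spec$times)))
    .arm_to_scenario(arm, labels[i])
  }), labels)
  rows <- .with_seed(spec$seed, {
    do.call(rbind, lapply(labels, function(lab) {
      tc <- simulate_scenario(scenarios[[lab]])
      idx <- match(spec$times, tc$time_h)
      do.call(rbind, lapply(spec$observables, function(obs) {
        truth <- tc[[obs]][idx]
        cv <- spec$cv[[obs]]
        if (cv > 0) {
          sdlog <- sqrt(log(1 + cv^2))
          draws <- matrix(
            stats::rlnorm(length(truth) * spec$n_subjects,
                          meanlog = rep(log(pmax(truth, .Machine$double.xmin)),
                                        each = spec$n_subjects) - sdlog^2 / 2,
                          sdlog = sdlog),
            nrow = spec$n_subjects)
          draws[, truth == 0] <- 0
          m <- colMeans(draws)
          s <- apply(draws, 2, stats::sd)
          if (spec$n_subjects == 1L) s <- rep(0, length(truth))
        } else {
          m <- truth
          s <- rep(0, length(truth))
        }
        data.frame(scenario_id = lab, observable = obs,
                   time_h = spec$times, mean = m, sd = s,
                   n = spec$n_subjects)
      }))
    }))
  })
  ds <- study_dataset(rows, scenarios)
  attr(ds, "truth") <- list(drug = spec$drug, pd = spec$pd)
  attr(ds, "seed") <- spec$seed
  attr(ds, "spec") <- spec
  ds
}

#' Write the canonical fixture suite
#'
#' Produces five synthetic datasets mirroring the canonical clinical study
#' classes — dose ranging (2.5-500 mg), a four-arm renal impairment study,
#' a four-arm hepatic impairment study, a fed/fasted crossover and a
#' multiple-dose regimen — as CSV files with JSON sidecars recording the
#' true parameters and the seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base seed; fixture k uses `seed + k`.
#' @param n_subjects Group size per arm.
#' @return Invisibly, a named character vector of the CSV paths.
#' @export
fixture_suite <- function(dir, seed = 42, n_subjects = 12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    dose_ranging = fixture_spec(
      arms = lapply(c(2.5, 10, 20, 50, 100, 250, 500), function(d)
        list(label = sprintf("dose_%smg", d), dose_mg = d)),
      seed = seed + 1, n_subjects = n_subjects, label = "dose_ranging"),
    renal_impairment = fixture_spec(
      arms = lapply(c("normal", "mild", "moderate", "severe"), function(cl)
        list(label = paste0("renal_", cl), dose_mg = 50, renal_class = cl,
             population = "T2DM")),
      observables = c("dap_plasma_ngml", "d3g_plasma_ngml", "dap_urine_mg",
                      "d3g_urine_mg", "uge_g"),
      seed = seed + 2, n_subjects = n_subjects, label = "renal_impairment"),
    hepatic_impairment = fixture_spec(
      arms = lapply(c("none", "CTP_A", "CTP_B", "CTP_C"), function(cl)
        list(label = paste0("hepatic_", cl), dose_mg = 10, hepatic_class = cl)),
      seed = seed + 3, n_subjects = n_subjects, label = "hepatic_impairment"),
    fed_fasted = fixture_spec(
      arms = list(list(label = "fasted", dose_mg = 10, prandial = "fasted"),
                  list(label = "fed", dose_mg = 10, prandial = "fed")),
      seed = seed + 4, n_subjects = n_subjects, label = "fed_fasted"),
    multiple_dose = fixture_spec(
      arms = list(list(label = "qd_10mg", dose_mg = 10, n_doses = 7,
                       interval_h = 24, t_end_h = 192)),
      times = c(1, 2, 4, 8, 12, 24, 48, 96, 144, 145, 146, 148, 152, 156,
                168, 180, 192),
      seed = seed + 5, n_subjects = n_subjects, label = "multiple_dose")
  )
  paths <- vapply(names(specs), function(nm) {
    ds <- generate_study(specs[[nm]])
    csv <- file.path(dir, sprintf("%s_seed%d.csv", nm, specs[[nm]]$seed))
    write_study_dataset(ds, csv)
    csv
  }, character(1))
  invisible(paths)
}
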
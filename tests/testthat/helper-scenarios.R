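# Shared fixtures: reference scenarios and memoized simulations so that
# expensive trajectories are computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_scenario <- function(dose_mg = 10, route = "oral", t_end_h = 96,
                         output_dt_h = 0.1, ...) {
  scenario(physiology = default_physiology(...),
           doses = list(dose_event(0, dose_mg, route)),
           t_end_h = t_end_h, output_dt_h = output_dt_h,
           label = sprintf("%s_%gmg", route, dose_mg))
}

# single 10 mg oral dose, healthy fasted 75 kg subject, 96 h
ref_tc <- function() memo("ref_tc", simulate_scenario(ref_scenario()))

# matched IV microdose for bioavailability
ref_tc_iv <- function() memo("ref_tc_iv",
  simulate_scenario(ref_scenario(dose_mg = 0.080, route = "iv")))

# one-compartment limit: uniform partitioning, no metabolism, slow renal
# elimination only; the whole body collapses to a single well-mixed volume
onecpt_scenario <- function(k_el = 0.3) {
  scenario(
    physiology = default_physiology(),
    drug = drug_parameters(Kp_DAP = 1, Kp_re_DAP = 1, ps_re = 100,
                           Vmax_li = 0, f_ki_Vmax = 0,
                           k_DAPEX_ki = k_el, k_D3GEX_ki = 1),
    doses = list(dose_event(0, 10, "iv")),
    t_end_h = 96, output_dt_h = 0.5, label = "one_compartment")
}

# one-point dataset whose model prediction exceeds the stated observation
# by exactly `resid`, so the weighted cost has a known closed form
one_point_dataset <- function(resid = 1, n = 10, sd = 2) {
  sc <- ref_scenario(t_end_h = 24, output_dt_h = 0.5)
  tc <- simulate_scenario(sc)
  pred <- tc$dap_plasma_ngml[tc$time_h == 4]
  study_dataset(
    data.frame(scenario_id = "s1", observable = "dap_plasma_ngml",
               time_h = 4, mean = pred - resid, sd = sd, n = n),
    scenarios = list(s1 = sc))
}

# small noiseless dose-ranging fixture used by the recovery tests
recovery_truth <- list(ka = 0.9, Vmax_li = 14, f_ki_Vmax = 90,
                       k_DAPEX_ki = 0.06, k_D3GEX_ki = 9)

recovery_spec <- function(cv = 0, seed = 7) {
  fixture_spec(
    arms = list(list(label = "dose_10mg", dose_mg = 10),
                list(label = "dose_100mg", dose_mg = 100)),
    observables = c("dap_plasma_ngml", "d3g_plasma_ngml",
                    "dap_urine_mg", "d3g_urine_mg"),
    times = c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48),
    n_subjects = 12, cv = cv, seed = seed, drug = recovery_truth,
    label = "dose_ranging")
}
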
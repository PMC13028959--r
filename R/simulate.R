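#' Dose event
#'
#' @param time_h Time of administration, h (>= 0).
#' @param amount_mg Dose, mg (>= 0).
#' @param route `"oral"` or `"iv"`.
#' @return Object of class `dapa_dose`.
#' @export
dose_event <- function(time_h = 0, amount_mg = 10, route = c("oral", "iv")) {
  route <- match.arg(route)
  if (!is.numeric(time_h) || length(time_h) != 1L || time_h < 0)
    stop("`time_h` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(amount_mg) || length(amount_mg) != 1L || amount_mg < 0)
    stop("`amount_mg` must be a single non-negative number", call. = FALSE)
  structure(list(time_h = time_h, amount_mg = amount_mg, route = route),
            class = "dapa_dose")
}

#' Simulation scenario
#'
#' Bundles a physiology, drug and PD parameter set with a dosing regimen
#' and an output grid.
#'
#' @param physiology A `dapa_physiology` object.
#' @param drug A `dapa_drug_params` object.
#' @param pd A `dapa_pd_params` object.
#' @param doses List of [dose_event()]s (sorted by time on construction).
#' @param t_end_h Simulation horizon, h; must not precede the last dose.
#' @param output_dt_h Output resolution, h (ignored when `output_grid`
#'   is given).
#' @param output_grid Optional explicit output time grid, h.
#' @param label Scenario label used in messages and file output.
#' @return Object of class `dapa_scenario`.
#' @export
#' @examples
#' sc <- scenario(doses = list(dose_event(0, 10, "oral")), t_end_h = 48)
scenario <- function(physiology = default_physiology(),
                     drug = drug_parameters(),
                     pd = pd_parameters(),
                     doses = list(dose_event(0, 10, "oral")),
                     t_end_h = 48, output_dt_h = 0.1,
                     output_grid = NULL, label = "scenario") {
  stopifnot(inherits(physiology, "dapa_physiology"))
  if (!inherits(drug, "dapa_drug_params")) validate_drug_parameters(drug)
  stopifnot(inherits(pd, "dapa_pd_params"))
  if (inherits(doses, "dapa_dose")) doses <- list(doses)
  ok <- vapply(doses, inherits, logical(1), "dapa_dose")
  if (!all(ok)) stop("`doses` must be a list of dose_event() objects",
                     call. = FALSE)
  if (length(doses)) {
    doses <- doses[order(vapply(doses, `[[`, numeric(1), "time_h"))]
    if (t_end_h < max(vapply(doses, `[[`, numeric(1), "time_h")))
      stop("`t_end_h` must not precede the last dose time", call. = FALSE)
  }
  if (is.null(output_grid)) {
    output_grid <- seq(0, t_end_h, by = output_dt_h)
  } else {
    output_grid <- sort(unique(as.numeric(output_grid)))
    if (any(output_grid < 0) || max(output_grid) > t_end_h)
      stop("`output_grid` must lie within [0, t_end_h]", call. = FALSE)
  }
  structure(list(physiology = physiology, drug = drug, pd = pd,
                 doses = doses, t_end_h = t_end_h,
                 output_grid = output_grid, label = label),
            class = "dapa_scenario")
}

#' @export
print.dapa_scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> %d dose(s), horizon %g h, %d output points\n",
              x$label, length(x$doses), x$t_end_h, length(x$output_grid)))
  for (d in x$doses)
    cat(sprintf("  %s %.3g mg at t = %g h\n", d$route, d$amount_mg, d$time_h))
  print(x$physiology)
  invisible(x)
}

# apply a dose bolus to the state vector (amounts in umol)
.apply_dose <- function(y, dose, drug) {
  umol <- dose$amount_mg / drug$MW_DAP * 1000
  if (dose$route == "oral") {
    y["DAP_lumen"] <- y["DAP_lumen"] + drug$F_gut * umol
    y["DAP_feces_transit"] <- y["DAP_feces_transit"] + (1 - drug$F_gut) * umol
  } else {
    y["DAP_bl"] <- y["DAP_bl"] + umol
  }
  y
}

#' Simulate a scenario
#'
#' Deterministic integration of the whole-body model with stepwise restarts
#' at every dose event. Oral events place `amount * F_gut` in the
#' absorbable lumen pool and the remainder in the fecal transit pool; IV
#' events are added to blood.
#'
#' @param sc A `dapa_scenario`.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @param compiled Use the compiled right-hand side (default); the
#'   interpreted vector field from [build_rhs()] gives identical results
#'   and is kept for inspection and cross-checking.
#' @return A `dapa_timecourse`: data frame with columns `time_h`,
#'   `dap_plasma_ngml`, `d3g_plasma_ngml`, `dap_urine_mg`, `d3g_urine_mg`,
#'   `dap_feces_mg`, `rtg_mM`, `uge_g`, carrying the full state matrix
#'   (umol), the cumulative administered dose and the scenario as
#'   attributes.
#' @export
simulate_scenario <- function(sc, rtol = 1e-8, atol = 1e-10,
                              compiled = TRUE) {
  stopifnot(inherits(sc, "dapa_scenario"))
  if (compiled) {
    pvec <- ode_parameter_vector(sc$physiology, sc$drug, sc$pd)
    integrate_seg <- function(y, tt)
      deSolve::lsoda(y, tt, func = "dapasim_derivs", parms = unname(pvec),
                     dllname = "dapasim", initfunc = "dapasim_initmod",
                     rtol = rtol, atol = atol)
  } else {
    rhs <- build_rhs(sc$physiology, sc$drug, sc$pd)
    integrate_seg <- function(y, tt)
      deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
  }
  grid <- sc$output_grid
  dose_times <- vapply(sc$doses, `[[`, numeric(1), "time_h")
  breaks <- sort(unique(c(grid[1], dose_times, max(grid))))
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  # doses at or before the grid start are applied as initial conditions
  out_rows <- NULL
  admin <- numeric(0)
  admin_cum <- 0
  t0 <- grid[1]
  for (d in sc$doses[dose_times <= t0]) {
    y <- .apply_dose(y, d, sc$drug)
    admin_cum <- admin_cum + d$amount_mg / sc$drug$MW_DAP * 1000
  }
  segs <- cbind(head(breaks, -1), tail(breaks, -1))
  segs <- segs[segs[, 1] < segs[, 2], , drop = FALSE]
  if (nrow(segs) == 0)
    segs <- matrix(c(t0, max(grid, t0)), ncol = 2)
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1]; b <- segs[i, 2]
    if (i > 1) {
      for (d in sc$doses[dose_times == a]) {
        y <- .apply_dose(y, d, sc$drug)
        admin_cum <- admin_cum + d$amount_mg / sc$drug$MW_DAP * 1000
      }
    }
    tt <- unique(c(a, grid[grid > a & grid <= b], b))
    sol <- tryCatch(
      integrate_seg(y, tt),
      warning = function(w)
        stop(sprintf("integration failed for scenario '%s': %s",
                     sc$label, conditionMessage(w)), call. = FALSE),
      error = function(e)
        stop(sprintf("integration failed for scenario '%s': %s",
                     sc$label, conditionMessage(e)), call. = FALSE))
    keep <- sol[, 1] %in% grid & (sol[, 1] > a | i == 1L)
    if (any(keep)) {
      out_rows <- rbind(out_rows, sol[keep, -1, drop = FALSE])
      admin <- c(admin, rep(admin_cum, sum(keep)))
    }
    y <- stats::setNames(sol[nrow(sol), -1], .state_names)
  }
  state <- out_rows
  colnames(state) <- .state_names
  state[state < 0 & state > -atol * 10] <- 0
  drug <- sc$drug
  phys <- sc$physiology
  pdp <- sc$pd
  cdap <- state[, "DAP_bl"] / (phys$FVbl * phys$BW) * drug$MW_DAP
  rtg_series <- rtg(cdap, pdp)
  uge_mmolh <- uge_rate(phys$FPG, rtg_series, phys$GFR_ref * phys$f_renal)
  uge_mmol <- c(0, cumsum(diff(grid) *
                            (head(uge_mmolh, -1) + tail(uge_mmolh, -1)) / 2))
  tc <- data.frame(
    time_h = grid,
    dap_plasma_ngml = cdap,
    d3g_plasma_ngml = state[, "D3G_bl"] / (phys$FVbl * phys$BW) * drug$MW_D3G,
    dap_urine_mg = state[, "DAP_urine"] * drug$MW_DAP / 1000,
    d3g_urine_mg = state[, "D3G_urine"] * drug$MW_D3G / 1000,
    dap_feces_mg = state[, "DAP_feces"] * drug$MW_DAP / 1000,
    rtg_mM = rtg_series,
    uge_g = uge_mmol * MOLAR_MASS[["glucose"]] / 1000
  )
  structure(tc, class = c("dapa_timecourse", "data.frame"),
            state = state, admin_umol = admin, scenario = sc,
            units = c(time_h = "h", dap_plasma_ngml = "ng/mL",
                      d3g_plasma_ngml = "ng/mL", dap_urine_mg = "mg",
                      d3g_urine_mg = "mg", dap_feces_mg = "mg",
                      rtg_mM = "mM", uge_g = "g"))
}

# resolve/assign one scalar addressed by a dotted path such as "drug.ka",
# "physiology.f_absorption", "pd.IC50" or the special path "dose_mg"
.set_scenario_param <- function(sc, param_path, value) {
  if (identical(param_path, "dose_mg")) {
    sc$doses <- lapply(sc$doses, function(d) { d$amount_mg <- value; d })
    return(sc)
  }
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L ||
      !parts[1] %in% c("physiology", "drug", "pd") ||
      is.null(sc[[parts[1]]][[parts[2]]]) ||
      !is.numeric(sc[[parts[1]]][[parts[2]]]))
    stop(sprintf("unknown parameter path '%s'", param_path), call. = FALSE)
  sc[[parts[1]]][[parts[2]]] <- value
  sc
}

#' Parameter scan
#'
#' Re-simulates a scenario over a grid of values for one scalar parameter,
#' holding everything else fixed, and summarises PK (NCA) and PD readouts
#' per value. Runs are independent, so results do not depend on the order
#' of `values`.
#'
#' @param base A `dapa_scenario`.
#' @param param_path Dotted path addressing one scalar: `"drug.<name>"`,
#'   `"physiology.<name>"`, `"pd.<name>"`, or `"dose_mg"` (sets the amount
#'   of every dose event).
#' @param values Numeric vector of parameter values.
#' @param uge_horizon_h Horizon for the cumulative-UGE readout, h.
#' @return Object of class `dapa_scan`: list with `summary` (data frame of
#'   value, AUC/Cmax/Tmax/half-life for DAP and D3G, `uge_g`) and
#'   `timecourses` (one `dapa_timecourse` per value).
#' @export
parameter_scan <- function(base, param_path, values, uge_horizon_h = 24) {
  stopifnot(inherits(base, "dapa_scenario"))
  runs <- lapply(values, function(v) {
    sc <- .set_scenario_param(base, param_path, v)
    sc$label <- sprintf("%s[%s=%g]", base$label, param_path, v)
    simulate_scenario(sc)
  })
  summ <- do.call(rbind, lapply(seq_along(values), function(i) {
    tc <- runs[[i]]
    pk_dap <- pk_params(tc, compound = "dap")
    pk_d3g <- pk_params(tc, compound = "d3g")
    data.frame(value = values[i],
               auc_dap = pk_dap$auc_inf, cmax_dap = pk_dap$cmax,
               tmax_dap = pk_dap$tmax, thalf_dap = pk_dap$thalf,
               auc_d3g = pk_d3g$auc_inf, cmax_d3g = pk_d3g$cmax,
               thalf_d3g = pk_d3g$thalf,
               uge_g = uge_at(tc, uge_horizon_h))
  }))
  names(summ)[1] <- "value"
  structure(list(param_path = param_path, summary = summ,
                 timecourses = runs),
            class = "dapa_scan")
}

#' @export
print.dapa_scan <- function(x, ...) {
  cat(sprintf("<parameter scan over %s, %d values>\n", x$param_path,
              nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Run a multi-arm study configuration
#'
#' Executes one simulation per arm, with per-arm physiology overrides and
#' dosing regimens, on the study's sampling grid.
#'
#' @param config List with optional `label` and an `arms` list; every arm
#'   is a list with `label`, dosing (`doses` as a list of [dose_event()]s,
#'   or `dose_mg`/`route`/`n_doses`/`interval_h` shorthand), optional
#'   physiology overrides (`bodyweight_kg`, `renal_class`, `hepatic_class`,
#'   `prandial`, `population`, `fpg_mM`), optional `pd`/`drug` overrides,
#'   `t_end_h` and `output_grid`.
#' @return Named list of `dapa_timecourse` objects, one per arm.
#' @export
run_study <- function(config) {
  if (is.null(config$arms) || !length(config$arms))
    stop("study config must contain a non-empty `arms` list", call. = FALSE)
  arms <- config$arms
  labels <- vapply(seq_along(arms), function(i)
    arms[[i]]$label %||% sprintf("arm%d", i), character(1))
  res <- lapply(seq_along(arms), function(i) {
    arm <- arms[[i]]
    sc <- tryCatch(.arm_to_scenario(arm, labels[i]),
                   error = function(e)
                     stop(sprintf("study arm '%s': %s", labels[i],
                                  conditionMessage(e)), call. = FALSE))
    simulate_scenario(sc)
  })
  stats::setNames(res, labels)
}

.arm_to_scenario <- function(arm, label) {
  phys <- default_physiology(
    BW = arm$bodyweight_kg %||% 75,
    renal_class = arm$renal_class %||% "normal",
    hepatic_class = arm$hepatic_class %||% "none",
    prandial = arm$prandial %||% "fasted",
    population = arm$population %||% "healthy",
    FPG = arm$fpg_mM)
  drug <- do.call(drug_parameters, as.list(arm$drug %||% list()))
  pd <- do.call(pd_parameters, as.list(arm$pd %||% list()))
  doses <- arm$doses
  if (is.null(doses)) {
    if (is.null(arm$dose_mg)) stop("arm specifies neither `doses` nor `dose_mg`")
    n <- arm$n_doses %||% 1
    dt <- arm$interval_h %||% 24
    doses <- lapply(seq_len(n) - 1,
                    function(k) dose_event(k * dt, arm$dose_mg,
                                           arm$route %||% "oral"))
  } else if (all(vapply(doses, is.list, logical(1))) &&
             !all(vapply(doses, inherits, logical(1), "dapa_dose"))) {
    doses <- lapply(doses, function(d)
      dose_event(d$time_h %||% 0, d$amount_mg, d$route %||% "oral"))
  }
  t_end <- arm$t_end_h %||% 48
  scenario(physiology = phys, drug = drug, pd = pd, doses = doses,
           t_end_h = t_end, output_dt_h = arm$output_dt_h %||% 0.1,
           output_grid = arm$output_grid, label = label)
}
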
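# Readers and writers: scenario JSON, tidy timecourse CSV, study-format
# dataset CSV with a JSON sidecar.

.known_units <- c("h", "ng/mL", "mg", "mM", "g", "mmol", "umol", "1")

#' Load a scenario from JSON
#'
#' Schema: `label`; `physiology` block (`bodyweight_kg`, `renal_class`,
#' `hepatic_class`, `prandial`, `population`, `fpg_mM`); optional `drug`
#' overrides (fields of [drug_parameters()]); optional `pd` block
#' (`rtg0_mM`, `imax`, `ic50_ng_ml`); `doses` (list of `time_h`, `route`,
#' `amount_mg`); `t_end_h`; `output_dt_h` or `output_grid`. Missing fields
#' take the documented defaults.
#'
#' @param path Path to a JSON scenario file.
#' @return A `dapa_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  scenario_from_list(cfg)
}

#' @rdname load_scenario
#' @param cfg Scenario configuration as a nested list (parsed JSON).
#' @export
scenario_from_list <- function(cfg) {
  ph <- cfg$physiology %||% list()
  phys <- tryCatch(
    default_physiology(BW = ph$bodyweight_kg %||% 75,
                       renal_class = ph$renal_class %||% "normal",
                       hepatic_class = ph$hepatic_class %||% "none",
                       prandial = ph$prandial %||% "fasted",
                       population = ph$population %||% "healthy",
                       FPG = ph$fpg_mM),
    error = function(e) stop("invalid `physiology` block: ",
                             conditionMessage(e), call. = FALSE))
  drug <- tryCatch(do.call(drug_parameters, as.list(cfg$drug %||% list())),
                   error = function(e) stop("invalid `drug` block: ",
                                            conditionMessage(e), call. = FALSE))
  pdcfg <- cfg$pd %||% list()
  pd <- tryCatch(
    pd_parameters(RTG0 = pdcfg$rtg0_mM, Imax = pdcfg$imax,
                  IC50 = pdcfg$ic50_ng_ml),
    error = function(e) stop("invalid `pd` block: ", conditionMessage(e),
                             call. = FALSE))
  doses <- lapply(cfg$doses %||% list(list(time_h = 0, amount_mg = 10,
                                           route = "oral")),
                  function(d) tryCatch(
                    dose_event(d$time_h %||% 0, d$amount_mg,
                               d$route %||% "oral"),
                    error = function(e) stop("invalid dose event: ",
                                             conditionMessage(e),
                                             call. = FALSE)))
  scenario(physiology = phys, drug = drug, pd = pd, doses = doses,
           t_end_h = cfg$t_end_h %||% 48,
           output_dt_h = cfg$output_dt_h %||% 0.1,
           output_grid = unlist(cfg$output_grid),
           label = cfg$label %||% "scenario")
}

#' Write / read a timecourse as tidy CSV
#'
#' Long format with columns `time_h`, `quantity`, `value`, `unit`; values
#' carry 12 significant digits so a write/read round trip is lossless to
#' that precision. Reading enforces strictly increasing time and a known
#' unit dialect (h, ng/mL, mg, mM, g).
#'
#' @param tc A `dapa_timecourse`.
#' @param path Output / input CSV path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a `dapa_timecourse` (without the simulation state attributes).
#' @export
write_timecourse <- function(tc, path) {
  units <- attr(tc, "units")
  qty <- setdiff(names(tc), "time_h")
  long <- do.call(rbind, lapply(qty, function(q)
    data.frame(time_h = tc$time_h, quantity = q,
               value = sprintf("%.12g", tc[[q]]),
               unit = unname(units[q]))))
  if (is.null(long))
    long <- data.frame(time_h = numeric(0), quantity = character(0),
                       value = character(0), unit = character(0))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_h", "quantity", "value", "unit")
  if (!all(req %in% names(long)))
    stop("timecourse CSV must have columns time_h, quantity, value, unit",
         call. = FALSE)
  bad <- setdiff(unique(long$unit), .known_units)
  if (length(bad) && nrow(long))
    stop("unknown unit string(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  qty <- unique(long$quantity)
  if (!nrow(long)) {
    out <- data.frame(time_h = numeric(0))
    return(structure(out, class = c("dapa_timecourse", "data.frame"),
                     units = c(time_h = "h")))
  }
  times <- sort(unique(long$time_h))
  units <- c(time_h = "h")
  out <- data.frame(time_h = times)
  for (q in qty) {
    sub <- long[long$quantity == q, ]
    if (any(diff(sub$time_h) <= 0))
      stop("times out of order for quantity ", q, call. = FALSE)
    out[[q]] <- as.numeric(sub$value)[match(times, sub$time_h)]
    units[q] <- sub$unit[1]
  }
  structure(out, class = c("dapa_timecourse", "data.frame"), units = units)
}

#' Write / read a study-format dataset
#'
#' The CSV holds the observation table (`scenario_id`, `observable`,
#' `time_h`, `mean`, `sd`, `n`); a JSON sidecar (same path, `.json`)
#' records the generating specification — arms, sampling grid, noise
#' model, seed and true parameters — so the dataset can be reconstructed
#' for fitting.
#'
#' @param ds A `dapa_dataset` (from [generate_study()] or
#'   [study_dataset()]).
#' @param path CSV path.
#' @return `write_study_dataset` returns `path` invisibly;
#'   `read_study_dataset` returns a `dapa_dataset`.
#' @export
write_study_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  spec <- attr(ds, "spec")
  if (!is.null(spec)) {
    side <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(
      list(label = spec$label, seed = spec$seed,
           n_subjects = spec$n_subjects, cv = as.list(spec$cv),
           observables = spec$observables, times = spec$times,
           true_parameters = list(drug = spec$drug, pd = spec$pd),
           arms = spec$arms),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_study_dataset
#' @param scenarios Optional named list of scenarios; required when no
#'   JSON sidecar is present.
#' @export
read_study_dataset <- function(path, scenarios = NULL) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- sub("\\.csv$", ".json", path)
  truth <- NULL
  if (is.null(scenarios) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = FALSE)
    labels <- vapply(seq_along(meta$arms), function(i)
      meta$arms[[i]]$label %||% sprintf("arm%d", i), character(1))
    truth <- meta$true_parameters
    scenarios <- stats::setNames(lapply(seq_along(meta$arms), function(i) {
      arm <- meta$arms[[i]]
      arm$drug <- utils::modifyList(as.list(arm$drug %||% list()),
                                    lapply(truth$drug %||% list(), identity))
      arm$pd <- utils::modifyList(as.list(arm$pd %||% list()),
                                  lapply(truth$pd %||% list(), identity))
      arm$t_end_h <- max(unlist(meta$times), arm$t_end_h %||% 0)
      arm$output_grid <- sort(unique(c(0, unlist(meta$times))))
      .arm_to_scenario(arm, labels[i])
    }), labels)
  }
  if (is.null(scenarios))
    stop("no JSON sidecar found; supply `scenarios` explicitly", call. = FALSE)
  ds <- study_dataset(data, scenarios)
  attr(ds, "truth") <- truth
  ds
}
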
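# Local normalized sensitivity analysis with symmetric midpoint differences.

.default_sens_params <- function() {
  c(paste0("drug.", c("ka", "F_gut", "Kp_DAP", "Kp_re_DAP", "Kp_D3G", "Km",
                      "Vmax_li", "f_ki_Vmax", "k_DAPEX_ki", "k_D3GEX_ki",
                      "k_feces", "ps_re")),
    paste0("pd.", c("RTG0", "Imax", "IC50")),
    paste0("physiology.", c("f_renal", "f_absorption", "GFR_ref", "FPG")))
}

.sens_readouts <- function(sc, uge_horizon_h = 24) {
  tc <- simulate_scenario(sc)
  dap <- pk_params(tc, "dap"); d3g <- pk_params(tc, "d3g")
  c(AUC_DAP = dap$auc_inf, Cmax_DAP = dap$cmax, thalf_DAP = dap$thalf,
    AUC_D3G = d3g$auc_inf, Cmax_D3G = d3g$cmax, thalf_D3G = d3g$thalf,
    UGE24 = uge_at(tc, uge_horizon_h))
}

#' Local normalized sensitivities of PK/PD readouts
#'
#' Perturbs each parameter by +/- `delta` (relative) around its reference
#' value and forms the symmetric midpoint difference, normalized to a
#' dimensionless elasticity:
#' `S = (q(p * (1 + delta)) - q(p * (1 - delta))) / (2 * delta * q(p))`.
#' Readouts are single-dose AUC, Cmax and half-life for DAP and D3G plus
#' cumulative urinary glucose excretion at 24 h. Parameters whose reference
#' value is 0 or whose base readout is 0 yield `NA` (flagged, not silently
#' zero). Physical constants, conversion factors and dosing are not part of
#' the default parameter set.
#'
#' @param base A `dapa_scenario` (typically a single 10 mg oral dose).
#' @param parameters Character vector of parameter paths (see
#'   [parameter_scan()]); default covers the estimable drug, PD and
#'   physiology scaling parameters.
#' @param delta Relative perturbation (default 0.01, i.e. +/- 1%).
#' @param uge_horizon_h Horizon of the UGE readout, h.
#' @return Matrix of class `sensitivity_matrix` (rows = parameters,
#'   columns = readouts) with attributes `perturbation` and
#'   `base_readouts`.
#' @export
local_sensitivity <- function(base, parameters = .default_sens_params(),
                              delta = 0.01, uge_horizon_h = 24) {
  stopifnot(inherits(base, "dapa_scenario"))
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  q0 <- .sens_readouts(base, uge_horizon_h)
  S <- matrix(NA_real_, nrow = length(parameters), ncol = length(q0),
              dimnames = list(parameters, names(q0)))
  for (i in seq_along(parameters)) {
    path <- parameters[i]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    p0 <- base[[parts[1]]][[parts[2]]]
    if (is.null(p0) || !is.numeric(p0))
      stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
    if (p0 == 0) next  # zero reference value: sensitivity undefined -> NA
    qp <- .sens_readouts(.set_scenario_param(base, path, p0 * (1 + delta)),
                         uge_horizon_h)
    qm <- .sens_readouts(.set_scenario_param(base, path, p0 * (1 - delta)),
                         uge_horizon_h)
    s <- (qp - qm) / (2 * delta * q0)
    s[q0 == 0] <- NA_real_
    S[i, ] <- s
  }
  structure(S, class = c("sensitivity_matrix", class(S)),
            perturbation = delta, base_readouts = q0)
}

#' Filter and cluster a sensitivity matrix
#'
#' Removes parameters whose normalized sensitivities all fall below
#' `threshold` in absolute value (or are undefined), then orders the
#' remaining rows by single-linkage hierarchical clustering on Euclidean
#' row distance.
#'
#' @param S A `sensitivity_matrix` from [local_sensitivity()].
#' @param threshold Absolute sensitivity below which a parameter is
#'   dropped (default 0.1).
#' @return The filtered, reordered matrix; the `hclust` object is attached
#'   as attribute `clustering` when at least two rows remain. An empty
#'   matrix (with a warning) when nothing survives the filter.
#' @export
filter_and_cluster <- function(S, threshold = 0.1) {
  keep <- apply(S, 1, function(r) any(abs(r) >= threshold, na.rm = TRUE))
  Sf <- S[keep, , drop = FALSE]
  if (nrow(Sf) == 0) {
    warning("no parameter exceeds the sensitivity threshold; empty result")
    return(structure(Sf, class = class(S),
                     perturbation = attr(S, "perturbation")))
  }
  hc <- NULL
  if (nrow(Sf) >= 2) {
    Sd <- Sf
    Sd[!is.finite(Sd)] <- 0  # undefined entries do not contribute distance
    hc <- stats::hclust(stats::dist(Sd), method = "single")
    Sf <- Sf[hc$order, , drop = FALSE]
  }
  structure(Sf, class = class(S), perturbation = attr(S, "perturbation"),
            base_readouts = attr(S, "base_readouts"), clustering = hc)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity matrix> %d parameters x %d readouts (delta = %g)\n",
              nrow(x), ncol(x), attr(x, "perturbation")))
  print(round(unclass(x), 3))
  invisible(x)
}
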
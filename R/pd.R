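#' Renal threshold for glucose under SGLT2 inhibition
#'
#' Saturable (Emax-type) reduction of the renal glucose threshold driven by
#' total dapagliflozin plasma concentration:
#' `RTG = RTG0 * (1 - Imax * C / (IC50 + C))`, strictly decreasing in `C`.
#'
#' @param C_dap_ngml Dapagliflozin plasma concentration, ng/mL (>= 0).
#' @param pd A `dapa_pd_params` object.
#' @return RTG in mM.
#' @export
#' @examples
#' rtg(0, pd_parameters())                    # baseline RTG0
#' rtg(pd_parameters()$IC50, pd_parameters()) # half-maximal reduction
rtg <- function(C_dap_ngml, pd = pd_parameters()) {
  stopifnot(inherits(pd, "dapa_pd_params"))
  if (any(C_dap_ngml < 0))
    stop("`C_dap_ngml` must be non-negative", call. = FALSE)
  pd$RTG0 * (1 - pd$Imax * C_dap_ngml / (pd$IC50 + C_dap_ngml))
}

#' Instantaneous urinary glucose excretion rate
#'
#' Filtered glucose above the renal threshold is excreted:
#' `GFR * max(0, FPG - RTG)`.
#'
#' @param FPG Plasma glucose, mM.
#' @param RTG Renal threshold for glucose, mM.
#' @param GFR Glomerular filtration rate, L/h.
#' @return Excretion rate, mmol/h.
#' @export
uge_rate <- function(FPG, RTG, GFR) {
  if (any(FPG < 0) || any(RTG < 0) || any(GFR < 0))
    stop("`FPG`, `RTG` and `GFR` must be non-negative", call. = FALSE)
  GFR * pmax(0, FPG - RTG)
}

#' Cumulative urinary glucose excretion from a simulated profile
#'
#' Integrates [uge_rate()] along the dapagliflozin plasma profile of a
#' timecourse (trapezoidal rule) and converts to grams of glucose.
#'
#' @param tc A `dapa_timecourse`.
#' @param phys Physiology providing GFR (`GFR_ref * f_renal`) and FPG;
#'   defaults to the scenario the timecourse was simulated from.
#' @param pd PD parameters; same default.
#' @param horizon_h Upper integration limit, h; must not exceed the
#'   profile span.
#' @return Cumulative UGE in g.
#' @export
cumulative_uge <- function(tc, phys = NULL, pd = NULL, horizon_h = 24) {
  sc <- attr(tc, "scenario")
  phys <- phys %||% sc$physiology
  pd <- pd %||% sc$pd
  t <- tc$time_h
  if (horizon_h > max(t) + 1e-9)
    stop("`horizon_h` exceeds the simulated trajectory", call. = FALSE)
  keep <- t <= horizon_h + 1e-12
  t <- t[keep]
  rate <- uge_rate(phys$FPG, rtg(tc$dap_plasma_ngml[keep], pd),
                   phys$GFR_ref * phys$f_renal)
  mmol <- sum(diff(t) * (head(rate, -1) + tail(rate, -1)) / 2)
  mmol * MOLAR_MASS[["glucose"]] / 1000
}

#' Cumulative urinary glucose excretion at a time point
#'
#' Reads the integrated UGE state of a simulated timecourse at `horizon_h`
#' (linear interpolation on the output grid).
#'
#' @param tc A `dapa_timecourse`.
#' @param horizon_h Time point, h (within the simulated span).
#' @return Cumulative UGE in g.
#' @export
uge_at <- function(tc, horizon_h = 24) {
  if (horizon_h > max(tc$time_h) + 1e-9)
    stop("`horizon_h` exceeds the simulated trajectory", call. = FALSE)
  stats::approx(tc$time_h, tc$uge_g, xout = horizon_h)$y
}
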
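#' Renal function scaling factor from KDIGO-style category
#'
#' Maps a renal function category to the factor `f_renal` applied to the
#' glomerular filtration rate and to the renal excretion of dapagliflozin
#' and D3G. Categories follow eGFR bands: normal (>= 90 mL/min), mild
#' (50-89), moderate (30-49), severe (<= 30).
#'
#' @param renal_class One of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @return `f_renal` in (0, 1].
#' @export
#' @examples
#' renal_factor("moderate")
renal_factor <- function(renal_class) {
  map <- c(normal = 1.00, mild = 0.69, moderate = 0.32, severe = 0.19)
  renal_class <- match.arg(renal_class, names(map))
  unname(map[renal_class])
}

#' Cirrhosis severity factor from Child-Turcotte-Pugh class
#'
#' Maps a CTP class to `f_cirrhosis`, the fraction of functional liver
#' parenchyma lost. The same fraction of hepatic inflow is treated as
#' portosystemic shunt.
#'
#' @param hepatic_class One of `"none"`, `"CTP_A"` (mild, 5-6 points),
#'   `"CTP_B"` (moderate, 7-9), `"CTP_C"` (severe, 10-15).
#' @return `f_cirrhosis` in \[0, 1).
#' @export
hepatic_factor <- function(hepatic_class) {
  map <- c(none = 0.00, CTP_A = 0.40, CTP_B = 0.70, CTP_C = 0.80)
  hepatic_class <- match.arg(hepatic_class, names(map))
  unname(map[hepatic_class])
}

#' Intestinal absorption activity from prandial state
#'
#' The fed state slows gastric emptying roughly threefold, modelled as a
#' proportional reduction of the first-order absorption rate constant:
#' `f_absorption` = 1.0 fasted, 0.3 fed.
#'
#' @param prandial `"fasted"` or `"fed"`.
#' @return `f_absorption` > 0.
#' @export
prandial_factor <- function(prandial) {
  map <- c(fasted = 1.0, fed = 0.3)
  prandial <- match.arg(prandial, names(map))
  unname(map[prandial])
}

#' Default fasting plasma glucose by population
#'
#' @param population `"healthy"` (5 mM), `"T1DM"` or `"T2DM"` (7.5 mM).
#' @return FPG in mM.
#' @export
default_fpg <- function(population) {
  map <- c(healthy = 5.0, T1DM = 7.5, T2DM = 7.5)
  population <- match.arg(population, names(map))
  unname(map[population])
}

#' Build the physiological parameter set for a subject
#'
#' Converts subject covariates into the physiology block consumed by the
#' ODE core: fractional organ volumes and blood flows (scaled with body
#' weight; tissue density 1 kg/L), cardiac output, reference GFR, and the
#' impairment/absorption scaling factors. The rest compartment receives the
#' volume and flow not assigned to a named organ, so fractional volumes sum
#' to 1 and systemic flows sum to cardiac output.
#'
#' @param BW Body weight in kg (> 0).
#' @param renal_class Renal function category, see [renal_factor()].
#' @param hepatic_class CTP class, see [hepatic_factor()].
#' @param prandial Prandial state, see [prandial_factor()].
#' @param population Population label used for the default FPG, see
#'   [default_fpg()].
#' @param FPG Optional study-specific fasting plasma glucose (mM);
#'   overrides the population default.
#' @return Object of class `dapa_physiology`: a list with fractional
#'   volumes `FVgu`, `FVki`, `FVli`, `FVlu`, `FVbl`, `FVre`; fractional
#'   flows `FQgu`, `FQki`, `FQh`, `FQlu`, `FQre`; `BW`, `CO` (L/h),
#'   `GFR_ref` (L/h at f_renal = 1), `f_renal`, `f_cirrhosis`,
#'   `f_absorption`, `FPG` (mM).
#' @export
#' @examples
#' phys <- default_physiology(BW = 75)
#' organ_volumes(phys)[["li"]]  # 1.575 L
default_physiology <- function(BW = 75, renal_class = "normal",
                               hepatic_class = "none", prandial = "fasted",
                               population = "healthy", FPG = NULL) {
  if (!is.numeric(BW) || length(BW) != 1L || !is.finite(BW) || BW <= 0)
    stop("`BW` must be a single positive number (kg)", call. = FALSE)
  FV <- c(gu = 0.0171, ki = 0.0044, li = 0.0210, lu = 0.0076, bl = 0.0786)
  FQ <- c(gu = 0.18, ki = 0.19, h = 0.215, lu = 1.0)
  fpg <- FPG %||% default_fpg(population)
  if (!is.numeric(fpg) || fpg < 0)
    stop("`FPG` must be a non-negative number (mM)", call. = FALSE)
  phys <- structure(list(
    BW = BW,
    FVgu = FV[["gu"]], FVki = FV[["ki"]], FVli = FV[["li"]],
    FVlu = FV[["lu"]], FVbl = FV[["bl"]],
    FVre = 1 - sum(FV),
    FQgu = FQ[["gu"]], FQki = FQ[["ki"]], FQh = FQ[["h"]],
    FQlu = FQ[["lu"]],
    FQre = 1 - FQ[["h"]] - FQ[["ki"]],
    CO = 108 * BW / 70,       # L/h, conventional resting value at 70 kg
    GFR_ref = 6.5,            # L/h (~108 mL/min) at f_renal = 1
    f_renal = renal_factor(renal_class),
    f_cirrhosis = hepatic_factor(hepatic_class),
    f_absorption = prandial_factor(prandial),
    FPG = fpg,
    renal_class = renal_class, hepatic_class = hepatic_class,
    prandial = prandial, population = population
  ), class = "dapa_physiology")
  phys
}

#' Absolute organ volumes (L) for a physiology
#'
#' @param phys A `dapa_physiology` object.
#' @return Named vector (gu, ki, li, lu, bl, re) in L, assuming 1 kg/L.
#' @export
organ_volumes <- function(phys) {
  stopifnot(inherits(phys, "dapa_physiology"))
  with(phys, c(gu = FVgu, ki = FVki, li = FVli, lu = FVlu,
               bl = FVbl, re = FVre) * BW)
}

#' Absolute blood flows (L/h) for a physiology
#'
#' `h` is hepatic venous outflow; the hepatic arterial inflow is
#' `h - gu` by conservation. `lu` equals cardiac output.
#'
#' @param phys A `dapa_physiology` object.
#' @return Named vector (gu, ki, h, ha, lu, re) in L/h.
#' @export
organ_flows <- function(phys) {
  stopifnot(inherits(phys, "dapa_physiology"))
  with(phys, c(gu = FQgu, ki = FQki, h = FQh, ha = FQh - FQgu,
               lu = FQlu, re = FQre) * CO)
}

#' @export
print.dapa_physiology <- function(x, ...) {
  cat(sprintf("<physiology> BW %.1f kg, CO %.1f L/h, GFR %.2f L/h\n",
              x$BW, x$CO, x$GFR_ref * x$f_renal))
  cat(sprintf("  renal %s (f_renal %.2f), hepatic %s (f_cirrhosis %.2f), %s (f_absorption %.2f)\n",
              x$renal_class, x$f_renal, x$hepatic_class, x$f_cirrhosis,
              x$prandial, x$f_absorption))
  cat(sprintf("  FPG %.2f mM (%s)\n", x$FPG, x$population))
  invisible(x)
}
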
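# ODE core: whole-body disposition of DAP and D3G plus the cumulative
# urinary-glucose state. The system is defined once, symbolically, in
# .ode_equations(); build_rhs() compiles it into a derivative function for
# deSolve and export_sbml() translates the same expressions to MathML.

# The integrated state carries only drug mass. Urinary glucose excretion
# is a pure readout of the DAP plasma profile (no feedback on PK), so it is
# accumulated by quadrature after integration; this makes the PK/PD
# decoupling structural -- trajectories are bit-identical for any FPG.
.state_names <- c(
  "DAP_lumen",          # absorbable oral dose in gut lumen, umol
  "DAP_feces_transit",  # non-absorbable split in transit, umol
  "DAP_feces",          # cumulative fecal DAP, umol
  "DAP_gu", "DAP_li", "DAP_ki", "DAP_lu", "DAP_re", "DAP_bl",  # tissues, umol
  "DAP_urine",          # cumulative unchanged DAP in urine, umol
  "D3G_bl", "D3G_ki",   # metabolite, umol
  "D3G_urine"           # cumulative D3G in urine, umol
)

# all states carry DAP-equivalents
.mass_states <- .state_names

# Algebraic intermediates, evaluated in order, then the time derivative of
# every state. All symbols are either states, parameters (see
# ode_parameter_vector) or earlier intermediates.
.ode_equations <- function() {
  aux <- c(
    C_bl   = "DAP_bl / Vbl",
    C_gu   = "DAP_gu / Vgu",
    C_li   = "DAP_li / Vli",
    C_ki   = "DAP_ki / Vki",
    C_lu   = "DAP_lu / Vlu",
    C_re   = "DAP_re / Vre",
    C3_bl  = "D3G_bl / Vbl",
    C3_ki  = "D3G_ki / Vki",
    abs_flux  = "ka * f_absorption * DAP_lumen",
    portal_in = "Qha * C_bl + Qgu * C_gu / Kp_DAP + abs_flux",
    v_met_li  = "(1 - f_cirrhosis) * Vmax_li * Vli * C_li / (Km + C_li)",
    v_met_ki  = "Vmax_li * f_ki_Vmax * Vki * C_ki / (Km + C_ki)",
    v_ex_dap  = "k_DAPEX_ki * f_renal * DAP_ki",
    v_ex_d3g  = "k_D3GEX_ki * f_renal * D3G_ki",
    C_dap_ngml = "C_bl * MW_DAP",
    RTG        = "RTG0 * (1 - Imax * C_dap_ngml / (IC50 + C_dap_ngml))",
    uge_mmolh  = "GFR_ref * f_renal * max(0, FPG - RTG)"
  )
  derivs <- c(
    DAP_lumen         = "-abs_flux",
    DAP_feces_transit = "-k_feces * DAP_feces_transit",
    DAP_feces         = "k_feces * DAP_feces_transit",
    DAP_gu = "Qgu * (C_bl - C_gu / Kp_DAP)",
    DAP_li = "(1 - f_cirrhosis) * portal_in - (1 - f_cirrhosis) * Qh * C_li / Kp_DAP - v_met_li",
    DAP_ki = "Qki * (C_bl - C_ki / Kp_DAP) - v_met_ki - v_ex_dap",
    DAP_lu = "Qlu * (C_bl - C_lu / Kp_DAP)",
    DAP_re = "PSre * (C_bl - C_re / Kp_re_DAP)",
    DAP_bl = paste(
      "f_cirrhosis * portal_in + (1 - f_cirrhosis) * Qh * C_li / Kp_DAP",
      "+ Qki * C_ki / Kp_DAP + Qlu * C_lu / Kp_DAP + PSre * C_re / Kp_re_DAP",
      "- (Qha + Qgu + Qki + Qlu) * C_bl - PSre * C_bl"),
    DAP_urine = "v_ex_dap",
    D3G_bl = "v_met_li + Qki * (C3_ki / Kp_D3G - C3_bl)",
    D3G_ki = "Qki * (C3_bl - C3_ki / Kp_D3G) + v_met_ki - v_ex_d3g",
    D3G_urine = "v_ex_d3g"
  )
  # pure quadrature states (no feedback on the mass states); accumulated
  # post hoc by the simulator, exported as rate rules in SBML
  quadrature <- c(UGE_mmol = "uge_mmolh")
  list(aux = aux, derivs = derivs, quadrature = quadrature)
}

#' Derived ODE parameter vector
#'
#' Resolves a physiology / drug-parameter / PD-parameter triple into the
#' flat named constant vector referenced by the model equations (organ
#' volumes and flows in absolute units, scaling factors, kinetic
#' constants).
#'
#' @param phys A `dapa_physiology` object.
#' @param drug A `dapa_drug_params` object.
#' @param pd A `dapa_pd_params` object.
#' @return Named numeric vector.
#' @export
ode_parameter_vector <- function(phys, drug, pd) {
  V <- organ_volumes(phys)
  Q <- organ_flows(phys)
  c(Vgu = V[["gu"]], Vki = V[["ki"]], Vli = V[["li"]], Vlu = V[["lu"]],
    Vbl = V[["bl"]], Vre = V[["re"]],
    Qgu = Q[["gu"]], Qki = Q[["ki"]], Qh = Q[["h"]], Qha = Q[["ha"]],
    Qlu = Q[["lu"]],
    PSre = drug$ps_re * V[["re"]],
    Kp_DAP = drug$Kp_DAP, Kp_re_DAP = drug$Kp_re_DAP, Kp_D3G = drug$Kp_D3G,
    ka = drug$ka, f_absorption = phys$f_absorption,
    f_renal = phys$f_renal, f_cirrhosis = phys$f_cirrhosis,
    Km = drug$Km, Vmax_li = drug$Vmax_li, f_ki_Vmax = drug$f_ki_Vmax,
    k_DAPEX_ki = drug$k_DAPEX_ki, k_D3GEX_ki = drug$k_D3GEX_ki,
    k_feces = drug$k_feces,
    GFR_ref = phys$GFR_ref, FPG = phys$FPG,
    RTG0 = pd$RTG0, Imax = pd$Imax, IC50 = pd$IC50,
    MW_DAP = drug$MW_DAP)
}

#' Build the model vector field
#'
#' Compiles the coupled DAP/D3G mass-transfer system into a derivative
#' function suitable for [deSolve::lsoda()]: first-order absorption from
#' the gut lumen (with the non-absorbable `1 - F_gut` split handled at
#' dosing time), flow-limited organ distribution, irreversible
#' Michaelis-Menten glucuronidation in liver (scaled by `1 - f_cirrhosis`,
#' with the same fraction of portal inflow shunted past the liver) and
#' kidney, first-order urinary excretion of DAP and D3G scaled by
#' `f_renal`, and the renal-threshold glucose excretion state.
#'
#' @inheritParams ode_parameter_vector
#' @return A function `(t, y, parms)` returning `list(dy/dt)`, with
#'   attributes `state_names` and `parameters`.
#' @export
build_rhs <- function(phys, drug, pd = pd_parameters()) {
  stopifnot(inherits(phys, "dapa_physiology"))
  if (!inherits(drug, "dapa_drug_params")) validate_drug_parameters(drug)
  p <- ode_parameter_vector(phys, drug, pd)
  eq <- .ode_equations()
  lines <- c(
    sprintf("%s <- y[%dL]", .state_names, seq_along(.state_names)),
    sprintf("%s <- %s", names(eq$aux), eq$aux),
    sprintf("d_%s <- %s", names(eq$derivs), eq$derivs),
    sprintf("list(c(%s))", paste0("d_", names(eq$derivs), collapse = ", "))
  )
  env <- list2env(as.list(p), parent = asNamespace("dapasim"))
  fn <- eval(parse(text = paste0(
    "function(t, y, parms = NULL) {\n",
    paste(lines, collapse = "\n"), "\n}")), envir = env)
  attr(fn, "state_names") <- .state_names
  attr(fn, "parameters") <- p
  fn
}

#' Michaelis-Menten rate
#'
#' @param C Substrate concentration, uM (>= 0).
#' @param Vmax Maximal rate, umol/h (>= 0).
#' @param Km Michaelis constant, uM (> 0).
#' @return Rate `Vmax * C / (Km + C)`, umol/h.
#' @export
#' @examples
#' mm_rate(479, 10, 479)  # half-saturation: Vmax / 2
mm_rate <- function(C, Vmax, Km) {
  if (any(Km <= 0)) stop("`Km` must be positive", call. = FALSE)
  if (any(C < 0)) stop("`C` must be non-negative", call. = FALSE)
  if (any(Vmax < 0)) stop("`Vmax` must be non-negative", call. = FALSE)
  Vmax * C / (Km + C)
}

#' Molar mass-balance error of a simulated trajectory
#'
#' All model states except the glucose bookkeeping carry DAP-equivalents in
#' umol, so their sum must equal the cumulative administered dose at every
#' output time. Returns the maximum absolute relative deviation (relative
#' to the total administered dose); defined as 0 for a zero-dose run.
#'
#' @param tc A `dapa_timecourse` from [simulate_scenario()].
#' @return Maximum relative balance error (dimensionless).
#' @export
mass_balance <- function(tc) {
  state <- attr(tc, "state")
  admin <- attr(tc, "admin_umol")
  if (is.null(state) || is.null(admin))
    stop("`tc` must be a simulated timecourse carrying its state matrix",
         call. = FALSE)
  total_dose <- max(admin)
  if (total_dose == 0) return(0)
  total <- rowSums(state[, .mass_states, drop = FALSE])
  max(abs(total - admin)) / total_dose
}
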
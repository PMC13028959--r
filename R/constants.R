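#' Molar masses used for unit conversion
#'
#' Named constants (g/mol) for dapagliflozin (DAP), its 3-O-glucuronide
#' (D3G) and glucose. Doses are given in mg, internal state is in umol and
#' plasma concentrations are reported in ng/mL, so every interface crossing
#' goes through these values.
#'
#' @format Named numeric vector of length 3.
#' @export
MOLAR_MASS <- c(dap = 408.87, d3g = 585.03, glucose = 180.16)

# fraction of an oral dose that reaches the absorption chain; the remainder
# (16%) is routed to feces at dosing time
.F_GUT_DEFAULT <- 0.84

`%||%` <- function(a, b) if (is.null(a)) b else a
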
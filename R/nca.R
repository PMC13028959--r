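# Non-compartmental analysis of concentration-time profiles.

# terminal slope: log-linear regression over candidate windows made of the
# last 3..10 points (Tmax excluded), best adjusted R-squared wins, ties go
# to the larger window
.lambda_z <- function(time, conc) {
  i_max <- which.max(conc)
  t_ok <- seq_along(time) > i_max & conc > 0
  times <- time[t_ok]; cs <- conc[t_ok]
  n <- length(cs)
  if (n < 3) return(list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_))
  best <- NULL
  for (k in 3:min(10, n)) {
    idx <- seq(n - k + 1, n)
    fit <- stats::lm(log(cs[idx]) ~ times[idx])
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    # noiseless profiles fit exactly; summary.lm warns about that
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || ar2 >= best$adj_r2 - 1e-12)
      best <- list(lambda_z = -slope, n_points = k, adj_r2 = ar2)
  }
  if (is.null(best))
    return(list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_))
  best
}

#' Area under a concentration-time curve
#'
#' Linear-up/log-down trapezoidal AUC to the last observation, with
#' extrapolation to infinity by `C_last / lambda_z`. When no terminal
#' log-linear phase can be identified (< 3 positive declining points)
#' `auc_inf` is `NA`.
#'
#' @param time Sampling times, h (strictly increasing, >= 3 points).
#' @param conc Concentrations (non-negative).
#' @return List with `auc_0_t`, `auc_inf`, `lambda_z`, `n_points_lambda_z`.
#' @export
#' @examples
#' t <- seq(0, 48, 0.5)
#' nca_auc(t, 100 * exp(-0.1 * t))$auc_inf  # ~1000
nca_auc <- function(time, conc) {
  if (length(time) < 3 || length(time) != length(conc))
    stop("need >= 3 (time, conc) pairs of equal length", call. = FALSE)
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  c1 <- head(conc, -1); c2 <- tail(conc, -1); dt <- diff(time)
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown, (c1 - c2) * dt / log(c1 / c2), (c1 + c2) / 2 * dt)
  auc_0_t <- sum(seg)
  lz <- .lambda_z(time, conc)
  auc_inf <- if (is.finite(lz$lambda_z)) {
    auc_0_t + conc[length(conc)] / lz$lambda_z
  } else if (all(conc == 0)) 0 else NA_real_
  list(auc_0_t = auc_0_t, auc_inf = auc_inf, lambda_z = lz$lambda_z,
       n_points_lambda_z = lz$n_points)
}

#' Terminal half-life
#'
#' `ln(2) / lambda_z`, with the terminal slope from log-linear regression
#' over the best candidate window (see [nca_auc()]).
#'
#' @inheritParams nca_auc
#' @return Half-life, h.
#' @export
nca_half_life <- function(time, conc) {
  lz <- .lambda_z(time, conc)
  if (!is.finite(lz$lambda_z))
    stop("no declining terminal log-linear phase identifiable ",
         "(need >= 3 positive points after Tmax with negative slope)",
         call. = FALSE)
  log(2) / lz$lambda_z
}

#' Urinary and fecal recovery of unchanged drug
#'
#' @param tc A `dapa_timecourse`.
#' @param dose_mg Administered dose; defaults to the scenario's total.
#' @return List with `frac_urine_unchanged` and `frac_feces`, % of dose.
#' @export
excretion_fractions <- function(tc, dose_mg = NULL) {
  sc <- attr(tc, "scenario")
  dose_mg <- dose_mg %||%
    sum(vapply(sc$doses, `[[`, numeric(1), "amount_mg"))
  if (is.null(dose_mg) || !is.finite(dose_mg) || dose_mg <= 0)
    stop("dose is zero or unknown; excretion fractions undefined",
         call. = FALSE)
  list(frac_urine_unchanged = 100 * tc$dap_urine_mg[nrow(tc)] / dose_mg,
       frac_feces = 100 * tc$dap_feces_mg[nrow(tc)] / dose_mg)
}

#' Absolute oral bioavailability
#'
#' Dose-normalised AUC ratio between an oral and an intravenous profile
#' from the same parameterization.
#'
#' @param oral,iv Lists with `auc_inf` and `dose_mg` (e.g. from
#'   [pk_params()]).
#' @return F in %.
#' @export
bioavailability <- function(oral, iv) {
  if (!is.finite(oral$auc_inf) || !is.finite(iv$auc_inf))
    stop("`auc_inf` unavailable for one of the profiles", call. = FALSE)
  100 * (oral$auc_inf / oral$dose_mg) / (iv$auc_inf / iv$dose_mg)
}

#' Non-compartmental PK summary of a simulated timecourse
#'
#' @param tc A `dapa_timecourse`.
#' @param compound `"dap"` or `"d3g"`.
#' @param dose_mg Dose used for dose-normalised quantities; defaults to
#'   the scenario total.
#' @return List with `auc_0_t`, `auc_inf` (ng*h/mL), `cmax` (ng/mL),
#'   `tmax` (h), `thalf` (h), `frac_urine_unchanged` and `frac_feces`
#'   (% of dose; `frac_feces` is `NA` for D3G, which has no fecal route),
#'   and `dose_mg`.
#' @export
pk_params <- function(tc, compound = c("dap", "d3g"), dose_mg = NULL) {
  compound <- match.arg(compound)
  sc <- attr(tc, "scenario")
  dose_mg <- dose_mg %||%
    (if (!is.null(sc)) sum(vapply(sc$doses, `[[`, numeric(1), "amount_mg")))
  conc <- if (compound == "dap") tc$dap_plasma_ngml else tc$d3g_plasma_ngml
  a <- nca_auc(tc$time_h, conc)
  lz <- a$lambda_z
  thalf <- if (is.finite(lz)) log(2) / lz else NA_real_
  urine <- if (compound == "dap") tc$dap_urine_mg else tc$d3g_urine_mg
  frac_urine <- if (!is.null(dose_mg) && dose_mg > 0)
    100 * urine[nrow(tc)] / dose_mg else NA_real_
  frac_feces <- if (compound == "dap" && !is.null(dose_mg) && dose_mg > 0)
    100 * tc$dap_feces_mg[nrow(tc)] / dose_mg else NA_real_
  list(auc_0_t = a$auc_0_t, auc_inf = a$auc_inf,
       cmax = max(conc), tmax = tc$time_h[which.max(conc)],
       thalf = thalf, frac_urine_unchanged = frac_urine,
       frac_feces = frac_feces, dose_mg = dose_mg)
}
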
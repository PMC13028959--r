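# Weighted least-squares calibration: the study-weighted cost function,
# multistart bounded local optimization (sequential PK then PD stages) and
# goodness-of-fit reporting.

.stage_params <- list(
  PK = c("ka", "Vmax_li", "f_ki_Vmax", "k_DAPEX_ki", "k_D3GEX_ki"),
  PD = c("RTG0", "Imax", "IC50")
)

.default_bounds <- list(
  ka = c(0.05, 10), Vmax_li = c(0.1, 1000), f_ki_Vmax = c(0.01, 1000),
  k_DAPEX_ki = c(1e-4, 10), k_D3GEX_ki = c(0.01, 100),
  RTG0 = c(5, 14), Imax = c(0.05, 1), IC50 = c(1, 1000)
)

#' Assemble a study-format dataset
#'
#' @param data Data frame with columns `scenario_id`, `observable` (a
#'   timecourse column name such as `"dap_plasma_ngml"`), `time_h`, `mean`,
#'   `sd` (may be `NA` or 0 for unknown), `n` (group size, >= 1).
#' @param scenarios Named list of `dapa_scenario` objects covering every
#'   `scenario_id`.
#' @return Object of class `dapa_dataset`.
#' @export
study_dataset <- function(data, scenarios) {
  req <- c("scenario_id", "observable", "time_h", "mean", "sd", "n")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(data$n < 1)) stop("group sizes `n` must be >= 1", call. = FALSE)
  unknown <- setdiff(unique(data$scenario_id), names(scenarios))
  if (length(unknown))
    stop("no scenario supplied for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (id in names(scenarios)) {
    tmax <- max(data$time_h[data$scenario_id == id], 0)
    if (tmax > scenarios[[id]]$t_end_h + 1e-9)
      stop(sprintf("data for '%s' extend beyond the scenario horizon", id),
           call. = FALSE)
  }
  structure(data, class = c("dapa_dataset", "data.frame"),
            scenarios = scenarios)
}

# substitute a named parameter vector (PK names -> drug block, PD names ->
# pd block) into a scenario
.scenario_with_params <- function(sc, par) {
  for (nm in names(par)) {
    block <- if (nm %in% .stage_params$PK) "drug" else
             if (nm %in% .stage_params$PD) "pd" else
             stop(sprintf("unknown fitted parameter '%s'", nm), call. = FALSE)
    sc[[block]][[nm]] <- unname(par[[nm]])
  }
  sc
}

# per-point weights n/sigma; non-positive or missing sigma falls back to
# the median sigma of its timecourse; a series entirely without
# uncertainties gets a scale-aware default of 10% of its median magnitude
# so differently-scaled observables contribute comparably
.point_weights <- function(data) {
  sigma <- data$sd
  sigma[!is.finite(sigma) | sigma <= 0] <- NA
  key <- paste(data$scenario_id, data$observable)
  med <- tapply(sigma, key, stats::median, na.rm = TRUE)
  fill <- med[key]
  scale_med <- tapply(abs(data$mean), key, function(x) {
    pos <- x[x > 0]
    if (length(pos)) stats::median(pos) else 10
  })
  fallback <- 0.1 * scale_med[key]
  fill[!is.finite(fill)] <- fallback[!is.finite(fill)]
  sigma[is.na(sigma)] <- fill[is.na(sigma)]
  data$n / sigma
}

# model predictions at every data point for a parameter vector
.predict_dataset <- function(par, dataset, rtol = 1e-6, atol = rtol / 100) {
  scenarios <- attr(dataset, "scenarios")
  pred <- numeric(nrow(dataset))
  for (id in unique(dataset$scenario_id)) {
    rows <- which(dataset$scenario_id == id)
    sc <- .scenario_with_params(scenarios[[id]], par)
    tt <- sort(unique(c(0, dataset$time_h[rows])))
    sc$output_grid <- tt
    tc <- simulate_scenario(sc, rtol = rtol, atol = atol)
    for (obs in unique(dataset$observable[rows])) {
      r2 <- rows[dataset$observable[rows] == obs]
      if (!obs %in% names(tc))
        stop(sprintf("unknown observable '%s'", obs), call. = FALSE)
      pred[r2] <- tc[[obs]][match(dataset$time_h[r2], tc$time_h)]
    }
  }
  pred
}

#' Weighted least-squares cost
#'
#' `F(p) = 1/2 * sum_ik w_ik * r_ik^2` with residuals
#' `r = prediction - observed mean`, weighted by `w_ik = n_k / sigma_ik`
#' (group size over per-point standard deviation). A failed simulation
#' yields a large finite penalty.
#'
#' @param par Named numeric vector of fitted parameters (PK and/or PD
#'   names, see [multistart_fit()]).
#' @param dataset A `dapa_dataset`.
#' @param rtol Integration tolerance used during fitting.
#' @return The scalar cost F.
#' @export
#' @examples
#' # a single point with n = 10, sd = 2 and residual 1 contributes
#' # 0.5 * (10 / 2) * 1^2 = 2.5
cost_function <- function(par, dataset, rtol = 1e-6) {
  w <- .point_weights(dataset)
  pred <- tryCatch(.predict_dataset(par, dataset, rtol = rtol),
                   error = function(e) NULL)
  if (is.null(pred)) return(1e12)
  r <- pred - dataset$mean
  0.5 * sum(w * r^2)
}

#' Multistart weighted least-squares fit
#'
#' Draws `n_starts` starting points log-uniformly within the bounds (seeded)
#' and runs a bounded Levenberg-Marquardt least-squares optimization
#' ([minpack.lm::nls.lm()] on log-transformed parameters) from each.
#' Stages are fitted sequentially: `"PK"` estimates
#' ka, Vmax_li, f_ki_Vmax, k_DAPEX_ki, k_D3GEX_ki; `"PD"` estimates
#' RTG0, Imax, IC50 with the PK parameters held at the values baked into
#' the dataset's scenarios (or supplied via `fixed`).
#'
#' @param dataset A `dapa_dataset`.
#' @param stage `"PK"` or `"PD"`.
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults
#'   are physiologic.
#' @param n_starts Number of starting points.
#' @param seed Integer seed for the start draws.
#' @param fixed Optional named vector of parameters held fixed (e.g. the
#'   PK estimate during the PD stage).
#' @param rtol Integration tolerance during fitting.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return Object of class `dapa_fit`: `par` (best parameters, natural
#'   scale), `cost`, `run_costs` (all starts, sorted by start index),
#'   `starts`, `bounds`, `stage`, `seed` and `gof` (per-timecourse R^2 and
#'   RMSE at the optimum).
#' @export
multistart_fit <- function(dataset, stage = c("PK", "PD"), bounds = NULL,
                           n_starts = 100, seed = 1, fixed = NULL,
                           rtol = 1e-6, maxiter = 50) {
  stage <- match.arg(stage)
  pnames <- .stage_params[[stage]]
  bounds <- bounds %||% .default_bounds[pnames]
  if (!all(pnames %in% names(bounds)))
    stop("bounds missing for: ",
         paste(setdiff(pnames, names(bounds)), collapse = ", "), call. = FALSE)
  lo <- log(vapply(bounds[pnames], `[[`, numeric(1), 1))
  hi <- log(vapply(bounds[pnames], `[[`, numeric(1), 2))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("bounds must be finite, positive and ordered", call. = FALSE)
  w <- .point_weights(dataset)
  sw <- sqrt(w)
  m <- nrow(dataset)
  resid_fn <- function(lp) {
    par <- stats::setNames(exp(lp), pnames)
    pred <- tryCatch(.predict_dataset(c(par, fixed), dataset, rtol = rtol),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, m))
    sw * (pred - dataset$mean)
  }
  starts <- .with_seed(seed, {
    matrix(stats::runif(n_starts * length(pnames), rep(lo, each = n_starts),
                        rep(hi, each = n_starts)),
           nrow = n_starts, dimnames = list(NULL, pnames))
  })
  fobj <- function(lp) { r <- resid_fn(lp); 0.5 * sum(r^2) }
  runs <- vector("list", n_starts)
  for (j in seq_len(n_starts)) {
    runs[[j]] <- tryCatch({
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = starts[j, ], fn = resid_fn, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = maxiter)))
      list(par = exp(fit$par), cost = 0.5 * fit$deviance,
           converged = fit$info %in% 1:4)
    }, error = function(e) list(par = exp(starts[j, ]), cost = Inf,
                                converged = FALSE))
  }
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  if (all(!is.finite(costs)))
    stop("all optimization starts failed", call. = FALSE)
  # The weighted least-squares surface has long, ill-conditioned valleys
  # (e.g. hepatic vs renal Vmax trade-off) on which Levenberg-Marquardt
  # stalls prematurely. Polish the leading runs by alternating simplex and
  # LM steps until the cost stops improving.
  for (j in utils::head(order(costs), 3L)) {
    lp <- log(runs[[j]]$par)
    cost <- costs[j]
    for (cycle in 1:4) {
      nm <- tryCatch(stats::optim(lp, fobj, method = "Nelder-Mead",
                                  control = list(maxit = 400,
                                                 reltol = 1e-14)),
                     error = function(e) NULL)
      if (!is.null(nm)) lp <- pmin(pmax(nm$par, lo), hi)
      f2 <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
        lp, fn = resid_fn, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-14,
                                             ptol = 1e-14))),
        error = function(e) NULL)
      if (!is.null(f2) && 0.5 * f2$deviance <= cost) {
        lp <- f2$par
        new_cost <- 0.5 * f2$deviance
      } else new_cost <- fobj(lp)
      improved <- cost - new_cost > 1e-10 * (1 + cost)
      cost <- min(cost, new_cost)
      if (!improved) break
    }
    if (cost < costs[j]) {
      runs[[j]]$par <- exp(lp)
      runs[[j]]$cost <- cost
      costs[j] <- cost
    }
  }
  best <- runs[[which.min(costs)]]
  par <- stats::setNames(best$par, pnames)
  structure(list(par = par, cost = best$cost, run_costs = costs,
                 starts = exp(starts), bounds = bounds, stage = stage,
                 seed = seed, fixed = fixed,
                 converged = best$converged,
                 gof = goodness_of_fit(c(par, fixed), dataset, rtol = rtol)),
            class = "dapa_fit")
}

#' Goodness of fit per timecourse
#'
#' Standard coefficient of determination and root-mean-square error per
#' (scenario, observable) series plus an aggregate row. R^2 is undefined
#' (`NA`, with a warning) for zero-variance observation series.
#'
#' @param par Named parameter vector (or a `dapa_fit`, whose best
#'   parameters are used).
#' @param dataset A `dapa_dataset`.
#' @param rtol Integration tolerance.
#' @return Data frame with columns `scenario_id`, `observable`, `n_points`,
#'   `r2`, `rmse`.
#' @export
goodness_of_fit <- function(par, dataset, rtol = 1e-6) {
  if (inherits(par, "dapa_fit")) par <- c(par$par, par$fixed)
  pred <- .predict_dataset(par, dataset, rtol = rtol)
  key <- interaction(dataset$scenario_id, dataset$observable, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- key == k
    obs <- dataset$mean[i]
    ss_tot <- sum((obs - mean(obs))^2)
    ss_res <- sum((pred[i] - obs)^2)
    r2 <- if (ss_tot == 0) { warning("zero-variance series: R^2 undefined");
                             NA_real_ } else 1 - ss_res / ss_tot
    data.frame(scenario_id = dataset$scenario_id[i][1],
               observable = dataset$observable[i][1],
               n_points = sum(i), r2 = r2,
               rmse = sqrt(mean((pred[i] - obs)^2)))
  })
  out <- do.call(rbind, rows)
  agg_tot <- sum((dataset$mean - mean(dataset$mean))^2)
  out <- rbind(out, data.frame(
    scenario_id = "(all)", observable = "(all)", n_points = nrow(dataset),
    r2 = if (agg_tot == 0) NA_real_ else
      1 - sum((pred - dataset$mean)^2) / agg_tot,
    rmse = sqrt(mean((pred - dataset$mean)^2))))
  out
}

#' @export
print.dapa_fit <- function(x, ...) {
  cat(sprintf("<%s fit> best cost F = %.6g over %d starts (%d finite)\n",
              x$stage, x$cost, length(x$run_costs),
              sum(is.finite(x$run_costs))))
  print(signif(x$par, 5))
  invisible(x)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
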
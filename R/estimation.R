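# Naive-pooled estimation of PBPK parameters against observed concentration
# tables, and fold-error predictive-performance metrics (AFE/AAFE).

#' Average fold error
#'
#' `AFE = 10^(mean(log10(pred/obs)))` — the geometric-mean prediction bias.
#' AFE of 1 means no bias; values within `[0.5, 2]` are the conventional
#' 2-fold acceptance band.
#'
#' @param pred,obs paired positive vectors of equal length.
#' @return scalar AFE.
#' @export
afe <- function(pred, obs) {
  .check_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10(pred/obs)|))` — the geometric-mean absolute fold
#' deviation (precision). Always `>= max(AFE, 1/AFE) >= 1`.
#'
#' @inheritParams afe
#' @export
aafe <- function(pred, obs) {
  .check_pairs(pred, obs)
  10^mean(abs(log10(pred / obs)))
}

.check_pairs <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 1) {
    stop("pred and obs must be paired vectors of equal length >= 1")
  }
  if (any(!is.finite(pred)) || any(!is.finite(obs)) ||
      any(pred <= 0) || any(obs <= 0)) {
    stop("fold errors require strictly positive finite values")
  }
  invisible(TRUE)
}

#' Specification of a PBPK fit
#'
#' Free parameters are addressed by path into the parameter object, e.g.
#' `"tissues.liver.Kup"`, `"tissues.spleen.PS"`, `"systemic.Pgt"`.
#' Optimisation runs on the log scale (all these parameters are positive
#' rates, coefficients or ratios), so bounds are diagnostics, not hard
#' constraints.
#'
#' @param free named numeric vector of initial values, names being parameter
#'   paths.
#' @param lower,upper optional named bounds (same names as `free`).
#' @param objective `"log_sse"` (default; residuals on log concentrations,
#'   matching the fold-error validation metrics) or `"sse"`.
#' @return a `fit_spec` list.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL,
                     objective = c("log_sse", "sse")) {
  objective <- match.arg(objective)
  stopifnot(is.numeric(free), !is.null(names(free)), all(free > 0))
  if (!is.null(lower) && any(free < lower[names(free)], na.rm = TRUE) ||
      !is.null(upper) && any(free > upper[names(free)], na.rm = TRUE)) {
    stop("initial values must lie within bounds")
  }
  structure(list(free = free, lower = lower, upper = upper,
                 objective = objective),
            class = "fit_spec")
}

# get/set a parameter by "a.b.c" path, revalidating the object on set
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- params
  for (p in parts) {
    v <- v[[p]]
    if (is.null(v)) stop("no parameter at path '", path, "'")
  }
  v
}

param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts,
                 quote(params))
  eval(call("<-", expr, value))
  # re-derive dependent volumes, then revalidate through the constructors
  tis <- lapply(params$tissues, function(ti) {
    tissue_params(ti$name, ti$Q, ti$V_total, ti$f_vasc, ti$PS, ti$P, ti$Kup)
  })
  s <- params$systemic
  sys <- systemic_params(s$Qp, s$Cl, s$Vd_per_kg, s$BW, s$Pgt, s$Kup_plasma)
  pbpk_parameters(sys, tis, params$formulation, params$group_label)
}

# pooled objective: residuals between model predictions and the pooled
# profile of each requested tissue (profiles pooled once, upstream)
.fit_objective <- function(theta_log, base, paths, pools, dose,
                           objective, include_carrier_bound, rtol) {
  p <- base
  for (i in seq_along(paths)) {
    p <- tryCatch(param_set(p, paths[i], exp(theta_log[i])),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
  }
  all_times <- sort(unique(unlist(lapply(pools, `[[`, "time_h"))))
  traj <- tryCatch(
    simulate_pbpk(p, dose, output_times = c(0, all_times), rtol = rtol,
                  atol = 1e-6),
    error = function(e) NULL)
  if (is.null(traj)) return(1e10)
  total <- 0
  for (ts in names(pools)) {
    pool <- pools[[ts]]
    pred <- predicted_concentration(traj, ts, include_carrier_bound)
    pred_at <- pred[match(pool$time_h, traj$times)]
    if (any(is.na(pred_at))) return(1e10)
    r <- if (objective == "log_sse") {
      if (any(pred_at <= 0) || any(pool$conc <= 0)) return(1e10)
      log(pred_at) - log(pool$conc)
    } else {
      pred_at - pool$conc
    }
    total <- total + sum(r^2)
  }
  total
}

#' Naive-pooled PBPK parameter estimation
#'
#' Pools all animals of the group, then minimises the squared-residual
#' objective between model-predicted assay concentrations (see
#' [predicted_concentration()]) and the pooled profiles over the free
#' parameters, with the BFGS quasi-Newton optimiser on log-transformed
#' parameters.  By default each observed tissue contributes to the
#' objective; restrict `tissues` for the per-tissue sequential strategy
#' (each tissue's `Kup`/`PS` against that tissue's own profile, `Pgt`
#' against plasma).
#'
#' @param obs an [observation_table()] for one group.
#' @param base a `pbpk_parameters` object holding every fixed parameter.
#' @param spec a [fit_spec()].
#' @param dose the group [dose_spec()].
#' @param tissues tissues whose profiles enter the objective; default every
#'   tissue present in `obs`.
#' @param include_carrier_bound predictions include carrier-bound drug
#'   (default `TRUE`).
#' @param rtol solver tolerance used inside the objective.
#' @return list with `params` (fitted object), `estimates` (named vector),
#'   `objective`, `convergence` (0 = converged), `counts`, and `spec`.
#' @export
fit_pbpk <- function(obs, base, spec, dose, tissues = NULL,
                     include_carrier_bound = TRUE, rtol = 1e-8) {
  stopifnot(inherits(obs, "observation_table"),
            inherits(base, "pbpk_parameters"), inherits(spec, "fit_spec"),
            inherits(dose, "dose_spec"))
  if (length(unique(obs$group)) != 1) {
    stop("fit one formulation group at a time")
  }
  if (is.null(tissues)) tissues <- unique(obs$tissue)
  paths <- names(spec$free)
  for (pa in paths) param_get(base, pa)  # fail early on bad paths
  group <- unique(obs$group)[1]
  pools <- lapply(tissues, function(ts) pool_by_time(obs, ts, group))
  names(pools) <- tissues
  if (length(paths) == 0 || length(spec$free) == 0) {
    val <- .fit_objective(numeric(0), base, character(0), pools, dose,
                          spec$objective, include_carrier_bound, rtol)
    return(list(params = base, estimates = numeric(0), objective = val,
                convergence = 0, counts = c(0, 0), spec = spec))
  }
  for (ts in tissues) {
    if (nrow(pools[[ts]]) < 2) {
      stop("tissue '", ts, "' has fewer than 2 observed times")
    }
  }
  par0 <- log(spec$free)
  # a derivative-free pre-search makes the quasi-Newton polish robust to the
  # flat/noisy regions a distant initial estimate has to cross: a coarse
  # log-scale scan around the initial value for one parameter, Nelder-Mead
  # for several
  obj1 <- function(th) {
    .fit_objective(th, base, paths, pools, dose, spec$objective,
                   include_carrier_bound, rtol)
  }
  if (length(par0) == 1) {
    cand <- par0 + log(10) * seq(-3, 1, by = 0.5)
    vals <- vapply(cand, obj1, numeric(1))
    par0 <- cand[which.min(vals)]
  } else {
    pre <- optim(par = par0, fn = obj1, method = "Nelder-Mead",
                 control = list(maxit = 500))
    par0 <- pre$par
  }
  opt <- optim(
    par = par0,
    fn = .fit_objective, method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12),
    base = base, paths = paths, pools = pools, dose = dose,
    objective = spec$objective,
    include_carrier_bound = include_carrier_bound, rtol = rtol)
  if (opt$convergence != 0) {
    stop("BFGS did not converge (code ", opt$convergence, "): ",
         if (is.null(opt$message)) "" else opt$message)
  }
  est <- setNames(exp(opt$par), paths)
  if (!is.null(spec$lower) || !is.null(spec$upper)) {
    at_lo <- !is.null(spec$lower) &
      est <= spec$lower[paths] * (1 + 1e-6)
    at_hi <- !is.null(spec$upper) &
      est >= spec$upper[paths] * (1 - 1e-6)
    if (any(at_lo | at_hi, na.rm = TRUE)) {
      warning("estimate at bound: ",
              paste(paths[which(at_lo | at_hi)], collapse = ", "))
    }
  }
  fitted_params <- base
  for (i in seq_along(paths)) {
    fitted_params <- param_set(fitted_params, paths[i], est[[i]])
  }
  list(params = fitted_params, estimates = est, objective = opt$value,
       convergence = opt$convergence, counts = opt$counts, spec = spec)
}

#' Validate model predictions against observations
#'
#' Pairs every above-LOQ observation with the model prediction at its nominal
#' time (the trajectory must contain those times) and reports per-tissue AFE
#' and AAFE, the overall correlation of log observed vs log predicted, and a
#' per-tissue flag for AFE within the 2-fold band `[0.5, 2]` (inclusive).
#'
#' @param traj a `pbpk_trajectory` simulated with the group's parameters.
#' @param obs an [observation_table()] for the same group.
#' @param include_carrier_bound see [predicted_concentration()].
#' @return a `validation_report`: data.frame `per_tissue` (tissue, AFE, AAFE,
#'   n_pairs, pass_afe), scalar `correlation`, and the paired table `pairs`.
#' @export
validate_predictions <- function(traj, obs, include_carrier_bound = TRUE) {
  stopifnot(inherits(traj, "pbpk_trajectory"),
            inherits(obs, "observation_table"))
  obs <- obs[!obs$below_loq & obs$conc > 0, ]
  tissues <- unique(obs$tissue)
  rows <- list(); pairs <- list()
  for (ts in tissues) {
    sub <- obs[obs$tissue == ts, ]
    idx <- match(sub$time_h, traj$times)
    if (any(is.na(idx))) {
      stop("trajectory does not cover observation times for '", ts, "'")
    }
    pred <- predicted_concentration(traj, ts, include_carrier_bound)[idx]
    ok <- pred > 0
    if (!any(ok)) next  # tissue reported absent, not failing
    a <- afe(pred[ok], sub$conc[ok])
    rows[[ts]] <- data.frame(
      tissue = ts, AFE = a, AAFE = aafe(pred[ok], sub$conc[ok]),
      n_pairs = sum(ok), pass_afe = a >= 0.5 & a <= 2)
    pairs[[ts]] <- data.frame(tissue = ts, time_h = sub$time_h[ok],
                              observed = sub$conc[ok], predicted = pred[ok])
  }
  if (!length(rows)) stop("no pairable above-LOQ data")
  pairs <- do.call(rbind, pairs)
  structure(
    list(per_tissue = do.call(rbind, rows),
         correlation = if (nrow(pairs) >= 3)
           cor(log(pairs$observed), log(pairs$predicted)) else NA_real_,
         pairs = pairs),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$per_tissue, row.names = FALSE, digits = 4)
  cat(sprintf("  overall log obs-pred correlation: %.3f (n = %d)\n",
              x$correlation, nrow(x$pairs)))
  invisible(x)
}

#' Write a validation report CSV (indices x tissues layout)
#' @param report a `validation_report`.
#' @param path output CSV path.
#' @export
write_validation_report <- function(report, path) {
  pt <- report$per_tissue
  wide <- data.frame(index = c("AFE", "AAFE"))
  for (i in seq_len(nrow(pt))) {
    wide[[pt$tissue[i]]] <- c(pt$AFE[i], pt$AAFE[i])
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
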
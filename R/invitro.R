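# In vitro kinetics: carrier drug-release profiles (percentage released vs
# time) and macrophage uptake profiles (percentage internalised vs time),
# fitted by nonlinear least squares with small-sample AIC model selection.

#' In vitro kinetic dataset
#'
#' @param times sampling times, h; non-negative and strictly increasing.
#' @param response percentage response (release: % of loaded drug released;
#'   uptake: % of added drug internalised).
#' @param condition_label free text (e.g. the buffer pH).
#' @return a `kinetic_dataset` list.
#' @export
kinetic_dataset <- function(times, response, condition_label = "") {
  stopifnot(length(times) == length(response))
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(response < 0) || any(response > 120)) {
    stop("responses must lie in [0, 100] (plus a small noise allowance)")
  }
  structure(list(times = as.numeric(times), response = as.numeric(response),
                 condition_label = condition_label),
            class = "kinetic_dataset")
}

#' First-order cumulative release fraction
#'
#' `F(t) = 1 - exp(-Krel t)`: the fraction of carrier-bound drug released by
#' time `t` under first-order release kinetics.
#'
#' @param Krel release rate constant, 1/h (> 0).
#' @param t time, h (>= 0); vectorised.
#' @return fraction in `[0, 1]`.
#' @export
release_fraction <- function(Krel, t) {
  stopifnot(is.finite(Krel), Krel > 0)
  if (any(t < 0)) stop("t must be non-negative")
  1 - exp(-Krel * t)
}

# Gaussian-residual AIC with small-sample correction (AICc).
# k counts the mean-model parameters plus the residual variance.  When the
# correction denominator vanishes (n = k + 1, possible at the sparse in vitro
# designs) the uncorrected AIC is used instead of an unusable infinity.
.aicc <- function(rss, n, n_par) {
  k <- n_par + 1
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else aic
}

.kinetic_models <- list(
  zero_order = list(
    n_par = 1,
    fit = function(t, y) {
      f <- lm(y ~ 0 + t)
      k0 <- unname(coef(f)[1])
      if (!is.finite(k0) || k0 <= 0) stop("zero-order slope not positive")
      list(pars = c(rate_constant = k0), plateau = NA_real_,
           fitted = pmin(k0 * t, 100))
    }),
  first_order = list(
    n_par = 1,
    fit = function(t, y) {
      start <- .fo_start(t, y, fixed_plateau = 100)
      f <- minpack.lm::nlsLM(y ~ 100 * (1 - exp(-k * t)),
                             start = list(k = unname(start["k"])),
                             lower = c(k = 1e-8),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      k <- unname(coef(f)["k"])
      list(pars = c(rate_constant = k), plateau = 100,
           fitted = fitted(f))
    }),
  first_order_plateau = list(
    n_par = 2,
    fit = function(t, y) {
      start <- .fo_start(t, y)
      f <- minpack.lm::nlsLM(y ~ umax * (1 - exp(-k * t)),
                             start = list(umax = unname(start["umax"]), k = unname(start["k"])),
                             lower = c(umax = 1e-6, k = 1e-8),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- coef(f)
      list(pars = c(rate_constant = unname(co["k"])),
           plateau = unname(co["umax"]), fitted = fitted(f))
    }),
  # burst + sustained first-order release: F(t) = B + (100 - B)(1 - e^{-kt})
  first_order_burst = list(
    n_par = 2,
    fit = function(t, y) {
      b0 <- max(min(y[t == min(t)], 90), 0)
      start <- .fo_start(t, pmax(y - b0, 0.1), fixed_plateau = 100 - b0)
      f <- minpack.lm::nlsLM(y ~ b + (100 - b) * (1 - exp(-k * t)),
                             start = list(b = b0, k = unname(start["k"])),
                             lower = c(b = 0, k = 1e-8),
                             upper = c(b = 100, k = Inf),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- coef(f)
      list(pars = c(rate_constant = unname(co["k"]), burst = unname(co["b"])),
           plateau = 100, fitted = fitted(f))
    }))

# starting values for saturating-exponential fits, from the log-linear
# transform of the approach to the plateau
.fo_start <- function(t, y, fixed_plateau = NULL) {
  umax <- if (is.null(fixed_plateau)) max(y) * 1.05 else fixed_plateau
  frac <- pmin(pmax(1 - y / umax, 1e-6), 1)
  pos <- t > 0
  k <- if (any(pos)) {
    max(-unname(coef(lm(log(frac[pos]) ~ 0 + t[pos]))[1]), 1e-4)
  } else 0.1
  c(umax = max(y), k = k)
}

.fit_one_kinetic <- function(data, model_name) {
  spec <- .kinetic_models[[model_name]]
  if (is.null(spec)) stop("unknown kinetic model '", model_name, "'")
  t <- data$times; y <- data$response
  n <- length(t)
  if (n < spec$n_par + 1) {
    stop("model '", model_name, "' has ", spec$n_par,
         " parameter(s) but only ", n, " data point(s)")
  }
  res <- spec$fit(t, y)
  rss <- sum((y - res$fitted)^2)
  structure(
    list(model_name = model_name,
         rate_constant = unname(res$pars["rate_constant"]),
         pars = res$pars, plateau = res$plateau,
         residual_sum_squares = rss,
         AIC = .aicc(max(rss, 1e-300), n, spec$n_par),
         n_points = n, fitted = res$fitted,
         residuals = y - res$fitted),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: rate = %.5g per h%s  RSS = %.4g  AICc = %.4g (n = %d)\n",
              x$model_name, x$rate_constant,
              if (!is.na(x$plateau)) sprintf("  plateau = %.4g%%", x$plateau) else "",
              x$residual_sum_squares, x$AIC, x$n_points))
  invisible(x)
}

#' Fit candidate release models and select by goodness of fit
#'
#' Fits each candidate to the cumulative release profile by least squares on
#' the untransformed percentages and selects the smallest small-sample AIC.
#' Candidates: `zero_order` `F(t) = k0 t` (capped at 100),
#' `first_order` `F(t) = 100 (1 - exp(-Krel t))`, and optionally
#' `first_order_burst` `F(t) = B + (100 - B)(1 - exp(-Krel t))` for profiles
#' with an initial burst.
#'
#' @param data a [kinetic_dataset()] with at least 3 time points.
#' @param candidates character vector of model names.
#' @return list with `best` (the selected `kinetic_fit`) and `fits` (all
#'   candidates that converged).
#' @export
fit_release <- function(data, candidates = c("first_order", "zero_order")) {
  stopifnot(inherits(data, "kinetic_dataset"))
  if (length(data$times) < 3) stop("need at least 3 time points")
  fits <- list()
  for (m in candidates) {
    f <- tryCatch(.fit_one_kinetic(data, m), error = function(e) e)
    if (!inherits(f, "error")) fits[[m]] <- f
  }
  if (!length(fits)) stop("no candidate release model could be fitted")
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  list(best = fits[[which.min(aics)]], fits = fits)
}

#' Fit an uptake kinetic model
#'
#' Carrier-bound drug is internalised by macrophages with saturating
#' first-order kinetics, `U(t) = U_max (1 - exp(-Kup t))`; free drug in
#' solution enters far more slowly, adequately described by a zero-order
#' slope `U(t) = k0 t`.  The fitted rate constant is the quantity carried
#' into the PBPK model.
#'
#' @param data a [kinetic_dataset()] with at least 3 points and a non-trivial
#'   response.
#' @param mode `"first_order"` or `"zero_order"`.
#' @return a `kinetic_fit`.
#' @export
fit_uptake <- function(data, mode = c("first_order", "zero_order")) {
  stopifnot(inherits(data, "kinetic_dataset"))
  mode <- match.arg(mode)
  if (length(data$times) < 3) stop("need at least 3 time points")
  if (all(data$response == 0)) {
    stop("degenerate dataset: all responses are zero, no kinetics to fit")
  }
  model <- if (mode == "first_order") "first_order_plateau" else "zero_order"
  f <- .fit_one_kinetic(data, model)
  f$model_name <- mode
  f
}

#' Write a kinetic fit report as JSON
#' @param fit a `kinetic_fit` (or the list returned by [fit_release()]).
#' @param path output path.
#' @export
write_kinetic_report <- function(fit, path) {
  strip <- function(f) f[c("model_name", "rate_constant", "plateau",
                           "residual_sum_squares", "AIC", "n_points")]
  rep <- if (inherits(fit, "kinetic_fit")) strip(fit) else {
    list(selected = strip(fit$best), candidates = lapply(fit$fits, strip))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
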
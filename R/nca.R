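# Model-independent (non-compartmental) analysis: trapezoid AUC/AUMC with
# log-linear terminal-phase extrapolation, on naive-pooled destructive
# sampling data.

#' Linear trapezoid area under a sampled curve
#' @param t,y sampled times (strictly increasing) and values.
#' @return scalar area.
#' @export
auc_trapz <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2, all(diff(t) > 0))
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Terminal log-linear rate constant
#'
#' Unweighted linear regression of `log(y)` on `t` over a terminal window.
#' When `n_tail` is given, the last `n_tail` positive points are used.
#' Otherwise the window is chosen by the standard best-adjusted-R2 rule:
#' every candidate window ends at the last point, starts strictly after the
#' observed maximum, and has at least 3 points; ties (within 1e-4) go to the
#' window with more points.
#'
#' @param t,y concentration-time samples; non-positive `y` are excluded.
#' @param n_tail optional fixed number of terminal points.
#' @return list with `lambda_z` (1/h), `intercept` (log scale), `n_points`,
#'   `adj_r2`, and the window `t_first`/`t_last`.
#' @export
lambda_z_fit <- function(t, y, n_tail = NULL) {
  keep <- is.finite(y) & y > 0
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 3) stop("need at least 3 positive concentrations for lambda_z")
  fit_window <- function(idx) {
    f <- lm(log(y[idx]) ~ t[idx])
    m <- length(idx)
    ly <- log(y[idx])
    rss <- sum(f$residuals^2)
    tss <- sum((ly - mean(ly))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    adj <- if (m > 2) 1 - (1 - r2) * (m - 1) / (m - 2) else r2
    list(lambda_z = -unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         n_points = m, adj_r2 = adj,
         t_first = t[idx[1]], t_last = t[idx[length(idx)]])
  }
  if (!is.null(n_tail)) {
    n_tail <- min(n_tail, n)
    if (n_tail < 3) stop("n_tail must be >= 3")
    return(fit_window(seq(n - n_tail + 1, n)))
  }
  i_max <- which.max(y)
  starts <- seq(i_max + 1, n - 2)
  if (i_max >= n - 1 || length(starts) == 0) {
    starts <- n - 2  # profile peaks at/near the end; fall back to last 3
  }
  fits <- lapply(starts, function(s) fit_window(seq(s, n)))
  score <- vapply(fits, `[[`, numeric(1), "adj_r2")
  npts <- vapply(fits, `[[`, numeric(1), "n_points")
  best <- which(score > max(score) - 1e-4)
  fits[[best[which.max(npts[best])]]]
}

#' AUC to infinity by trapezoid plus terminal extrapolation
#'
#' `AUC_inf = AUC(0..t_last) + C_last / lambda_z`.  With a mono-exponential
#' tail the extrapolated term is exact, which is what makes AUC-ratio
#' partition-coefficient estimates insensitive to the truncation horizon.
#'
#' @inheritParams lambda_z_fit
#' @return list with `auc_last`, `auc_inf`, `lambda_z`, `extrapolated_fraction`.
#' @export
auc_infinity <- function(t, y, n_tail = NULL) {
  auc_last <- auc_trapz(t, y)
  lz <- lambda_z_fit(t, y, n_tail = n_tail)
  if (lz$lambda_z <= 0) stop("non-positive terminal slope; cannot extrapolate")
  c_last <- tail(y[y > 0], 1)
  auc_inf <- auc_last + c_last / lz$lambda_z
  list(auc_last = auc_last, auc_inf = auc_inf, lambda_z = lz$lambda_z,
       extrapolated_fraction = 1 - auc_last / auc_inf)
}

#' AUC of one trajectory state
#'
#' @param traj a `pbpk_trajectory`.
#' @param state a state name, or a numeric series over `traj$times`.
#' @param extrapolate add the terminal `C_last/lambda_z` tail (default);
#'   `FALSE` gives the truncated trapezoid area.
#' @param n_tail number of terminal points for the slope fit; default the
#'   points in the last 10 percent of the horizon (at least 10).
#' @return scalar AUC, ng*h/mL.
#' @export
trajectory_auc <- function(traj, state, extrapolate = TRUE, n_tail = NULL) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  y <- if (is.character(state)) trajectory_state(traj, state) else state
  if (!extrapolate) return(auc_trapz(traj$times, y))
  if (is.null(n_tail)) {
    n_tail <- max(10, sum(traj$times >= 0.9 * max(traj$times)))
  }
  auc_infinity(traj$times, y, n_tail = n_tail)$auc_inf
}

#' Build/validate an observation table
#'
#' Long-format destructive-sampling data: one row per animal, tissue and
#' sacrifice time.  Concentrations are ng/mL (plasma) or ng/g (tissue);
#' records below the assay quantification limit carry `below_loq = TRUE`.
#'
#' @param df data.frame with columns `subject_id`, `group`, `tissue`,
#'   `time_h`, `conc`, `dose_mg_per_kg`, `bw_kg` and optionally `below_loq`.
#' @return the validated data.frame with class `observation_table`.
#' @export
observation_table <- function(df) {
  req <- c("subject_id", "group", "tissue", "time_h", "conc",
           "dose_mg_per_kg", "bw_kg")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$below_loq)) df$below_loq <- FALSE
  if (any(df$time_h < 0)) stop("negative observation times")
  if (any(df$conc < 0 & !df$below_loq)) {
    stop("negative concentrations must be flagged below_loq")
  }
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Read / write the observation-table CSV dialect
#' @param path CSV path.
#' @return an `observation_table`.
#' @export
read_observations <- function(path) {
  observation_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param obs an `observation_table`.
#' @export
write_observations <- function(obs, path) {
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Naive-pooled mean concentration profile
#'
#' Pools all animals of one group and tissue: the arithmetic mean of
#' above-LOQ concentrations at each nominal time.  Below-LOQ records are
#' dropped (not zero-substituted); a time where every record is censored is
#' dropped with a warning.
#'
#' @param obs an [observation_table()].
#' @param tissue,group selectors.
#' @return data.frame with `time_h`, `conc`, `n` (animals contributing),
#'   ordered by time.
#' @export
pool_by_time <- function(obs, tissue, group) {
  stopifnot(inherits(obs, "observation_table"))
  sub <- obs[obs$tissue == tissue & obs$group == group, ]
  if (nrow(sub) == 0) stop("no records for tissue '", tissue, "', group '",
                           group, "'")
  keep <- !sub$below_loq
  if (!any(keep)) stop("no above-LOQ records for tissue '", tissue, "'")
  lost <- setdiff(unique(sub$time_h), unique(sub$time_h[keep]))
  if (length(lost)) {
    warning("all records below LOQ at t = ", paste(lost, collapse = ", "),
            " h for ", tissue, " (", group, "); time point(s) dropped")
  }
  sub <- sub[keep, ]
  agg <- aggregate(conc ~ time_h, data = sub, FUN = mean)
  agg$n <- aggregate(conc ~ time_h, data = sub, FUN = length)$conc
  agg[order(agg$time_h), c("time_h", "conc", "n")]
}

#' Non-compartmental analysis of one pooled profile
#'
#' Computes `AUC_last` (linear trapezoid), the terminal rate constant
#' `lambda_z` (best-adjusted-R2 log-linear window, see [lambda_z_fit()]),
#' `AUC_inf = AUC_last + C_last/lambda_z`, the first-moment area `AUMC_inf`,
#' `MRT = AUMC_inf/AUC_inf` (bolus input), and `t_half = ln 2 / lambda_z`.
#' For plasma, clearance `Cl = dose_ng / AUC_inf` (reported in L/h) and the
#' terminal-phase distribution volume `Vz = Cl / lambda_z` (L/kg) are added;
#' `Vss = Cl * MRT` is reported as a secondary field.
#'
#' @param profile data.frame with `time_h` and `conc` (from [pool_by_time()]
#'   or any concentration-time table).
#' @param dose a [dose_spec()]; needed for clearance and dose normalisation.
#' @param is_plasma whether the profile is plasma (enables Cl/Vd).
#' @param tissue label carried into the result.
#' @param n_tail optional fixed terminal window (see [lambda_z_fit()]).
#' @return an `nca_result` list.
#' @export
nca_profile <- function(profile, dose, is_plasma = FALSE, tissue = NA_character_,
                        n_tail = NULL) {
  stopifnot(inherits(dose, "dose_spec"))
  t <- profile$time_h; y <- profile$conc
  o <- order(t); t <- t[o]; y <- y[o]
  if (length(t) < 3) stop("need >= 3 time points for NCA")
  lz <- lambda_z_fit(t, y, n_tail = n_tail)
  if (lz$lambda_z <= 0) {
    stop("terminal phase is not declining (lambda_z <= 0)")
  }
  keep <- y > 0
  t_last <- tail(t[keep], 1); c_last <- tail(y[keep], 1)
  auc_last <- auc_trapz(t, y)
  auc_inf <- auc_last + c_last / lz$lambda_z
  aumc_last <- auc_trapz(t, t * y)
  aumc_inf <- aumc_last + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2
  extrap <- 1 - auc_last / auc_inf
  if (extrap > 0.5) {
    warning("more than 50% of AUC_inf is extrapolated (",
            signif(extrap, 3), ")")
  }
  res <- list(
    tissue = tissue,
    AUC_last = auc_last,
    AUC_inf = auc_inf,
    AUC_inf_dose_norm = auc_inf / dose$dose_per_kg,
    AUMC_inf = aumc_inf,
    MRT = aumc_inf / auc_inf,
    lambda_z = lz$lambda_z,
    t_half = log(2) / lz$lambda_z,
    extrapolated_fraction = extrap,
    lambda_z_window = lz,
    Cl = NA_real_, Vd = NA_real_, Vss = NA_real_)
  if (is_plasma) {
    cl_ml_h <- dose$dose_ng / auc_inf          # mL/h: ng / (ng*h/mL)
    res$Cl <- cl_ml_h / 1000                   # L/h
    res$Vd <- res$Cl / lz$lambda_z / dose$BW   # Vz, L/kg
    res$Vss <- res$Cl * res$MRT / dose$BW      # L/kg, secondary
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>", if (!is.na(x$tissue)) x$tissue else "", "\n")
  cat(sprintf("  AUC_last %.4g  AUC_inf %.4g  (extrapolated %.1f%%)\n",
              x$AUC_last, x$AUC_inf, 100 * x$extrapolated_fraction))
  cat(sprintf("  lambda_z %.4g 1/h  t_half %.3g h  MRT %.3g h\n",
              x$lambda_z, x$t_half, x$MRT))
  if (!is.na(x$Cl)) {
    cat(sprintf("  Cl %.3g L/h  Vz %.3g L/kg  Vss %.3g L/kg\n",
                x$Cl, x$Vd, x$Vss))
  }
  invisible(x)
}

#' Tissue/plasma partition coefficient from AUC ratio
#'
#' `P = AUC_inf(tissue) / AUC_inf(plasma)` on dose-normalised areas — the
#' definition used to carry the in vivo results into the PBPK model.
#'
#' @param tissue_result,plasma_result `nca_result` objects from the same
#'   group (dose normalisation makes mixed doses comparable).
#' @return scalar P.
#' @export
partition_coefficient <- function(tissue_result, plasma_result) {
  stopifnot(inherits(tissue_result, "nca_result"),
            inherits(plasma_result, "nca_result"))
  if (plasma_result$AUC_inf_dose_norm <= 0) stop("plasma AUC must be > 0")
  tissue_result$AUC_inf_dose_norm / plasma_result$AUC_inf_dose_norm
}

#' NCA over every tissue of one group
#'
#' @param obs an [observation_table()].
#' @param group group label to analyse.
#' @param dose a [dose_spec()] for that group.
#' @param n_tail optional fixed terminal window.
#' @return data.frame, one row per tissue, mirroring the usual reporting
#'   layout (AUC_inf dose-normalised, MRT, t_half, plus Cl/Vd for plasma and
#'   the AUC-ratio partition coefficient for tissues).
#' @export
nca_by_tissue <- function(obs, group, dose, n_tail = NULL) {
  stopifnot(inherits(obs, "observation_table"))
  tissues <- unique(obs$tissue[obs$group == group])
  if (!"plasma" %in% tissues) stop("group '", group, "' has no plasma data")
  results <- lapply(tissues, function(ts) {
    nca_profile(pool_by_time(obs, ts, group), dose,
                is_plasma = ts == "plasma", tissue = ts, n_tail = n_tail)
  })
  names(results) <- tissues
  plasma <- results[["plasma"]]
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      tissue = r$tissue, group = group,
      AUC_inf_dose_norm = r$AUC_inf_dose_norm,
      MRT_h = r$MRT, t_half_h = r$t_half, lambda_z = r$lambda_z,
      extrapolated_fraction = r$extrapolated_fraction,
      Cl_L_h = r$Cl, Vd_L_kg = r$Vd,
      P_auc_ratio = if (r$tissue == "plasma") NA_real_
                    else partition_coefficient(r, plasma))
  }))
}
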
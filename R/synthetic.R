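# Virtual-study generator: in vivo destructive-sampling biodistribution
# studies and in vitro release/uptake experiments with the statistical
# structure the analysis pipeline assumes.  Stands in for the original raw
# animal data, which are not deposited; every dataset it emits is synthetic.

#' In vivo study design
#'
#' Defaults mirror the biodistribution study: destructive sampling at 1, 3,
#' 6, 12 and 24 h; plasma, liver, spleen, thymus and brain sampled from each
#' animal; doses 11.9 mg/kg (solution) and 15.6 mg/kg (carrier); body weight
#' 252 +/- 12 g; assay quantification limit 1 ng/mL.  Noise is multiplicative
#' lognormal; the default in vivo CV of 0.30 (biological plus assay
#' variability) is an implementation default, not a reported value.
#'
#' @param sampling_times sacrifice times, h.
#' @param n_per_time animals per sacrifice time (destructive sampling; with
#'   2 groups x 5 times, n = 3-4 reaches the study's 38-animal scale).
#' @param tissues matrices sampled from each animal.
#' @param dose_solution,dose_nanoparticle group mean doses, mg/kg.
#' @param BW_mean,BW_sd body-weight distribution, kg.
#' @param noise_cv multiplicative lognormal coefficient of variation.
#' @param loq lower limit of quantification, ng/mL.
#' @return a `study_design` list.
#' @export
study_design <- function(sampling_times = c(1, 3, 6, 12, 24),
                         n_per_time = 4,
                         tissues = c("plasma", "liver", "spleen", "thymus",
                                     "brain"),
                         dose_solution = 11.9, dose_nanoparticle = 15.6,
                         BW_mean = 0.252, BW_sd = 0.012,
                         noise_cv = 0.30, loq = 1) {
  stopifnot(all(sampling_times > 0), n_per_time >= 1, noise_cv >= 0,
            BW_mean > 0, BW_sd >= 0, loq >= 0)
  structure(list(sampling_times = sort(sampling_times),
                 n_per_time = n_per_time, tissues = tissues,
                 dose_solution = dose_solution,
                 dose_nanoparticle = dose_nanoparticle,
                 BW_mean = BW_mean, BW_sd = BW_sd,
                 noise_cv = noise_cv, loq = loq),
            class = "study_design")
}

# lognormal multiplier with unit mean-log and the requested CV
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = 0, sd = sdlog))
}

#' Generate a virtual in vivo biodistribution study
#'
#' One virtual animal per row-group: its body weight is drawn from a
#' truncated normal, the appropriate PBPK model is simulated at its dose,
#' and the assay concentration of every sampled matrix is recorded at the
#' animal's single sacrifice time with multiplicative lognormal noise.
#' Records below the quantification limit are kept but flagged
#' `below_loq`.
#'
#' @param params a `pbpk_parameters` object (its formulation decides the
#'   model and the group dose).
#' @param design a [study_design()].
#' @param seed integer seed; the output is fully reproducible from it.
#' @return an [observation_table()].
#' @export
generate_in_vivo <- function(params, design = study_design(), seed = 1) {
  stopifnot(inherits(params, "pbpk_parameters"),
            inherits(design, "study_design"))
  set.seed(seed)
  group <- params$group_label
  dose_per_kg <- if (params$formulation$kind == "nanoparticle") {
    design$dose_nanoparticle
  } else {
    design$dose_solution
  }
  rows <- list()
  subj <- 0L
  for (tt in design$sampling_times) {
    for (a in seq_len(design$n_per_time)) {
      subj <- subj + 1L
      bw <- 0
      while (bw <= 0) bw <- rnorm(1, design$BW_mean, design$BW_sd)
      ds <- dose_spec(dose_per_kg, BW = bw)
      traj <- simulate_pbpk(params, ds, output_times = c(0, tt),
                            rtol = 1e-8, atol = 1e-6)
      noise <- .lognoise(length(design$tissues), design$noise_cv)
      conc <- vapply(seq_along(design$tissues), function(i) {
        predicted_concentration(traj, design$tissues[i])[2] * noise[i]
      }, numeric(1))
      rows[[subj]] <- data.frame(
        subject_id = sprintf("%s_%03d", substr(group, 1, 3), subj),
        group = group, tissue = design$tissues, time_h = tt,
        conc = conc, dose_mg_per_kg = dose_per_kg, bw_kg = bw,
        below_loq = conc < design$loq)
    }
  }
  observation_table(do.call(rbind, rows))
}

#' Generate an in vitro release dataset
#'
#' First-order cumulative release, `F(t) = 100 (1 - exp(-Krel t))`, sampled
#' at the release-study times (default 1, 24, 48, 72 h) with multiplicative
#' lognormal noise.
#'
#' @param Krel release rate constant, 1/h.
#' @param times sampling times, h.
#' @param noise_cv multiplicative CV (default 0.05, typical in vitro assay
#'   variability).
#' @param seed integer seed.
#' @param condition_label carried into the dataset (e.g. `"pH 7.4"`).
#' @return a [kinetic_dataset()].
#' @export
generate_release_data <- function(Krel, times = c(1, 24, 48, 72),
                                  noise_cv = 0.05, seed = 1,
                                  condition_label = "") {
  stopifnot(Krel > 0)
  set.seed(seed)
  resp <- 100 * release_fraction(Krel, times) * .lognoise(length(times),
                                                          noise_cv)
  kinetic_dataset(times, pmin(resp, 120), condition_label)
}

#' Generate an in vitro uptake dataset
#'
#' Saturating first-order uptake, `U(t) = Umax (1 - exp(-Kup t))`, sampled at
#' the uptake-study times (default 1, 6, 24, 48 h).
#'
#' @param Kup uptake rate constant, 1/h.
#' @param Umax plateau, percent of the added amount, in (0, 100].
#' @param times sampling times, h.
#' @inheritParams generate_release_data
#' @return a [kinetic_dataset()].
#' @export
generate_uptake_data <- function(Kup, Umax = 100, times = c(1, 6, 24, 48),
                                 noise_cv = 0.05, seed = 1,
                                 condition_label = "") {
  stopifnot(Kup > 0, Umax > 0, Umax <= 100)
  set.seed(seed)
  resp <- Umax * (1 - exp(-Kup * times)) * .lognoise(length(times), noise_cv)
  kinetic_dataset(times, pmin(resp, 120), condition_label)
}
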
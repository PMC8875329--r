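test_that("fold-error metrics match their closed forms", {
  obs <- c(1, 2, 3, 4)
  expect_equal(afe(obs, obs), 1)
  expect_equal(aafe(obs, obs), 1)
  expect_equal(afe(2 * obs, obs), 2)
  # ratios {2, 0.5}: bias cancels in AFE but not in AAFE
  expect_equal(afe(c(2, 0.5), c(1, 1)), 1)
  expect_equal(aafe(c(2, 0.5), c(1, 1)), 2)
  expect_error(afe(c(1, -1), c(1, 1)), "positive")
  expect_error(aafe(1, c(1, 2)), "equal length")
})

test_that("fold-error metrics agree with brute-force log-space sums", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    pred <- exp(rnorm(n)); obs <- exp(rnorm(n))
    expect_equal(afe(pred, obs),
                 10^(sum(log10(pred / obs)) / n), tolerance = 1e-12)
    expect_equal(aafe(pred, obs),
                 10^(sum(abs(log10(pred / obs))) / n), tolerance = 1e-12)
    expect_gte(aafe(pred, obs) + 1e-12, max(afe(pred, obs),
                                            1 / afe(pred, obs)))
  }
})

test_that("validation on model-generated data is exactly unbiased", {
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  obs <- generate_in_vivo(p, noiseless_design(), seed = 5)
  tr <- simulate_pbpk(p, ref_dose_carrier(),
                      output_times = c(0, unique(obs$time_h)))
  rep <- validate_predictions(tr, obs)
  expect_equal(rep$per_tissue$AFE, rep(1, 5), tolerance = 1e-6)
  expect_equal(rep$per_tissue$AAFE, rep(1, 5), tolerance = 1e-6)
  expect_equal(rep$correlation, 1, tolerance = 1e-9)
  expect_true(all(rep$per_tissue$pass_afe))

  # doubled observations give AFE 0.5, still inside the inclusive band
  half <- obs; half$conc <- half$conc * 2
  rep2 <- validate_predictions(tr, observation_table(half))
  expect_equal(rep2$per_tissue$AFE, rep(0.5, 5), tolerance = 1e-6)
  expect_true(all(rep2$per_tissue$pass_afe))
  # and 2.01-fold predictions fall outside it
  over <- obs; over$conc <- over$conc / 2.01
  rep3 <- validate_predictions(tr, observation_table(over))
  expect_false(any(rep3$per_tissue$pass_afe))
})

test_that("fitting no free parameters returns the base objective", {
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  obs <- generate_in_vivo(p, noiseless_design(), seed = 5)
  sp <- fit_spec(c(`tissues.liver.Kup` = 0.564))
  sp$free <- sp$free[0]
  res <- fit_pbpk(obs, p, sp, ref_dose_carrier(), tissues = "liver")
  expect_equal(res$params, p)
  expect_lt(res$objective, 1e-10)
})

test_that("noise-free fits recover the generating tissue uptake constants", {
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  obs <- generate_in_vivo(p, noiseless_design(), seed = 42)
  d <- ref_dose_carrier()
  # per-tissue sequential strategy, in vitro value 0.564 1/h as the initial
  # estimate, as in the original optimisation
  f_liv <- fit_pbpk(obs, p, fit_spec(c(`tissues.liver.Kup` = 0.564)), d,
                    tissues = "liver")
  expect_equal(unname(f_liv$estimates), 0.15, tolerance = 0.05)
  f_spl <- fit_pbpk(obs, p, fit_spec(c(`tissues.spleen.Kup` = 0.564)), d,
                    tissues = "spleen")
  expect_equal(unname(f_spl$estimates), 0.03, tolerance = 0.05)
})

test_that("the general-tissue partition coefficient is identifiable from
           plasma", {
  truth <- default_rat_parameters("solution", BW = 0.252, Pgt = 0.8)
  obs <- generate_in_vivo(truth, noiseless_design(), seed = 7)
  base <- default_rat_parameters("solution", BW = 0.252, Pgt = 1)
  expect_warning(
    f <- fit_pbpk(obs, base, fit_spec(c(`systemic.Pgt` = 1)),
                  ref_dose_solution(), tissues = "plasma"),
    "below LOQ")
  expect_equal(unname(f$estimates), 0.8, tolerance = 0.05)
})

test_that("joint (Kup, PS) spleen fits stay near truth under 20% noise", {
  d <- ref_dose_carrier()
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  errs <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    des <- study_design(noise_cv = 0.20, n_per_time = 3)
    obs <- suppressWarnings(generate_in_vivo(p, des, seed = 1000 + s))
    f <- suppressWarnings(
      fit_pbpk(obs, p,
               fit_spec(c(`tissues.spleen.Kup` = 0.564,
                          `tissues.spleen.PS` = 1)),
               d, tissues = "spleen", rtol = 1e-6))
    errs[s, ] <- abs(f$estimates / c(0.03, 0.49) - 1)
  }
  expect_lt(median(errs[, 1]), 0.30)
})

test_that("parameter paths are validated and bounds reported", {
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  obs <- generate_in_vivo(p, noiseless_design(), seed = 5)
  expect_error(fit_pbpk(obs, p, fit_spec(c(`tissues.liver.Qup` = 1)),
                        ref_dose_carrier(), tissues = "liver"),
               "no parameter")
  expect_error(fit_spec(c(`tissues.liver.Kup` = 0.5),
                        lower = c(`tissues.liver.Kup` = 1)),
               "within bounds")
})

test_that("validation reports export in the indices-by-tissue layout", {
  p <- default_rat_parameters("nanoparticle", BW = 0.252)
  obs <- generate_in_vivo(p, noiseless_design(), seed = 5)
  tr <- simulate_pbpk(p, ref_dose_carrier(),
                      output_times = c(0, unique(obs$time_h)))
  rep <- validate_predictions(tr, obs)
  f <- tempfile(fileext = ".csv")
  write_validation_report(rep, f)
  out <- read.csv(f)
  expect_equal(out$index, c("AFE", "AAFE"))
  expect_true(all(c("plasma", "liver", "spleen", "thymus", "brain")
                  %in% names(out)))
  unlink(f)
})
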
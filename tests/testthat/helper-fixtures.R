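# Shared fixtures.  Long-horizon trajectories are computed once per test run
# and reused across files.

ref_dose_solution <- function(BW = 0.252) dose_spec(11.9, BW = BW)
ref_dose_carrier <- function(BW = 0.252) dose_spec(15.6, BW = BW)

# noiseless single-animal design at a fixed body weight, for exact-recovery
# checks
noiseless_design <- function(n_per_time = 1) {
  study_design(noise_cv = 0, n_per_time = n_per_time, BW_sd = 0)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

long_solution_traj <- function() {
  cached("sol200", simulate_pbpk(default_rat_parameters("solution"),
                                 ref_dose_solution(),
                                 output_times = output_grid(200)))
}

long_carrier_traj <- function() {
  cached("np200", simulate_pbpk(default_rat_parameters("nanoparticle"),
                                ref_dose_carrier(),
                                output_times = output_grid(200)))
}

# zero-Kup, (numerically) zero-release carrier parameter set whose free-drug
# states must reduce to the solution model with the same PS/P
degenerate_carrier_parameters <- function() {
  base <- default_rat_parameters("solution")
  tis <- lapply(base$tissues, function(ti) {
    tissue_params(ti$name, ti$Q, ti$V_total, ti$f_vasc, ti$PS, ti$P, Kup = 0)
  })
  s <- base$systemic
  pbpk_parameters(
    systemic_params(s$Qp, s$Cl, s$Vd_per_kg, s$BW, s$Pgt, Kup_plasma = 0),
    tis,
    formulation_params("nanoparticle", Krel = 1e-12, loading_fraction = 0),
    group_label = "degenerate_carrier")
}
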
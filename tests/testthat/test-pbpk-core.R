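zero_state <- function(kind) {
  setNames(numeric(length(pbpk_state_names(kind))), pbpk_state_names(kind))
}

test_that("the origin is an equilibrium of both systems", {
  sol <- default_rat_parameters("solution")
  np <- default_rat_parameters("nanoparticle")
  expect_equal(unname(solution_rhs(zero_state("solution"), sol)),
               rep(0, 11))
  expect_equal(unname(carrier_rhs(zero_state("nanoparticle"), np)),
               rep(0, 22))
  expect_error(solution_rhs(zero_state("solution"), np), "nanoparticle")
  expect_error(carrier_rhs(zero_state("nanoparticle"), sol), "solution")
  bad <- zero_state("solution"); bad[1] <- NaN
  expect_error(solution_rhs(bad, sol), "non-finite")
})

test_that("partition equilibrium nulls the trans-membrane flux", {
  p <- default_rat_parameters("solution")
  st <- zero_state("solution")
  for (nm in names(p$tissues)) {
    st[paste0(nm, "_v")] <- 50
    st[paste0(nm, "_ev")] <- p$tissues[[nm]]$P * 50
  }
  d <- solution_rhs(st, p)
  for (nm in names(p$tissues)) {
    expect_equal(unname(d[paste0(nm, "_ev")]), 0)
  }
})

test_that("derivatives match hand-evaluated balances at a probe state", {
  # free-drug system, Cp = 100, everything else 0
  p <- default_rat_parameters("solution")  # BW 0.250
  st <- zero_state("solution"); st["Cp"] <- 100
  d <- solution_rhs(st, p)
  Vd_mL <- 1.84 * 0.250 * 1000
  expect_equal(unname(d["Cp"]), -(3.09 + 0.46) * 1000 * 100 / Vd_mL)
  liver <- p$tissues$liver
  expect_equal(unname(d["liver_v"]), 0.60 * 1000 * 100 / (liver$V_v * 1000))
  expect_equal(unname(d["A_elim"]), 0.46 * 1000 * 100)
  expect_equal(unname(d["brain_ev"]), 0)

  # carrier system, Cp_np = 100, everything else 0
  np <- default_rat_parameters("nanoparticle")
  stn <- zero_state("nanoparticle"); stn["Cp_np"] <- 100
  dn <- carrier_rhs(stn, np)
  Vdn_mL <- 2.92 * 0.250 * 1000
  expect_equal(unname(dn["Cp"]), 0.058 * 100)          # released drug
  expect_equal(unname(dn["Cp_np"]),
               -3.09 * 1000 * 100 / Vdn_mL - (0.058 + 0.56) * 100)
  expect_equal(unname(dn["liver_v_np"]),
               0.60 * 1000 * 100 / (np$tissues$liver$V_v * 1000))
  expect_equal(unname(dn["A_seq"]), 0.56 * 100 * Vdn_mL)
})

test_that("bolus initial conditions and plasma decline are as expected", {
  p <- default_rat_parameters("solution")
  d <- ref_dose_solution()            # 11.9 mg/kg at 252 g
  tr <- simulate_pbpk(p, d, t_end = 24)
  expect_equal(trajectory_state(tr, "Cp")[1],
               2.9988e6 / 463.68, tolerance = 1e-6)
  # wherever general tissue remains below its plasma equilibrium, the plasma
  # balance is strictly negative, so Cp declines over those intervals
  cp <- trajectory_state(tr, "Cp")
  cgt <- trajectory_state(tr, "Cgt")
  below <- which(cgt / p$systemic$Pgt < cp)
  runs <- below[which(diff(below) == 1)]
  expect_gt(length(runs), 10)
  expect_true(all(diff(cp)[runs] < 0))

  np <- default_rat_parameters("nanoparticle")
  trn <- simulate_pbpk(np, ref_dose_carrier(), t_end = 24)
  expect_equal(trajectory_state(trn, "Cp_np")[1],
               15.6 * 0.252 * 1e6 / (2.92 * 0.252 * 1000))
  expect_equal(trajectory_state(trn, "Cp")[1], 0)
})

test_that("instant-release limit reaches the dose/clearance plasma AUC", {
  p <- default_rat_parameters("nanoparticle")
  p$formulation$Krel <- 1e3
  for (nm in names(p$tissues)) p$tissues[[nm]]$Kup <- 0
  p$systemic$Kup_plasma <- 0
  d <- ref_dose_carrier()
  tr <- simulate_pbpk(p, d, output_times = output_grid(200))
  auc <- trajectory_auc(tr, "Cp")
  expect_equal(auc, d$dose_ng / (0.73 * 1000), tolerance = 0.01)
})

test_that("AUC identities hold for the free-drug model", {
  tr <- long_solution_traj()
  d <- tr$dose
  aucp <- trajectory_auc(tr, "Cp")
  # clearance is the only exit: AUC(Cp) = dose / Cl
  expect_equal(aucp, d$dose_ng / (0.46 * 1000), tolerance = 0.005)
  for (nm in names(tr$params$tissues)) {
    ti <- tr$params$tissues[[nm]]
    # extravascular AUC / plasma AUC recovers the partition coefficient
    expect_equal(trajectory_auc(tr, paste0(nm, "_ev")) / aucp, ti$P,
                 tolerance = 0.01)
    # vascular AUC equals plasma AUC
    expect_equal(trajectory_auc(tr, paste0(nm, "_v")) / aucp, 1,
                 tolerance = 0.01)
  }
})

test_that("no state dips below the non-negativity tolerance", {
  for (tr in list(long_solution_traj(), long_carrier_traj())) {
    expect_true(min(tr$states) >= -1e-9 * max(tr$states))
  }
})

test_that("carrier model reduces to the free-drug model without carrier", {
  deg <- degenerate_carrier_parameters()
  d <- ref_dose_solution()
  grid <- output_grid(24)
  trc <- simulate_pbpk(deg, d, output_times = grid)
  trs <- simulate_pbpk(default_rat_parameters("solution", BW = 0.252), d,
                       output_times = grid)
  for (nm in pbpk_state_names("solution")) {
    expect_equal(trajectory_state(trc, nm), trajectory_state(trs, nm),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # carrier pools stay (numerically) empty
  expect_lt(max(trc$states[, grep("_np$", colnames(trc$states))]), 1e-6)
})

test_that("reported AUCs are stable under tolerance refinement", {
  p <- default_rat_parameters("solution")
  d <- ref_dose_solution()
  grid <- output_grid(200)
  a1 <- trajectory_auc(simulate_pbpk(p, d, output_times = grid), "Cp")
  a2 <- trajectory_auc(simulate_pbpk(p, d, output_times = grid,
                                     rtol = 5e-10, atol = 5e-4), "Cp")
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("tissue totals are the volume-weighted sub-compartment mean", {
  tr <- long_solution_traj()
  fake <- tr
  fake$states[, "liver_v"] <- 7
  fake$states[, "liver_ev"] <- 7
  expect_equal(unique(tissue_total_concentration(fake, "liver")), 7)
  f <- fake$params$tissues$liver$f_vasc
  fake$states[, "liver_v"] <- 2
  fake$states[, "liver_ev"] <- 0
  expect_equal(unique(tissue_total_concentration(fake, "liver")), 2 * f)
  expect_error(tissue_total_concentration(tr, "kidney"), "unknown tissue")
  # weighted mean lies between the two sub-compartment AUCs
  auc_tot <- trajectory_auc(tr, tissue_total_concentration(tr, "liver"))
  auc_v <- trajectory_auc(tr, "liver_v")
  auc_ev <- trajectory_auc(tr, "liver_ev")
  expect_gte(auc_tot, min(auc_v, auc_ev))
  expect_lte(auc_tot, max(auc_v, auc_ev))
})

test_that("mass audit closes on the conserved set and flags satellites", {
  trs <- long_solution_traj()
  ma <- mass_audit(trs)
  expect_equal(ma$conserved_ng[1], trs$dose$dose_ng)  # exact at t = 0
  expect_lt(attr(ma, "max_drift"), 1e-4)
  expect_true(attr(ma, "ok"))
  # satellite tissues accumulate mass that is not drawn from plasma
  expect_true(all(ma$satellite_ng >= 0))

  man <- mass_audit(long_carrier_traj())
  expect_equal(man$conserved_ng[1], 15.6 * 0.252 * 1e6)
  expect_lt(attr(man, "max_drift"), 1e-4)

  # accumulators never decrease
  expect_true(all(diff(trajectory_state(long_carrier_traj(), "A_elim")) >= 0))
  expect_true(all(diff(trajectory_state(long_carrier_traj(), "A_seq")) >= 0))
})

test_that("mass-conserving plasma mode conserves the whole body", {
  p <- default_rat_parameters("solution")
  d <- ref_dose_solution()
  tr <- simulate_pbpk(p, d, output_times = output_grid(48),
                      mass_conserving_plasma = TRUE)
  ma <- mass_audit(tr)
  expect_lt(attr(ma, "max_drift"), 1e-4)
  expect_true(all(ma$satellite_ng == 0))
})

test_that("the tidy trajectory view is long and labelled", {
  tr <- simulate_pbpk(default_rat_parameters("nanoparticle"),
                      ref_dose_carrier(), output_times = c(0, 1, 2))
  df <- as.data.frame(tr)
  expect_setequal(unique(df$species), c("free", "carrier", "accumulator"))
  expect_equal(nrow(df), 3 * 22)
})
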
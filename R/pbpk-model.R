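# Whole-body PBPK model for stavudine given as free solution or bound to a
# 40 nm gold-nanoparticle carrier.  Compartments: plasma, a lumped "general
# tissue", and four permeability-limited tissues (brain, liver, spleen,
# thymus), each split into a vascular and an extravascular sub-compartment.
#
# Structure notes (deliberate, see the methods vignette):
#  * The plasma equation carries no return flow from the four named tissues:
#    they are driven "satellite" compartments.  An optional
#    mass_conserving_plasma mode adds the return terms for sensitivity
#    analysis.
#  * Tissue nanoparticle uptake is a first-order flux on the vascular
#    carrier amount, J = Kup * C_v_np * V_v, moved into the extravascular
#    carrier pool; the plasma-phase uptake flux Kup_plasma * Cp_np * Vd is an
#    irreversible exit accumulated in A_seq.
#  * Carrier release happens in every carrier pool at the single pH 7.4 Krel.
#
# Internal units: ng, mL, h.  1 L = 1000 mL; tissue density 1 g/mL, so ng/g
# and ng/mL are interchangeable for tissue concentrations.

.solution_state_names <- function() {
  c("Cp", "Cgt",
    as.vector(t(outer(.TISSUES, c("_v", "_ev"), paste0))),
    "A_elim")
}

.carrier_state_names <- function() {
  c(.solution_state_names(),
    "Cp_np", "Cgt_np",
    as.vector(t(outer(.TISSUES, c("_v_np", "_ev_np"), paste0))),
    "A_seq")
}

#' State-vector names for a formulation kind
#' @param kind `"solution"` or `"nanoparticle"`.
#' @return character vector of state names. Concentrations are ng/mL; the
#'   accumulators `A_elim` (amount cleared) and `A_seq` (carrier amount
#'   sequestered from plasma) are ng.
#' @export
pbpk_state_names <- function(kind = c("solution", "nanoparticle")) {
  kind <- match.arg(kind)
  if (kind == "solution") .solution_state_names() else .carrier_state_names()
}

# Parameters converted once to internal units (mL, mL/h), with per-tissue
# values as plain vectors in the fixed .TISSUES order so the ODE right-hand
# side stays vectorised (deSolve calls it thousands of times per solve).
.internal_params <- function(params) {
  s <- params$systemic
  g <- function(fld) vapply(params$tissues[.TISSUES], `[[`, numeric(1), fld)
  list(
    Qp = s$Qp * 1000, Cl = s$Cl * 1000, Vd = s$Vd_L * 1000,
    Pgt = s$Pgt, Kupp = s$Kup_plasma,
    Krel = params$formulation$Krel,
    Q = g("Q") * 1000, V_v = g("V_v") * 1000, V_ev = g("V_ev") * 1000,
    PS = g("PS") * 1000, P = g("P"), Kup = g("Kup"),
    tis = lapply(params$tissues[.TISSUES], function(ti) {
      list(Q = ti$Q * 1000, V_v = ti$V_v * 1000, V_ev = ti$V_ev * 1000,
           PS = ti$PS * 1000, P = ti$P, Kup = ti$Kup)
    }))
}

# state-vector index layout: tissue vascular/extravascular pairs follow
# plasma and general tissue, accumulators last
.IV  <- c(3L, 5L, 7L, 9L)   # <tissue>_v
.IEV <- .IV + 1L            # <tissue>_ev
.IVN  <- c(14L, 16L, 18L, 20L)  # <tissue>_v_np
.IEVN <- .IVN + 1L              # <tissue>_ev_np

.check_state <- function(state, kind) {
  nms <- pbpk_state_names(kind)
  if (length(state) != length(nms)) {
    stop("state vector must have ", length(nms), " components (", kind,
         " model), got ", length(state))
  }
  if (!all(is.finite(state))) stop("non-finite value in state vector")
  if (is.null(names(state))) names(state) <- nms
  state
}

#' Right-hand side of the free-solution PBPK system
#'
#' Time-derivatives of the 10 concentration states plus the cleared-amount
#' accumulator.  Plasma: `Vd dCp/dt = Qp (Cgt/Pgt - Cp) - Cl Cp`; general
#' tissue: `Vd dCgt/dt = Qp (Cp - Cgt/Pgt)`; each tissue:
#' `V_v dC_v/dt = Q (Cp - C_v) + PS (C_ev/P - C_v)` and
#' `V_ev dC_ev/dt = PS (C_v - C_ev/P)`.
#'
#' @param state named state vector (see [pbpk_state_names()]), ng/mL.
#' @param params a `pbpk_parameters` object with solution formulation.
#' @param mass_conserving_plasma if `TRUE`, add the (non-default) return
#'   flows `-sum Q_i (Cp - C_i_v)` to the plasma balance.
#' @return named derivative vector, ng/mL/h (ng/h for `A_elim`).
#' @export
solution_rhs <- function(state, params, mass_conserving_plasma = FALSE) {
  stopifnot(inherits(params, "pbpk_parameters"))
  if (params$formulation$kind != "solution") {
    stop("params describe a ", params$formulation$kind, " formulation")
  }
  state <- .check_state(state, "solution")
  ip <- .internal_params(params)
  .solution_deriv(state, ip, mass_conserving_plasma)
}

.solution_deriv <- function(y, ip, mcp = FALSE) {
  d <- numeric(11L)
  Cp <- y[1L]; Cgt <- y[2L]
  Cv <- y[.IV]; Cev <- y[.IEV]
  dCp_amt <- ip$Qp * (Cgt / ip$Pgt - Cp) - ip$Cl * Cp
  d[2L] <- ip$Qp * (Cp - Cgt / ip$Pgt) / ip$Vd
  d[.IV] <- (ip$Q * (Cp - Cv) + ip$PS * (Cev / ip$P - Cv)) / ip$V_v
  d[.IEV] <- ip$PS * (Cv - Cev / ip$P) / ip$V_ev
  if (mcp) dCp_amt <- dCp_amt - sum(ip$Q * (Cp - Cv))
  d[1L] <- dCp_amt / ip$Vd
  d[11L] <- ip$Cl * Cp
  names(d) <- names(y)
  d
}

#' Right-hand side of the carrier (nanoparticle) PBPK system
#'
#' Extends the free-drug system with carrier-bound pools in plasma, general
#' tissue and every tissue sub-compartment.  Carrier release is first order
#' (`Krel`) everywhere and feeds the co-located free-drug pool; tissue uptake
#' moves carrier from the vascular to the extravascular pool at rate `Kup`
#' (flux `Kup * C_v_np * V_v`); the plasma uptake flux
#' `Kup_plasma * Cp_np * Vd` leaves the system and accrues in `A_seq`.
#' Free-drug trans-membrane exchange uses the carrier-group `PS` and `P`.
#'
#' @inheritParams solution_rhs
#' @export
carrier_rhs <- function(state, params, mass_conserving_plasma = FALSE) {
  stopifnot(inherits(params, "pbpk_parameters"))
  if (params$formulation$kind != "nanoparticle") {
    stop("params describe a ", params$formulation$kind,
         " formulation; carrier parameters absent")
  }
  state <- .check_state(state, "nanoparticle")
  ip <- .internal_params(params)
  .carrier_deriv(state, ip, mass_conserving_plasma)
}

.carrier_deriv <- function(y, ip, mcp = FALSE) {
  d <- numeric(22L)
  Cp <- y[1L]; Cgt <- y[2L]
  Cpn <- y[12L]; Cgtn <- y[13L]
  Cv <- y[.IV]; Cev <- y[.IEV]
  Cvn <- y[.IVN]; Cevn <- y[.IEVN]
  dCp_amt <- ip$Qp * (Cgt / ip$Pgt - Cp) + ip$Krel * Cpn * ip$Vd - ip$Cl * Cp
  dCpn_amt <- ip$Qp * (Cgtn - Cpn) - ip$Krel * Cpn * ip$Vd -
    ip$Kupp * Cpn * ip$Vd
  d[2L] <- (ip$Qp * (Cp - Cgt / ip$Pgt) + ip$Krel * Cgtn * ip$Vd) / ip$Vd
  d[13L] <- (ip$Qp * (Cpn - Cgtn) - ip$Krel * Cgtn * ip$Vd) / ip$Vd
  J_up <- ip$Kup * Cvn * ip$V_v          # vascular -> extravascular carrier, ng/h
  d[.IVN] <- (ip$Q * (Cpn - Cvn) - J_up) / ip$V_v - ip$Krel * Cvn
  d[.IEVN] <- J_up / ip$V_ev - ip$Krel * Cevn
  d[.IV] <- (ip$Q * (Cp - Cv) + ip$PS * (Cev / ip$P - Cv)) / ip$V_v +
    ip$Krel * Cvn
  d[.IEV] <- ip$PS * (Cv - Cev / ip$P) / ip$V_ev + ip$Krel * Cevn
  if (mcp) {
    dCp_amt <- dCp_amt - sum(ip$Q * (Cp - Cv))
    dCpn_amt <- dCpn_amt - sum(ip$Q * (Cpn - Cvn))
  }
  d[1L] <- dCp_amt / ip$Vd
  d[12L] <- dCpn_amt / ip$Vd
  d[11L] <- ip$Cl * Cp
  d[22L] <- ip$Kupp * Cpn * ip$Vd
  names(d) <- names(y)
  d
}

#' Output grid with a dense early phase
#'
#' Plasma mixes and declines fast after the bolus; a grid dense over the first
#' day and coarser afterwards keeps trapezoid AUCs accurate without inflating
#' the solver output.
#'
#' @param t_end end of the grid, h.
#' @return numeric vector of times starting at 0.
#' @export
output_grid <- function(t_end = 24) {
  g <- c(seq(0, min(1, t_end), by = 0.005),
         if (t_end > 1) seq(1.05, min(24, t_end), by = 0.05),
         if (t_end > 24) seq(24.5, t_end, by = 0.5))
  unique(g)
}

#' Simulate a PBPK trajectory after an instantaneous bolus
#'
#' Initial condition: for a solution formulation the whole dose mixes into
#' plasma, `Cp(0) = dose_ng / Vd_mL`; for the carrier formulation the
#' carrier-bound fraction enters `Cp_np` and the remainder (if any) enters
#' `Cp`.  Integration uses a stiff-capable solver (`deSolve::lsoda`).
#'
#' @param params a `pbpk_parameters` object.
#' @param dose a [dose_spec()]. Its `BW` is used for the total dose; the
#'   distribution volume in millilitres is `Vd_per_kg * BW * 1000` with the
#'   same `BW`.
#' @param t_end simulation horizon, h (ignored when `output_times` given).
#' @param output_times explicit output grid (must start at 0); default
#'   [output_grid()] of `t_end`.
#' @param rtol,atol solver relative / absolute (ng/mL) tolerances.
#' @param mass_conserving_plasma see [solution_rhs()].
#' @return a `pbpk_trajectory`: list with `times`, `states` (matrix, one
#'   column per state), `params`, `dose`, `solver_meta`.
#' @export
simulate_pbpk <- function(params, dose, t_end = 24, output_times = NULL,
                          rtol = 1e-9, atol = 1e-3,
                          mass_conserving_plasma = FALSE) {
  stopifnot(inherits(params, "pbpk_parameters"), inherits(dose, "dose_spec"))
  if (is.null(output_times)) {
    if (t_end <= 0) stop("t_end must be > 0")
    output_times <- output_grid(t_end)
  }
  output_times <- sort(unique(as.numeric(output_times)))
  if (output_times[1] != 0) output_times <- c(0, output_times)
  kind <- params$formulation$kind
  ip <- .internal_params(params)
  # dose scales with the administered animal's weight; so does Vd
  ip$Vd <- params$systemic$Vd_per_kg * dose$BW * 1000
  nms <- pbpk_state_names(kind)
  y0 <- setNames(numeric(length(nms)), nms)
  if (kind == "solution") {
    y0[["Cp"]] <- dose$dose_ng / ip$Vd
    deriv <- .solution_deriv
  } else {
    lf <- params$formulation$loading_fraction
    y0[["Cp_np"]] <- lf * dose$dose_ng / ip$Vd
    y0[["Cp"]] <- (1 - lf) * dose$dose_ng / ip$Vd
    deriv <- .carrier_deriv
  }
  func <- function(t, y, p) list(deriv(y, p, mass_conserving_plasma))
  out <- deSolve::lsoda(y = y0, times = output_times, func = func, parms = ip,
                        rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (nrow(out) < length(output_times)) {
    stop("ODE solver failed at t = ", max(out[, 1]),
         " (istate = ", diagn[1], ")")
  }
  states <- out[, -1, drop = FALSE]
  peak <- max(abs(states))
  if (min(states) < -1e-6 * peak) {
    stop("solver produced negative concentrations beyond tolerance (min = ",
         min(states), ")")
  }
  states[states < 0] <- 0
  structure(
    list(times = out[, 1], states = states, params = params, dose = dose,
         solver_meta = list(method = "lsoda", rtol = rtol, atol = atol,
                            istate = diagn,
                            mass_conserving_plasma = mass_conserving_plasma)),
    class = "pbpk_trajectory")
}

#' @export
print.pbpk_trajectory <- function(x, ...) {
  cat("<pbpk_trajectory>", x$params$group_label, "model,",
      length(x$times), "time points over", max(x$times), "h,",
      ncol(x$states), "states\n")
  invisible(x)
}

#' Extract one state series from a trajectory
#' @param traj a `pbpk_trajectory`.
#' @param state a state name (see [pbpk_state_names()]).
#' @return numeric vector over `traj$times`.
#' @export
trajectory_state <- function(traj, state) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  if (!state %in% colnames(traj$states)) stop("unknown state '", state, "'")
  traj$states[, state]
}

#' Tidy long-format view of a trajectory
#'
#' @param x a `pbpk_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `time_h`, `compartment`, `species`
#'   (`free`/`carrier`/`accumulator`), `concentration_ng_per_ml`.
#' @export
as.data.frame.pbpk_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  nms <- colnames(x$states)
  species <- ifelse(nms %in% c("A_elim", "A_seq"), "accumulator",
                    ifelse(grepl("_np$", nms), "carrier", "free"))
  comp <- sub("_np$", "", nms)
  do.call(rbind, lapply(seq_along(nms), function(j) {
    data.frame(time_h = x$times, compartment = comp[j], species = species[j],
               concentration_ng_per_ml = x$states[, j])
  }))
}

#' Whole-tissue homogenate concentration
#'
#' Volume-weighted mean over the vascular and extravascular sub-compartments,
#' `(V_v C_v + V_ev C_ev [+ carrier pools]) / V_total` — the quantity a
#' homogenised-tissue assay measures (density 1 g/mL, so ng/mL = ng/g).
#'
#' @param traj a `pbpk_trajectory`.
#' @param tissue `"brain"`, `"liver"`, `"spleen"` or `"thymus"`.
#' @param include_carrier_bound include carrier-bound drug (default `TRUE`;
#'   the assay's acid treatment liberates particle-bound drug).
#' @return concentration series, ng/g, over `traj$times`.
#' @export
tissue_total_concentration <- function(traj, tissue,
                                       include_carrier_bound = TRUE) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  if (!tissue %in% .TISSUES) stop("unknown tissue '", tissue, "'")
  ti <- traj$params$tissues[[tissue]]
  tot <- ti$V_v * trajectory_state(traj, paste0(tissue, "_v")) +
    ti$V_ev * trajectory_state(traj, paste0(tissue, "_ev"))
  if (include_carrier_bound &&
      traj$params$formulation$kind == "nanoparticle") {
    tot <- tot + ti$V_v * trajectory_state(traj, paste0(tissue, "_v_np")) +
      ti$V_ev * trajectory_state(traj, paste0(tissue, "_ev_np"))
  }
  tot / ti$V_total
}

#' Model-predicted assay concentration for a sampled matrix
#'
#' Plasma returns `Cp` (plus `Cp_np` when carrier-bound drug is included);
#' tissues delegate to [tissue_total_concentration()].
#'
#' @inheritParams tissue_total_concentration
#' @param tissue `"plasma"` or one of the four sampled tissues.
#' @export
predicted_concentration <- function(traj, tissue,
                                    include_carrier_bound = TRUE) {
  if (tissue == "plasma") {
    out <- trajectory_state(traj, "Cp")
    if (include_carrier_bound &&
        traj$params$formulation$kind == "nanoparticle") {
      out <- out + trajectory_state(traj, "Cp_np")
    }
    out
  } else {
    tissue_total_concentration(traj, tissue, include_carrier_bound)
  }
}

#' Mass-balance audit of a trajectory
#'
#' The printed plasma balance has no return flow from the four named tissues,
#' so the conserved set is plasma + general tissue (free and carrier) plus the
#' cleared (`A_elim`) and sequestered (`A_seq`) accumulators; satellite-tissue
#' amounts are reported separately.  In `mass_conserving_plasma` mode the
#' satellite amounts join the conserved set.
#'
#' @param traj a `pbpk_trajectory`.
#' @param tol relative drift beyond which the audit is flagged.
#' @return data.frame with `time_h`, `conserved_ng`, `satellite_ng`,
#'   `relative_drift`; attributes `max_drift` and `ok`.
#' @export
mass_audit <- function(traj, tol = 1e-4) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  p <- traj$params
  Vd <- p$systemic$Vd_per_kg * traj$dose$BW * 1000
  st <- traj$states
  conserved <- Vd * (st[, "Cp"] + st[, "Cgt"]) + st[, "A_elim"]
  if (p$formulation$kind == "nanoparticle") {
    conserved <- conserved + Vd * (st[, "Cp_np"] + st[, "Cgt_np"]) +
      st[, "A_seq"]
  }
  satellite <- 0
  for (nm in .TISSUES) {
    ti <- p$tissues[[nm]]
    amt <- (ti$V_v * st[, paste0(nm, "_v")] +
            ti$V_ev * st[, paste0(nm, "_ev")]) * 1000
    if (p$formulation$kind == "nanoparticle") {
      amt <- amt + (ti$V_v * st[, paste0(nm, "_v_np")] +
                    ti$V_ev * st[, paste0(nm, "_ev_np")]) * 1000
    }
    satellite <- satellite + amt
  }
  if (isTRUE(traj$solver_meta$mass_conserving_plasma)) {
    conserved <- conserved + satellite
    satellite <- rep(0, length(conserved))
  }
  drift <- conserved / traj$dose$dose_ng - 1
  res <- data.frame(time_h = traj$times, conserved_ng = conserved,
                    satellite_ng = satellite, relative_drift = drift)
  attr(res, "max_drift") <- max(abs(drift))
  attr(res, "ok") <- max(abs(drift)) <= tol
  res
}
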
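#' @importFrom stats coef fitted lm optim rnorm setNames aggregate cor
#' @importFrom utils head tail read.csv write.csv
NULL

# Canonical internal units are ng, mL and h; parameter files and constructors
# take the literature units (L, L/h, L/kg, 1/h) and conversion happens once,
# inside the ODE layer.

.TISSUES <- c("brain", "liver", "spleen", "thymus")

# Vascular volume fractions are not tabulated in the source physiology
# compilations used here; these are implementation defaults, overridable in
# any configuration file.  AUC-ratio identities are exact for any f_vasc.
.DEFAULT_F_VASC <- c(brain = 0.03, liver = 0.21, spleen = 0.22, thymus = 0.03)

#' Per-tissue PBPK parameters
#'
#' A permeability-limited tissue is split into a vascular and an extravascular
#' sub-compartment.  `Q` is the plasma flow perfusing the vascular side,
#' `PS` the permeability-surface area coefficient governing trans-membrane
#' exchange, `P` the tissue/plasma partition coefficient at distribution
#' equilibrium, and `Kup` the first-order nanoparticle uptake rate constant
#' (carrier formulations only; 0 for a free-drug solution).
#'
#' @param name one of `"brain"`, `"liver"`, `"spleen"`, `"thymus"`.
#' @param Q plasma flow, L/h.
#' @param V_total total tissue volume, L.
#' @param f_vasc vascular volume fraction, in (0, 1).
#' @param PS permeability-surface area coefficient, L/h.
#' @param P tissue/plasma partition coefficient (dimensionless).
#' @param Kup nanoparticle uptake rate constant, 1/h.
#' @return a `tissue_params` list with derived sub-compartment volumes
#'   `V_v = f_vasc * V_total` and `V_ev = (1 - f_vasc) * V_total` (L).
#' @export
tissue_params <- function(name, Q, V_total, f_vasc, PS, P, Kup = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% .TISSUES) {
    stop("unknown tissue '", name, "'; expected one of: ",
         paste(.TISSUES, collapse = ", "))
  }
  for (fld in c("Q", "V_total", "f_vasc", "PS", "P", "Kup")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("tissue '", name, "': field '", fld, "' must be a finite number")
    }
  }
  if (Q <= 0) stop("tissue '", name, "': Q must be > 0")
  if (V_total <= 0) stop("tissue '", name, "': V_total must be > 0")
  if (f_vasc <= 0 || f_vasc >= 1) {
    stop("tissue '", name, "': f_vasc must lie strictly in (0, 1)")
  }
  if (PS < 0) stop("tissue '", name, "': PS must be >= 0")
  if (P <= 0) stop("tissue '", name, "': P must be > 0")
  if (Kup < 0) stop("tissue '", name, "': Kup must be >= 0")
  structure(
    list(name = name, Q = Q, V_total = V_total, f_vasc = f_vasc,
         PS = PS, P = P, Kup = Kup,
         # V_ev by difference so the two sub-volumes sum to V_total exactly
         V_v = f_vasc * V_total, V_ev = V_total - f_vasc * V_total),
    class = "tissue_params")
}

#' Systemic (plasma + general tissue) parameters
#'
#' The general-tissue compartment lumps every non-sampled tissue; it exchanges
#' free drug with plasma through the plasma flow `Qp` and a partition
#' coefficient `Pgt`.  Elimination is free-drug plasma clearance `Cl`.
#' `Vd_per_kg` is the apparent distribution volume, used both as the plasma
#' mixing volume and as the general-tissue volume.
#'
#' @param Qp plasma flow to general tissue, L/h.
#' @param Cl plasma clearance, L/h.
#' @param Vd_per_kg apparent distribution volume, L/kg.
#' @param BW body weight, kg.
#' @param Pgt general-tissue partition coefficient. Not identifiable from
#'   physiology alone; defaults to 1 and is normally estimated from plasma
#'   data (see [fit_pbpk()]).
#' @param Kup_plasma plasma-phase nanoparticle uptake (sequestration) rate
#'   constant, 1/h; 0 for a solution formulation.
#' @return a `systemic_params` list; `Vd_L = Vd_per_kg * BW` is derived.
#' @export
systemic_params <- function(Qp, Cl, Vd_per_kg, BW, Pgt = 1, Kup_plasma = 0) {
  vals <- c(Qp = Qp, Cl = Cl, Vd_per_kg = Vd_per_kg, BW = BW, Pgt = Pgt)
  if (!all(is.finite(vals)) || !is.finite(Kup_plasma)) {
    stop("systemic parameters must all be finite numbers")
  }
  bad <- names(vals)[vals <= 0]
  if (length(bad)) {
    stop("systemic parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  }
  if (Kup_plasma < 0) stop("Kup_plasma must be >= 0")
  structure(
    list(Qp = Qp, Cl = Cl, Vd_per_kg = Vd_per_kg, BW = BW,
         Vd_L = Vd_per_kg * BW, Pgt = Pgt, Kup_plasma = Kup_plasma),
    class = "systemic_params")
}

#' Formulation parameters
#'
#' @param kind `"solution"` (free drug) or `"nanoparticle"` (drug surface-bound
#'   to a 40 nm gold carrier).
#' @param Krel first-order carrier release rate constant, 1/h. Required for
#'   the nanoparticle kind; the release study estimate at physiological pH
#'   (7.4) is used throughout the body.
#' @param loading_fraction fraction of the administered dose that is
#'   carrier-bound at t = 0. Default 1 (the whole dose enters the carrier-bound
#'   plasma pool at the bolus).
#' @export
formulation_params <- function(kind = c("solution", "nanoparticle"),
                               Krel = NULL, loading_fraction = 1) {
  kind <- match.arg(kind)
  if (kind == "nanoparticle") {
    if (is.null(Krel) || !is.finite(Krel) || Krel <= 0) {
      stop("nanoparticle formulation requires Krel > 0")
    }
    if (loading_fraction < 0 || loading_fraction > 1) {
      stop("loading_fraction must lie in [0, 1]")
    }
  } else {
    if (!is.null(Krel)) {
      stop("carrier field 'Krel' must not be set for a solution formulation")
    }
    Krel <- 0
    loading_fraction <- 0
  }
  structure(list(kind = kind, Krel = Krel,
                 loading_fraction = loading_fraction),
            class = "formulation_params")
}

#' Assemble a full PBPK parameter set
#'
#' @param systemic a [systemic_params()] object.
#' @param tissues named list of [tissue_params()] for brain, liver, spleen and
#'   thymus (the general tissue lives in `systemic`).
#' @param formulation a [formulation_params()] object.
#' @param group_label free-text label for the formulation group.
#' @return a validated `pbpk_parameters` object.
#' @export
pbpk_parameters <- function(systemic, tissues, formulation,
                            group_label = formulation$kind) {
  stopifnot(inherits(systemic, "systemic_params"),
            inherits(formulation, "formulation_params"))
  missing <- setdiff(.TISSUES, names(tissues))
  if (length(missing)) {
    stop("missing tissue(s): ", paste(missing, collapse = ", "))
  }
  tissues <- tissues[.TISSUES]
  for (ti in tissues) stopifnot(inherits(ti, "tissue_params"))
  if (formulation$kind == "solution") {
    kups <- vapply(tissues, `[[`, numeric(1), "Kup")
    if (any(kups != 0) || systemic$Kup_plasma != 0) {
      stop("carrier fields (Kup, Kup_plasma) must not be set for a ",
           "solution formulation")
    }
  }
  structure(list(systemic = systemic, tissues = tissues,
                 formulation = formulation,
                 group_label = as.character(group_label)),
            class = "pbpk_parameters")
}

#' @export
print.pbpk_parameters <- function(x, ...) {
  s <- x$systemic
  cat("<pbpk_parameters> group:", x$group_label,
      "| formulation:", x$formulation$kind, "\n")
  cat(sprintf("  systemic: Qp=%.3g L/h  Cl=%.3g L/h  Vd=%.3g L/kg  BW=%.3g kg  Pgt=%.3g\n",
              s$Qp, s$Cl, s$Vd_per_kg, s$BW, s$Pgt))
  if (x$formulation$kind == "nanoparticle") {
    cat(sprintf("  carrier: Krel=%.3g 1/h  Kup_plasma=%.3g 1/h  loading=%.3g\n",
                x$formulation$Krel, s$Kup_plasma, x$formulation$loading_fraction))
  }
  for (ti in x$tissues) {
    cat(sprintf("  %-7s Q=%.3g L/h  V=%.3g L  f_vasc=%.2f  PS=%.3g L/h  P=%.2f  Kup=%.3g 1/h\n",
                ti$name, ti$Q, ti$V_total, ti$f_vasc, ti$PS, ti$P, ti$Kup))
  }
  invisible(x)
}

# Reference parameter table for a 250 g rat.  Physiology (Q, V) is shared by
# the two formulation groups; PS, P, Kup and the systemic disposition differ.
.TABLE_RAT <- list(
  Qp = 3.09, BW_ref = 0.250,
  solution = list(
    Cl = 0.46, Vd = 1.84,
    tissues = list(
      brain  = list(Q = 0.08, V = 1.5e-3, PS = 3.75e-7, P = 0.36),
      liver  = list(Q = 0.60, V = 1.2e-2, PS = 2.65e-6, P = 0.27),
      spleen = list(Q = 0.18, V = 7.0e-4, PS = 7.50e-6, P = 0.70),
      thymus = list(Q = 0.02, V = 5.0e-4, PS = 9.62e-8, P = 0.28))),
  nanoparticle = list(
    Cl = 0.73, Vd = 2.92, Krel = 0.058, Kup_plasma = 0.56,
    tissues = list(
      brain  = list(Q = 0.08, V = 1.5e-3, PS = 0.17,    P = 0.46, Kup = 7.9e-3),
      liver  = list(Q = 0.60, V = 1.2e-2, PS = 14.4,    P = 0.55, Kup = 0.15),
      spleen = list(Q = 0.18, V = 7.0e-4, PS = 0.49,    P = 0.77, Kup = 0.03),
      thymus = list(Q = 0.02, V = 5.0e-4, PS = 0.10,    P = 0.61, Kup = 1.00e-3))))

#' Reference rat parameter sets
#'
#' Returns the full PBPK parameter set for a 250 g rat for one of the two
#' formulation groups: free stavudine in solution, or stavudine bound to a
#' 40 nm gold-nanoparticle carrier.  Systemic clearance and distribution
#' volume come from model-independent analysis of the in vivo study
#' (solution: Cl 0.46 L/h, Vd 1.84 L/kg; carrier: Cl 0.73 L/h, Vd 2.92 L/kg);
#' tissue PS and Kup are the optimised estimates; the carrier release constant
#' is the pH 7.4 in vitro value, Krel = 0.058 1/h.
#'
#' @param group `"solution"` or `"nanoparticle"`.
#' @param BW body weight in kg; default 0.250 (the reference weight of the
#'   parameter table). The in vivo study mean weight was 0.252 kg.
#' @param Pgt general-tissue partition coefficient; 1 by default (estimated
#'   from plasma data in the original analysis but never tabulated).
#' @return a `pbpk_parameters` object.
#' @export
default_rat_parameters <- function(group = c("solution", "nanoparticle"),
                                   BW = 0.250, Pgt = 1) {
  group <- match.arg(group)
  tab <- .TABLE_RAT[[group]]
  sys <- systemic_params(
    Qp = .TABLE_RAT$Qp, Cl = tab$Cl, Vd_per_kg = tab$Vd, BW = BW, Pgt = Pgt,
    Kup_plasma = if (group == "nanoparticle") tab$Kup_plasma else 0)
  tis <- lapply(names(tab$tissues), function(nm) {
    r <- tab$tissues[[nm]]
    tissue_params(nm, Q = r$Q, V_total = r$V,
                  f_vasc = .DEFAULT_F_VASC[[nm]],
                  PS = r$PS, P = r$P,
                  Kup = if (is.null(r$Kup)) 0 else r$Kup)
  })
  names(tis) <- names(tab$tissues)
  form <- if (group == "nanoparticle") {
    formulation_params("nanoparticle", Krel = tab$Krel)
  } else {
    formulation_params("solution")
  }
  pbpk_parameters(sys, tis, form, group_label = group)
}

#' Dosing specification
#'
#' The intraperitoneal administration of the in vivo study is modelled as an
#' instantaneous bolus into plasma (solution group) or into the carrier-bound
#' plasma pool (nanoparticle group).
#'
#' @param dose_per_kg dose, mg/kg. Study means: 11.9 (solution),
#'   15.6 (nanoparticle).
#' @param BW body weight, kg; study mean 0.252.
#' @return a `dose_spec` with the derived total dose in ng
#'   (`dose_ng = dose_per_kg * BW * 1e6`).
#' @export
dose_spec <- function(dose_per_kg, BW = 0.252) {
  stopifnot(is.finite(dose_per_kg), is.finite(BW))
  if (dose_per_kg <= 0 || BW <= 0) stop("dose_per_kg and BW must be > 0")
  structure(list(dose_per_kg = dose_per_kg, BW = BW,
                 dose_ng = dose_per_kg * BW * 1e6,
                 route = "instantaneous_bolus"),
            class = "dose_spec")
}

#' Read a PBPK parameter configuration
#'
#' Reads a YAML or JSON file with top-level keys `systemic`, `tissues` (a map
#' keyed by tissue name), `formulation` and `group_label`, in the literature
#' units (L, L/h, L/kg, 1/h).  Missing `f_vasc` entries are filled from the
#' package defaults; every invariant is checked on construction.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `pbpk_parameters` object.
#' @seealso [write_parameters()] for the inverse; a fixture transcribing the
#'   reference rat table ships in `system.file("extdata", package = "stavupbpk")`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("systemic", "tissues", "formulation")) {
    if (is.null(cfg[[key]])) stop("config is missing top-level key '", key, "'")
  }
  s <- cfg$systemic
  f <- cfg$formulation
  kind <- f$kind
  if (is.null(kind)) stop("formulation must name its 'kind'")
  sys <- systemic_params(
    Qp = s$Qp, Cl = s$Cl, Vd_per_kg = s$Vd_per_kg, BW = s$BW,
    Pgt = if (is.null(s$Pgt)) 1 else s$Pgt,
    Kup_plasma = if (is.null(s$Kup_plasma)) 0 else s$Kup_plasma)
  if (kind == "solution" && !is.null(s$Kup_plasma) && s$Kup_plasma != 0) {
    stop("carrier field 'Kup_plasma' must not be set for a solution config")
  }
  tis <- lapply(names(cfg$tissues), function(nm) {
    r <- cfg$tissues[[nm]]
    tissue_params(
      nm, Q = r$Q, V_total = r$V_total,
      f_vasc = if (is.null(r$f_vasc)) .DEFAULT_F_VASC[[nm]] else r$f_vasc,
      PS = r$PS, P = r$P,
      Kup = if (is.null(r$Kup)) 0 else r$Kup)
  })
  names(tis) <- names(cfg$tissues)
  if (kind == "solution") {
    set <- names(cfg$tissues)[vapply(cfg$tissues,
                                     function(r) !is.null(r$Kup) && r$Kup != 0,
                                     logical(1))]
    if (length(set)) {
      stop("carrier field 'Kup' must not be set for a solution config ",
           "(tissue: ", paste(set, collapse = ", "), ")")
    }
  }
  form <- formulation_params(
    kind,
    Krel = f$Krel,
    loading_fraction = if (is.null(f$loading_fraction)) 1 else f$loading_fraction)
  pbpk_parameters(sys, tis, form,
                  group_label = if (is.null(cfg$group_label)) kind else cfg$group_label)
}

#' Write a PBPK parameter configuration
#'
#' Serialises a `pbpk_parameters` object to YAML or JSON in the same layout
#' [load_parameters()] reads, so that a write-then-read round trip returns an
#' identical object.
#'
#' @param params a `pbpk_parameters` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "pbpk_parameters"))
  s <- params$systemic
  cfg <- list(
    group_label = params$group_label,
    systemic = list(Qp = s$Qp, Cl = s$Cl, Vd_per_kg = s$Vd_per_kg, BW = s$BW,
                    Pgt = s$Pgt, Kup_plasma = s$Kup_plasma),
    tissues = lapply(params$tissues, function(ti) {
      list(Q = ti$Q, V_total = ti$V_total, f_vasc = ti$f_vasc,
           PS = ti$PS, P = ti$P, Kup = ti$Kup)
    }),
    formulation = list(kind = params$formulation$kind,
                       Krel = params$formulation$Krel,
                       loading_fraction = params$formulation$loading_fraction))
  if (cfg$formulation$kind == "solution") {
    cfg$formulation$Krel <- NULL
    cfg$systemic$Kup_plasma <- NULL
    cfg$tissues <- lapply(cfg$tissues, function(ti) { ti$Kup <- NULL; ti })
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}
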
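---
title: "Methods: a permeability-limited PBPK model for stavudine and its gold-nanoparticle carrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a permeability-limited PBPK model for stavudine and its gold-nanoparticle carrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stavupbpk)
```

## The problem

Stavudine is a hydrophilic antiretroviral with a very short half-life and
poor penetration into the macrophage-rich tissues (liver, spleen) where HIV
persists. Binding the drug to the surface of a 40 nm citrate-stabilised gold
nanoparticle changes its biodistribution: macrophages internalise the
carrier avidly, so carrier-bound drug accumulates in reticuloendothelial
tissues and is released there over time. This package implements a
whole-body physiologically based pharmacokinetic (PBPK) model for the rat
that quantifies that change, together with the analysis pipeline around it:
in vitro release/uptake kinetic fitting, model-independent (non-compartmental)
analysis, naive-pooled parameter estimation, fold-error validation, and a
virtual-study generator.

## Model structure

Both formulations share one skeleton: plasma, a lumped **general tissue**
(everything not sampled), and four sampled tissues — brain, liver, spleen,
thymus. Every tissue is **permeability rate-limited**: it is split into a
vascular sub-compartment (volume $V_v = f_{vasc} V$) perfused by plasma flow
$Q$, and an extravascular sub-compartment ($V_{ev} = V - V_v$) that
exchanges with the vascular side only through a permeability–surface area
coefficient $PS$ against the partition-coefficient gradient:

$$V_v \frac{dC_v}{dt} = Q\,(C_p - C_v) + PS\left(\frac{C_{ev}}{P} - C_v\right),
\qquad
V_{ev} \frac{dC_{ev}}{dt} = PS\left(C_v - \frac{C_{ev}}{P}\right).$$

Plasma exchanges free drug with the general tissue through $Q_p$ and a
general-tissue partition coefficient $P_{gt}$, and loses drug by first-order
clearance $Cl$; the apparent distribution volume $V_d$ serves as both the
plasma mixing volume and the general-tissue volume:

$$V_d \frac{dC_p}{dt} = Q_p\left(\frac{C_{gt}}{P_{gt}} - C_p\right) - Cl\,C_p.$$

The carrier model duplicates every pool for carrier-bound drug. Carrier
releases free drug everywhere at the single first-order rate $K_{rel}$
(the in vitro estimate at physiological pH 7.4 — the environment of both
sub-compartments; endosomal acidity is not modelled). Tissue uptake moves
carrier from the vascular to the extravascular pool at a per-tissue
first-order rate $K_{up}$, and a plasma-phase uptake constant removes
carrier irreversibly from circulation. The intraperitoneal dose is treated
as an instantaneous bolus: the whole dose appears at $t=0$ in plasma
(solution) or in the carrier-bound plasma pool (carrier,
`loading_fraction = 1` by default).

### Deliberate structural choices

Three points in the printed equation set required a decision; all three are
implemented as stated below and are exercised by the test suite.

* **Satellite tissues.** The plasma balance contains no return flow from
  the four named tissues, so they are driven compartments that do not
  deplete plasma. We implement this literally, because adding return flows
  changes every simulated concentration. `mass_audit()` therefore reports a
  *conserved set* (plasma + general tissue + accumulators), which closes to
  $10^{-4}$ relative, and the satellite amounts separately. An optional
  `mass_conserving_plasma` mode adds the return terms for sensitivity
  analysis; it is not the default.
* **Units of the uptake term.** A first-order rate constant in 1/h must act
  on an amount to give a mass flux. The tissue uptake flux is implemented
  as $J = K_{up} C_{v}^{np} V_v$ (ng/h), removed from the vascular carrier
  pool and added to the extravascular carrier pool, which preserves the
  first-order in vitro kinetics and makes tissue mass auditable. The plasma
  uptake flux $K_{up,p} C_p^{np} V_d$ has no printed destination and is
  booked as irreversible sequestration in the `A_seq` accumulator.
* **General-tissue volume.** The general-tissue pools use $V_d$ as their
  volume, as printed.

No exocytosis term is included (anionic 40 nm gold particles exocytose
slowly from macrophages), and clearance acts on free drug only.

## Parameters

`default_rat_parameters()` ships the reference set for a 250 g rat.
Solution group: $Q_p$ 3.09 L/h, $Cl$ 0.46 L/h, $V_d$ 1.84 L/kg; carrier
group: $Cl$ 0.73 L/h, $V_d$ 2.92 L/kg, $K_{rel}$ 0.058 1/h, plasma uptake
0.56 1/h; per-tissue $Q$, $V$, $PS$, $P$, $K_{up}$ as tabulated. Two
parameters are package defaults rather than literature values and are
flagged as such wherever they appear:

* **Vascular fractions** $f_{vasc}$ (brain 0.03, liver 0.21, spleen 0.22,
  thymus 0.03) — plausible rat values, overridable in every configuration
  file. The package's AUC-ratio identities are exact for any $f_{vasc}$,
  so none of the headline checks depends on them.
* **$P_{gt} = 1$** — the general-tissue partition coefficient was estimated
  from plasma data in the original analysis and never tabulated; 1 is a
  neutral default and `fit_pbpk()` estimates it from plasma profiles.

Internal canonical units are ng, mL and h; configurations are written in
the literature units (L, L/h, L/kg, 1/h), and a tissue density of 1 g/mL
makes ng/g and ng/mL interchangeable for homogenate concentrations. The
reference body weight of the parameter table is 0.250 kg; the in vivo
study's mean weight, 0.252 kg, is the default of `dose_spec()` and of the
virtual-study design.

## Numerics

Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-9`,
`atol = 1e-3` ng/mL, on a grid dense over the first day (`output_grid()`:
0.005 h steps to 1 h, 0.05 h to 24 h, 0.5 h beyond). Halving the tolerances
moves reported AUCs by far less than 0.1%. States are clipped at zero only
below $10^{-6}$ of the peak; anything worse errors out.

**AUC to infinity.** The partition coefficient is defined as the ratio of
tissue to plasma $AUC_0^\infty$. With the tabulated solution-group $PS$
values the extravascular pools equilibrate on a 100–1000 h scale, so a
truncated trapezoid AUC at any practical horizon badly underestimates the
tissue area. `trajectory_auc()` and `nca_profile()` therefore add the
standard terminal extrapolation $C_{last}/\lambda_z$, with $\lambda_z$ from
an unweighted log-linear regression. On a 200 h horizon this reproduces the
configured $P$ to better than 0.5% for every tissue (exactly the analytic
identity $AUC(C_{ev})/AUC(C_p) = P$ obtained by integrating the tissue
balances to infinity).

**Terminal-window selection.** For sparse profiles the $\lambda_z$ window
is chosen by the standard best-adjusted-$R^2$ rule over candidate windows
of at least 3 points ending at the last observation and starting after the
maximum; ties go to the longer window. Dense simulated profiles use a fixed
tail (the last 10% of the horizon). The linear trapezoid is used throughout;
$V_d$ is reported as $V_z = Cl/\lambda_z$ (per kg), the convention under
which the printed clearance/volume pairs and plasma half-lives are mutually
consistent ($t_{1/2} = \ln 2 \cdot V_d \cdot BW / Cl = 0.70$ h for the
carrier group at 252 g); $V_{ss} = Cl \cdot MRT$ is reported as a secondary
field.

**Below-LOQ handling.** Records under the 1 ng/mL quantification limit are
kept but flagged, and dropped (not zero-imputed) from naive-pooled means;
a nominal time where every record is censored is dropped with a warning.
Destructive sampling with five time points makes anything more elaborate
unstable.

## In vitro kinetic fitting

Release profiles are fitted by least squares on untransformed percentages
to zero-order ($k_0 t$), first-order ($100(1-e^{-K_{rel}t})$) and, for
burst profiles, $B + (100-B)(1-e^{-K_{rel}t})$ candidates; selection is by
small-sample-corrected Gaussian AIC (falling back to plain AIC when the
correction denominator vanishes at $n = k + 1$, which happens for
two-parameter candidates at the four-point designs). Uptake fits include a
plateau $U_{max}$ because internalisation cannot exceed the added amount;
only the rate constant is carried into the PBPK model. On noise-free data
at the studies' sampling times (release 1, 24, 48, 72 h; uptake 1, 6, 24,
48 h) the fitted constants match the generating values (0.058, 0.026,
0.564 1/h) to $10^{-6}$.

## Estimation and validation

Estimation is **naive-pooled**: all animals of a group are averaged per
nominal time (each contributes a single destructive sample) and the pooled
profile is treated as one subject. `fit_pbpk()` minimises squared residuals
— on log concentrations by default, matching the fold-error metrics and the
data's dynamic range — over free parameters addressed by path (e.g.
`tissues.liver.Kup`), with BFGS on log-transformed parameters. Because the
in vitro initial estimate (0.564 1/h) can sit far from a tissue's optimum
across a flat, noisy objective, a cheap pre-search precedes the BFGS
polish: a log-scale scan for one free parameter, Nelder-Mead for several.
The per-tissue sequential strategy (each tissue's constants against its own
profile, $P_{gt}$ against plasma) is the default; passing several tissues
fits jointly.

Validation pairs each above-LOQ observation with the model's homogenate
prediction at its nominal time and reports per-tissue average fold error
$AFE = 10^{\frac{1}{n}\sum \log_{10}(pred/obs)}$ (bias) and absolute
average fold error $AAFE = 10^{\frac{1}{n}\sum |\log_{10}(pred/obs)|}$
(precision), plus the overall log–log correlation. The 2-fold band
$[0.5, 2]$ is inclusive at both ends.

## The virtual-study generator

The raw animal data behind the original analysis are not deposited, so
`generate_in_vivo()` emulates the in vivo design: 2 formulation groups,
destructive sampling at 1, 3, 6, 12, 24 h, plasma plus four tissues from
each animal, doses 11.9 / 15.6 mg/kg, body weight Normal(252, 12) g
truncated positive, LOQ 1 ng/mL. Noise is multiplicative lognormal; the
defaults — CV 0.30 in vivo (biological plus assay variability; the assay
alone is ~15% for biological matrices), 0.05 in vitro — are implementation
choices, stated once here and not tuned. Four animals per time per group
(40 total) is the package default, bracketing the study's 38 animals.

What the generator deliberately does *not* emulate: inter-animal
variability in physiology ($Q$, $V$, $PS$ have no population model),
intraperitoneal absorption kinetics, and dose jitter (group mean doses are
used). Passing tests on synthetic data therefore demonstrate that the
pipeline inverts its own generative assumptions — parameter recovery,
self-consistent validation, correct metric arithmetic — not that the model
describes any particular animal dataset. The printed in vivo results (the
tabulated AUC/MRT values, the fold errors of the original fit, the
observed–predicted correlation of 0.76) depend on those unpublished data
and are not desk-reproducible; the corresponding package checks are
structural: mass balance closes to $10^{-4}$, the carrier system
degenerates to the free-drug system when release and uptake vanish,
noise-free recovery returns the tabulated optimised constants within 5%,
and at 30% CV the per-tissue AFE stays inside the 2-fold band in ≥90% of
seeded replicates.

## Known limitations

* Sparse-design NCA is biased: with five destructive time points and no
  back-extrapolation to $t=0$, plasma clearance is overestimated and
  slowly-equilibrating tissue AUCs are underestimated — visible in the
  virtual-study NCA tables and one reason printed in vivo values cannot be
  checked to printed precision.
* Spleen $PS$ (carrier group) is practically non-identifiable from spleen
  homogenate totals: carrier-bound pools dominate the signal and the
  objective is flat in $PS$. The uptake constant is well identified.
* The worked problem sizes (200 h horizons, 20-replicate properties,
  10-seed noise studies) were chosen to make every identity check tight at
  interactive runtimes; all are parameters of the corresponding functions.

## A worked example

```{r example, eval = FALSE}
params <- default_rat_parameters("solution", BW = 0.252)
dose <- dose_spec(11.9, BW = 0.252)
traj <- simulate_pbpk(params, dose, output_times = output_grid(200))
trajectory_auc(traj, "liver_ev") / trajectory_auc(traj, "Cp")
#> [1] 0.2699881   # the configured liver partition coefficient, 0.27
```

The numbered scripts under `analysis/` run the full workflow —
in vitro fits, biodistribution simulation, virtual-study NCA, parameter
recovery, fold-error validation — and write their tables under `results/`.
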
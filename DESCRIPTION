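Package: stavupbpk
Title: Physiologically Based Pharmacokinetics of Stavudine Gold-Nanoparticle
    Delivery in Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) modelling
    of stavudine biodistribution in rats after bolus administration either as a
    free-drug solution or bound to a 40 nm gold-nanoparticle carrier. Provides
    the two permeability-limited compartmental ODE systems (plasma, general
    tissue, and vascular/extravascular sub-compartments for brain, liver,
    spleen and thymus), first-order carrier release and tissue uptake kinetics,
    in vitro release/uptake curve fitting with model selection, model-independent
    (non-compartmental) analysis of concentration-time data, naive-pooled
    quasi-Newton parameter estimation, fold-error model validation (AFE/AAFE),
    and a virtual-study generator emulating the destructive-sampling in vivo
    design so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
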
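Package: cimipkpd
Title: Pharmacokinetic/Pharmacodynamic Dose Determination for a Canine Coxib
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pharmacometric pipeline for determining an oral dosing regimen
    of cimicoxib, a COX-2 selective non-steroidal anti-inflammatory drug, in
    the dog. Implements closed-form one-compartment oral absorption
    (Bateman) pharmacokinetics with lag time, iteratively reweighted
    polyexponential fitting with AIC model selection, intravenous
    non-compartmental analysis, sparse-sampling terminal half-life
    estimation, four indirect-response (turnover) pharmacodynamic models
    driven by individual plasma concentration curves, dose-effect simulation
    over an oral dose grid for regimen selection, metabolizer-subpopulation
    classification and comparison, breed half-life ANOVA, and a synthetic
    cohort generator emulating a two-study canine design so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
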
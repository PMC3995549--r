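Package: hdpkdose
Title: Simulation-Based Dose Selection for Pharmacokinetic Studies in
    Hemodialysis Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to plan pharmacokinetic (PK) studies in hemodialysis
    patients from a safe subpharmacological dose.  Implements
    non-compartmental analysis (linear trapezoidal AUC, Cmax/Tmax,
    apparent oral clearance, recovery-method dialytic clearance),
    dose-proportionality assessment via the power model with a
    confidence-interval gate and Kruskal-Wallis comparison of
    dose-normalized parameters, nonparametric superposition to predict
    exposure at untested doses, inversion of the dose-exposure curve to
    the dose achieving a target metabolite AUC, and validation of the
    predictions against observed profiles.  A synthetic study generator
    simulates a prodrug/active-metabolite system with intermittent
    dialytic clearance and serves as ground truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
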
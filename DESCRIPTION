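Package: hptsim
Title: Personalized Simulation of Thyroid Hormone Regulation and Replacement Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic compartmental model of the hypothalamic-pituitary-thyroid
    axis, personalized with a patient's sex, height and body weight through
    anthropometric plasma and TSH distribution volumes and allometric T3
    clearance scaling. Simulates plasma T4, T3 and TSH dynamics under oral
    levothyroxine (LT4) and liothyronine (LT3) regimens including constant T3
    infusion, optimizes mono- and combination-therapy doses against
    normal-range targets by deterministic grid search, computes steady-state
    hormone curves versus residual thyroid function (RTF) with inverse RTF
    estimation, and fits model parameters to hormone time courses by maximum
    likelihood with inverse-Hessian variability estimates. Includes synthetic
    data generators for cohorts, blood-volume scatter and noisy hormone time
    courses so that every component is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
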
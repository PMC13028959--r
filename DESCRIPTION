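Package: dapasim
Title: Whole-Body PBPK/PD Simulation of Dapagliflozin and Its Glucuronide
    Metabolite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic whole-body physiologically based
    pharmacokinetic/pharmacodynamic (PBPK/PD) model of the SGLT2 inhibitor
    dapagliflozin and its major metabolite dapagliflozin-3-O-glucuronide.
    Couples flow-limited organ disposition with Michaelis-Menten UGT1A9
    glucuronidation in liver and kidney, first-order renal excretion, and a
    renal-glucose-threshold pharmacodynamic model of urinary glucose
    excretion. Provides scenario simulation with dose events, scans over
    dose, renal and hepatic impairment and prandial state, non-compartmental
    analysis, local normalized sensitivity analysis with single-linkage
    clustering, multistart weighted least-squares calibration, a seeded
    synthetic clinical-study generator, and flat SBML export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
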
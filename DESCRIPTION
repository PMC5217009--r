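Package: crcscreen
Title: Markov Modelling of Long-Term Colorectal Cancer Screening Effects
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic five-state Markov cohort model of the
    adenoma-carcinoma sequence (no neoplasm, nonadvanced adenoma, advanced
    adenoma, preclinical colorectal cancer, diagnosed colorectal cancer)
    with annual cycles, competing general-population mortality via period
    life tables, and screening-colonoscopy interventions. Projects
    cumulative colorectal cancer incidence over up to 25 years of follow-up
    for screened and unscreened cohorts, derives relative risks and risk
    differences by follow-up year, and runs deterministic sensitivity
    sweeps over the confidence bounds of the transition rates. Ships
    registry-derived baseline prevalence counts and sex- and age-specific
    annual transition rates as packaged fixtures, plus generators for
    synthetic registry count tables and Gompertz-type life tables so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
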
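Package: hfscores
Title: Multi-Site Heart Failure Risk Score Pipeline on Harmonized Routine Data
Version: 0.1.0
Authors@R:
    person("HF Scores", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Ingests openEHR-template-shaped clinical tables from multiple
    hospital sites, harmonizes them (partial-date completion, closest-record
    selection, medication-group mapping, pseudonymization), applies
    plausibility range checks that convert implausible values to missing,
    evaluates declarative heart-failure mortality risk scores (an additive
    points score with stratified lookup tables in the style of MAGGIC, and a
    Cox linear-predictor survival score with reference-value imputation in
    the style of the Barcelona Bio-HF v1 calculator), and compares score
    distributions across sites with rank tests and a permutation-based
    conditional inference tree. Ships a seeded synthetic multi-site cohort
    generator with configurable missingness, inpatient/outpatient mix and
    reduced date precision for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
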
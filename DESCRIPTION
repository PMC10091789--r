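Package: pgxtwist
Title: Pharmacogenetic Outcome Scans and Genetically Moderated Treatment
    Effects from Primary-Care Prescribing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pharmacogenetic outcome studies of
    dihydropyridine calcium-channel blocker (dCCB) users in linked
    primary-care data. Builds treatment exposure episodes from dated
    prescription records, ascertains incident diagnoses from coded health
    records, runs per-variant Cox proportional-hazards association scans
    with Benjamini-Hochberg correction, estimates the genetically moderated
    treatment effect (GMTE) with the TWIST triangulation framework on
    constant-coefficient (Lin-Ying) additive-hazards models, and translates
    per-year hazard differences into avoidable-diagnosis counts. Ships a
    fully synthetic cohort generator emulating the statistical structure of
    UK primary-care prescribing data so the whole pipeline is testable
    without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
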
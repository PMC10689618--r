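Package: phagoscreen
Title: Phagocytosis Plate-Screen Analysis and Drug-Repurposing Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content astrocyte phagocytosis
    screens and downstream drug-repurposing evidence. Normalizes 384-well
    red:green (pHrodo:calcein) intensities to percent of the plate median,
    flags toxic wells, classifies compound dose series into increase /
    decrease / toxic categories and fits four-parameter logistic
    dose-response curves; builds drug-network phenotype presence matrices,
    clusters drugs on one-hot gene encodings and ranks genes per effect
    group by ridge logistic regression; computes two-list hypergeometric
    term enrichment with fold enrichment and Benjamini-Hochberg FDR; and
    emulates an observational cohort study (propensity scores, stabilized
    inverse-probability weighting, caliper matching and a weighted Cox
    partial-likelihood fitter with robust variance). Seeded synthetic-data
    generators with planted ground truth make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
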
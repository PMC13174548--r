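Package: synscreen
Title: Quantitative High-Throughput Screening, Dose-Matrix Synergy and
    Set-Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative high-throughput drug
    screens in cancer cell models. Normalizes raw plate luminescence to
    control-anchored percent viability, fits four-parameter logistic
    dose-response curves, scores single-agent activity by dose-averaged
    viability (AUC) and its library-wide Z-transform (Z-AUC), and ranks
    compounds across cell models. Scores two-drug dose matrices against
    the Highest-Single-Agent reference (Excess HSA), calls synergy hits,
    clusters combination profiles and traces time-course synergy.
    Provides preranked permutation-based set enrichment (drug-target
    sets on activity ranks, gene sets on proteomics rank metrics),
    replicate differential-abundance filtering, leading-edge and
    overlap/exclusivity analysis, and gene-signature quartile scoring.
    Includes seeded synthetic-data generators for every input type so
    the full pipeline is testable without raw screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
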
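Package: CINspect
Title: Single-Cell Karyotype Instability Scoring, Copy-Number Curation and
    Mitotic Interactome Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromosomal instability from shallow single-cell
    whole-genome sequencing: GC correction of binned read counts, dual
    change-point copy-number calling (recursive binary t-segmentation and
    e-divisive energy segmentation) with concordance-based curation and
    read-depth library QC, and the aneuploidy, heterogeneity and structural
    instability scores of a curated cell population. Also implements a
    label-free spectral-count pipeline for FLAG-IP interactome data
    (replicate QC against a histone H4 anchor, empty-vector background
    subtraction, anchor normalization and unique/common/enriched interactor
    classification) and rank-sum comparison of autosomal copy-number
    aberration burden between tumor subtype cohorts. Ships seeded synthetic
    generators for cell populations, binned read counts, spectral-count
    tables and cohort burden tables so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
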
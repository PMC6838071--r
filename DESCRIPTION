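Package: pdcscreen
Title: Pharmacogenomic Biomarker Discovery with Patient-Derived Cancer Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain used to
    discover genomic predictors of targeted-drug sensitivity in patient-derived
    cancer cell line (PDC) panels: somatic variant filtering with explicit
    tumor/normal criteria, tumor/normal read-depth copy-number calling with
    GC correction, BIC-penalised segmentation and gene-level gain/loss calls,
    four-parameter logistic dose-response fitting with censoring-aware IC50
    derivation, a drug-by-genotype association screen with group-size and
    false-discovery-rate rules and FDR-gap candidate selection, and supporting
    cohort statistics (recurrence, co-occurrence, Kaplan-Meier/log-rank,
    exact Wilcoxon rank-sum, Z-score normalization). A synthetic-data module
    generates every pipeline input with known ground truth so the whole chain
    is exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
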
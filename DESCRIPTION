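Package: neodeplete
Title: Quantifying Immune Counterselection of Somatic Mutations in
    MHC-Displayed Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the depletion of somatic missense mutations inside
    peptides predicted to be displayed by MHC class I receptors, stratified by
    gene expression level and by the number of displaying HLA allele copies
    carried by each patient (D0/D1/D2). Implements residue-level display masks
    from strong-binder 9-mer predictions, expression quantile stratification,
    opportunity-adjusted mutation density ratios with Fisher's exact tests, a
    sequence-composition correction using undetectably expressed genes as a
    negative control, patient-level bootstrap confidence intervals, and the
    implied immune-clearance rate. Ships a seed-deterministic synthetic cohort
    generator so the whole pipeline is testable without access to tumor
    sequencing consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
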
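Package: metatrio
Title: Stratified Somatic Variant Analysis of Tumor-Metastasis Trios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for matched normal/primary-tumor/metastasis
    ("trio") whole-genome somatic variant data. Stratifies somatic SNVs into
    truncal (shared), tumor-private and metastasis-private sets using mutant
    allele fraction cross-rescue between the paired tumor and metastasis,
    rescues variants mislabelled germline due to tumor-in-normal
    contamination by clustering B-allele frequencies (TiNDA), decomposes
    per-stratum 96-context mutational catalogs against a signature matrix by
    non-negative least squares with signature-specific cutoffs and
    cohort-level detection, detects kataegis loci, calls gain/loss/LOH
    copy-number states relative to sample base ploidy with arm-level
    recurrence summaries, and computes cohort-level recurrence,
    mutual-exclusivity and enrichment statistics. A synthetic-data module
    generates trio cohorts with known truth labels so every stage is
    verifiable without access to controlled sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
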
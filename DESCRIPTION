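Package: her2landscape
Title: Genomic Comparison of HER2-Low and HER2-0 Breast Tumors from
    Tumor-Only Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the somatic genomic landscape of HER2-low
    (IHC 1+ or 2+/ISH-negative) and HER2-0 metastatic breast cancer from
    tumor-only targeted panel sequencing. Implements the germline filtering
    cascade for tumor-only calls (gnomAD/ClinVar removal with COSMIC
    recurrence rescue), oncogenicity classification of mutations and copy
    number events, tumor mutational burden with changepoint-based
    hypermutation calling, purity-corrected relative ERBB2 copy-count
    estimation from segmented log2 ratios, covariate-adjusted per-gene
    logistic-regression enrichment with Benjamini-Hochberg false discovery
    rate control, estrogen-receptor-stratified Cochran-Mantel-Haenszel and
    rank tests, and a synthetic cohort generator that emulates the joint
    clinical and genomic structure of such cohorts for end-to-end testing
    and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
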
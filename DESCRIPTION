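Package: wescohort
Title: Somatic Variant Filtering and Genomic Instability Metrics for
    Tumor Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of tumor/normal whole-exome cohorts:
    multi-criteria somatic SNV filtering with hotspot rescue, six-class
    mutation-spectrum and transition/transversion analysis, tumor
    mutational burden (TMB), mutant-allele tumor heterogeneity (MATH),
    a microsatellite-instability caller based on STR allele counts
    against a normal-panel baseline, copy-number gain/loss calling, a
    Z-score copy-number-instability (CNI) score, and cohort-level group
    comparisons.  Includes a seeded synthetic-cohort generator with a
    truth manifest so the whole pipeline is testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
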
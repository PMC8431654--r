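Package: epiage
Title: Targeted Epigenetic Age Analysis from Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for epigenetic-age analysis of blood samples with
    targeted bisulfite amplicon sequencing (BA-seq). Implements bisulfite-aware
    alignment of amplicon reads and per-CpG methylation calling, a linear
    epigenetic clock engine including a published three-CpG blood clock
    (CCDC102B, FHL2, PDE4C), delta-age group comparisons with Welch's t-test,
    reference-based leukocyte deconvolution by non-negative constrained least
    squares, and age-adjusted telomere-length percentile analysis. A synthetic
    cohort generator with full ground truth emulates the statistical structure
    of a clinical blood-methylation study for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    quadprog,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
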
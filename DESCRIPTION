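Package: oligotwohit
Title: Two-Hit Inactivation Calling in Oligodendroglial Tumors from
    Integrated Copy-Number, Expression, Mutation and qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative detection of biallelic tumor-suppressor
    inactivation in 1p/19q-codeleted oligodendroglial tumors. Implements a
    purity-aware copy-number mixture model for aCGH log2 ratios with
    arm-level calling, genetic-subtype classification and focal
    homozygous-deletion candidate detection; RPKM normalization with
    low-expression outlier flagging and group comparisons; minimal HGVS
    parsing with mutation-consequence and damaging-effect classification;
    qPCR delta-Ct copy classification with breakpoint refinement;
    self-contained cohort statistics (two-sided Fisher exact test, odds
    ratio, Mann-Whitney U, Bonferroni and Benjamini-Hochberg adjustment);
    and a synthetic-cohort generator with matched ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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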
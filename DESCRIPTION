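Package: prsgrowth
Title: Polygenic Risk Scores, Vitamin D Status and Child Growth Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gene-environment relations between a
    weighted polygenic risk score (PRS) for body-mass index, serum
    25-hydroxyvitamin D status and BMI-for-age z-scores (zBMI) in young
    children. Provides SNP-level genotype quality control (missing rate,
    minor allele frequency, Hardy-Weinberg exact test), PRS computation
    with per-subject rescaling for missing genotypes and decile-based
    risk grouping, LMS growth-reference z-scoring with the restricted
    adjustment beyond three standard deviations, a nonparametric
    inference layer (Spearman and covariate-adjusted Spearman, Wilcoxon
    rank-sum, Kruskal-Wallis, Dunn's unequal-n multiple comparisons,
    Jonckheere-Terpstra trend, Scheirer-Ray-Hare rank interaction,
    chi-square), a seeded synthetic-cohort generator with planted
    effects for validation, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
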
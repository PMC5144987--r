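Package: microplast
Title: Microenvironmental Plasticity Analysis for Individual-Level RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gene-expression differences and microenvironmental
    plasticity among individuals of fixed genotype from bulk RNA-seq read
    counts. Provides negative-binomial generalized linear model
    likelihood-ratio testing over a genotype x sex x replicate factorial
    design, median-of-ratios normalization with an empirical low-expression
    threshold derived from intergenic read counts, heterogeneity-of-variance
    (Levene and Brown-Forsythe) tests, the coefficient of environmental
    variation (CV_E) and its ANOVA, expected-mean-squares variance components
    and broad-sense heritability, modularity-maximizing coexpression
    clustering with hypergeometric gene-set enrichment, covariate screens
    (Wolbachia infection, residual heterozygosity, rRNA level), and a
    negative-binomial count simulator that emulates a balanced
    multi-genotype individual-fly design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    car,
    fgsea,
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
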
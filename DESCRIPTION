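Package: nadphnet
Title: Elasticity Analysis of the NADP-Reducing Enzyme Network Across
    Environmental Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genetic interactions in the Drosophila NADP-reducing
    enzyme network (G6PD, IDH, MEN) and two downstream phenotypes
    (triglyceride and carbohydrate stores) across environmental conditions.
    Provides a synthetic-data generator emulating a 3-gene x 7-background x
    2-genotype x 4-condition factorial cross design with a log-linear
    compensation model; activity standardization by soluble protein;
    covariate-adjusted genotype tests (ANCOVA); gated elasticity-coefficient
    estimation from per-background ln-ln slopes; and cross-condition
    comparison of pooled genotype ratios by one-way ANOVA with Tukey HSD
    multiple comparisons, rendered as a signed-magnitude interaction matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
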
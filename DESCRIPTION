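Package: triepistasis
Title: Estimation of Three-Way Additive QTL Interaction Effects in
    Doubled Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the total additive x additive x additive
    (aaa) three-way epistatic interaction effect of quantitative trait
    loci in doubled haploid (DH) populations, and to compare two
    estimators of it: a phenotypic estimator based on groups of extreme
    lines, and a genotypic estimator based on marker regression with
    staged stepwise-AIC marker selection and Bonferroni-corrected
    significance of interaction terms.  Includes readers and writers for
    line-by-marker genotype tables (coded -1/+1), linkage maps and
    phenotype tables; preprocessing (arcsin square-root transformation,
    flanking-marker imputation of missing genotypes under the Haldane
    map function, chi-square segregation pre-test); a DH population
    simulator with known genetic architecture; and batch comparison of
    the two estimators across trait-by-environment sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
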
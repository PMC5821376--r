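Package: gxeds
Title: Differential Susceptibility and Diathesis-Stress Analysis of
    Gene-Environment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for testing whether a gene-by-environment (GxE)
    interaction follows a differential-susceptibility, diathesis-stress,
    or vantage-sensitivity pattern. Builds binary risk-carrier moderators
    from biallelic SNP genotypes (Hardy-Weinberg checks, pairwise linkage
    disequilibrium, EM haplotype-frequency estimation with posterior
    diplotype assignment), fits moderated ordinary-least-squares
    regressions of an environmental exposure on continuous outcomes with
    simple slopes, curvilinearity and covariate-interaction (Keller)
    checks, and computes the crossover point, Johnson-Neyman regions of
    significance on the environment axis, the Proportion of Interaction
    (PoI) and Proportion Affected (PA) indices, and a pattern
    classification.  A synthetic-study generator reproduces the
    statistical structure these analyses assume (haplotype-block
    genotypes in Hardy-Weinberg equilibrium, a truncated-normal life-event
    impact score, crossover-interaction outcomes) so the whole pipeline
    can be exercised and calibrated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
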
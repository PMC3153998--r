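Package: pleioscan
Title: Genome-Wide Pleiotropy Scans for Correlated Quantitative Traits in Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying genetic pleiotropy between pairs of
    correlated quantitative traits measured in two-generational family samples.
    Provides pedigree-aware simulation of genotypes (gene dropping) and
    multivariate phenotypes, genotype and sample quality control, principal
    components for population structure with projection of related individuals,
    covariate residualization with inverse-normal transforms, maximum-likelihood
    univariate and bivariate polygenic variance-components models (heritability,
    genetic and environmental correlations), kinship-adjusted mixed-model SNP
    association scans, and a shared-association pleiotropy statistic calibrated
    against gene-dropping simulation nulls and a bivariate-normal analytic
    expectation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
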
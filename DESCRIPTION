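Package: gemvar
Title: Dissecting Genetic and Environmental Contributions to DNA Methylome Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies variably methylated loci (VMLs) in DNA methylation
    microarray data and dissects the individual (G, E), additive (G+E), and
    interactive (GxE) contributions of cis genetic variants and environmental
    exposures to their methylation levels. Implements highly variable probe
    detection on covariate-adjusted M values, proximity- and correlation-based
    chaining of probes into variably methylated regions alongside sparse
    single-probe loci, cis SNP mapping, LASSO screening of candidate variables
    with unpenalized covariates, AIC-based competition of linear G/E/G+E/GxE
    models, Lindeman-Merenda-Gold variance decomposition, and a permutation
    null filter for winning models. Includes a fully synthetic data generator
    with planted effect architectures so every stage can be validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
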
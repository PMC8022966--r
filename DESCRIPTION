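Package: BDTSelect
Title: Multi-Trait Bayesian Decision-Theoretic Parental Selection for
    Genomic Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parental selection for multi-trait genomic breeding programs
    using Bayesian decision theory. Fits a multi-trait GBLUP mixed model by
    Gibbs sampling on a genomic relationship matrix, approximates each
    candidate line's posterior-predictive distribution, and ranks candidates
    by posterior expected loss against the truncated multivariate-normal
    distribution of selected parents under three multivariate loss
    functions: Kullback-Leibler divergence, the Energy Score, and a
    multivariate asymmetric linear loss. Includes a seeded synthetic-data
    generator emulating wheat multi-trait datasets, genomic relationship
    matrix construction from centered and standardized markers, and
    selection reporting with pairwise selected-set overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mvtnorm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'traitconfig.R'
    'io.R'
    'grm.R'
    'synthetic.R'
    'gibbs.R'
    'loss.R'
    'pel.R'
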
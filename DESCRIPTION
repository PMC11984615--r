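Package: plncount
Title: Poisson Lognormal Models for Multivariate Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, moments, moment matching and sampling for the Poisson,
    negative binomial and (multivariate) Poisson lognormal (PLN/MPLN)
    distributions; maximum-likelihood fitting of the univariate families by
    adaptive Gauss-Hermite quadrature; variational Gaussian estimation of the
    MPLN distribution with log-scale normalization offsets; model-based
    clustering of count matrices via finite mixtures of MPLN distributions
    with BIC model selection, MAP assignment, and an optional two-step hybrid
    Bayesian refinement of the component parameters; TMM and median-of-ratios
    normalization factors; and simulation drivers for mean/variance recovery,
    quantile comparison, and latent-versus-observed correlation mapping
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    DESeq2,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
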
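Package: hmrfclust
Title: Spatially Aware Bayesian Clustering of Spatial Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian clustering and cell population annotation for spatial
    proteomics single-cell data (imaging mass cytometry, MIBI, CODEX).
    Latent cell population labels are modelled with a hidden Markov random
    field defined on a cell neighbour graph, so that the propensity of cell
    types to neighbour one another (autonomous and nonautonomous
    interactions) informs cluster assignment. Marker expression is modelled
    with independent Normal emissions under conjugate Normal-Gamma priors,
    giving a collapsed Gibbs sampler for labels; the cluster-interaction
    affinity matrix is sampled with a double Metropolis-Hastings step that
    sidesteps the intractable Potts normalizing constant. Supports
    unsupervised clustering, prior-expression-matrix guided clustering, and
    anchor-based label transfer from disaggregated assays, plus forward
    simulators for spatially structured benchmark data and entropy-based
    clustering accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
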
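Package: trcest
Title: Phylogenetic Estimation of Recombination Cessation Times on Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of the timing of recombination cessation (t_RC) between
    sex-chromosome gametologs (Z-W or X-Y copies of a gene). Implements
    enumeration of hypothetical gametolog topologies over a dated reference
    species tree, expected likelihood weights (ELW) by RELL bootstrap,
    simplified Bayesian node dating with calibration priors, the NG86 counting
    estimator of pairwise synonymous divergence, and collapsed
    maximum-likelihood tree position ranges, together with the clustering and
    nonparametric statistics used to evaluate them and a synthetic gametolog
    data generator with known cessation times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    cluster,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
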
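Package: mtenet
Title: Multivariate Transfer Entropy Network Inference with Hierarchical
    Statistical Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Greedy inference of directed effective networks from multivariate
    time series using conditional and collective transfer entropy with
    nonuniform embedding. Candidate past variables of the target and of the
    sources are selected iteratively by conditional mutual information and
    tested with hierarchical nonparametric statistics (maximum statistic,
    minimum statistic, omnibus test) that control the family-wise error rate,
    followed by false-discovery-rate correction across targets. Provides a
    covariance-based Gaussian estimator with an analytic chi-square null and a
    Kraskov-Grassberger nearest-neighbour estimator with its Frenzel-Pompe
    extension to conditional mutual information, surrogate-data permutation
    testing, simulators for vector autoregressive and coupled logistic map
    dynamics on random directed networks, and scoring of inferred networks
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
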
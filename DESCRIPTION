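Package: dpmixpop
Title: Dirichlet Process Mixture Clustering of Multilocus Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference of genetic population structure from
    multilocus genotype data using a Dirichlet process mixture model.
    The number of populations and the assignment of individuals are
    inferred jointly under a Chinese restaurant process prior, with
    population allele frequencies integrated out analytically under
    symmetric Dirichlet priors. The Markov chain combines Gibbs scans
    with sequentially-allocated merge-split (SAMS) proposals, and the
    Dirichlet hyperparameter of the allele-frequency prior can be fixed
    or sampled by Metropolis-Hastings, either shared across loci or
    per locus. Fixed-K baseline samplers with uncorrelated (FUM) and
    correlated (FCM) allele-frequency priors, partition summaries
    (partition distance via the Hungarian algorithm, mean partition,
    co-assignment matrices and complete-linkage dendrograms), a
    Weir-Cockerham Fst estimator, and two genotype simulators (a
    correlated-Dirichlet drift model and a finite-island Wright-Fisher
    model) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
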
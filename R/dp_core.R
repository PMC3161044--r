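#' Chinese restaurant process assignment weights
#'
#' Sequential prior probabilities for assigning the next individual: an
#' existing cluster of size `|S_j|` attracts it with probability proportional
#' to `|S_j|`, a new cluster with probability proportional to `alpha`.
#'
#' @param sizes integer vector of current cluster sizes (may be empty).
#' @param alpha concentration parameter, > 0.
#' @return Probability vector of length `length(sizes) + 1`; the last entry
#'   is the new-cluster probability.
#' @export
crp_weights <- function(sizes, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  if (length(sizes) && any(sizes <= 0)) stop("cluster sizes must be positive")
  w <- c(sizes, alpha)
  w / sum(w)
}

#' Log prior probability of a partition under the CRP
#'
#' `log[ alpha^K * Gamma(alpha)/Gamma(alpha + n) * prod_j Gamma(|S_j|) ]`,
#' the product of the sequential CRP weights over any insertion order.
#'
#' @param labels cluster labels of the `n` individuals (any coding).
#' @param alpha concentration parameter, > 0.
#' @return log prior probability.
#' @export
log_partition_prior <- function(labels, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  sizes <- as.vector(table(labels))
  n <- sum(sizes)
  length(sizes) * log(alpha) + lgamma(alpha) - lgamma(alpha + n) +
    sum(lgamma(sizes))
}

#' Aggregate allele-copy counts by cluster
#'
#' Sufficient statistics `y_jlh`: the number of copies of allele `h` at
#' locus `l` carried by the individuals of cluster `j`. Missing copies
#' contribute nothing.
#'
#' @param x a [genotype_table()].
#' @param labels cluster labels (length `n`).
#' @return A list with one element per cluster (in order of first
#'   appearance), each a list of per-locus integer count vectors of length
#'   `J_l`.
#' @export
cluster_allele_counts <- function(x, labels) {
  stopifnot(inherits(x, "genotype_table"))
  labs <- canonicalize_labels(labels)
  K <- max(labs)
  P <- x$ploidy; L <- n_loci(x)
  lapply(seq_len(K), function(j) {
    rows <- which(labs == j)
    lapply(seq_len(L), function(l) {
      cols <- ((l - 1L) * P + 1L):(l * P)
      v <- x$alleles[rows, cols, drop = FALSE]
      as.vector(table(factor(v[!is.na(v)], levels = seq_len(x$J[l]))))
    })
  })
}

#' Log predictive probability of one individual's genotype
#'
#' The Dirichlet-multinomial predictive of one multilocus genotype given the
#' allele-copy counts of a cluster, with the per-population allele
#' frequencies integrated out under a symmetric `Dirichlet(lambda_l)` prior.
#' At each locus the closed form is
#' `2^het * Gamma(y_l. + J_l lambda_l) / Gamma(y_l. + J_l lambda_l + m) *
#'  prod_h Gamma(y_lh + lambda_l + c_h) / Gamma(y_lh + lambda_l)`
#' where `c_h` are the individual's allele copies (`m = sum c_h`) and the
#' factor 2 applies to observed heterozygous diploid genotypes. Missing
#' copies are skipped; a fully missing locus contributes a factor of 1.
#'
#' @param geno integer vector of length `ploidy * L`, 1-based allele codes
#'   with `NA` for missing copies (a row of a [genotype_table()]).
#' @param counts cluster counts for one cluster as produced by
#'   [cluster_allele_counts()] (a list of per-locus count vectors), or `NULL`
#'   for an empty cluster (predictive under the prior alone).
#' @param lambda per-locus Dirichlet hyperparameter (recycled to `L`).
#' @param J per-locus observed allele counts.
#' @param ploidy 1 or 2.
#' @return log predictive probability.
#' @export
log_predictive_individual <- function(geno, counts, lambda, J, ploidy = 2L) {
  L <- length(J)
  lambda <- rep_len(lambda, L)
  if (any(lambda <= 0)) stop("lambda must be positive")
  lp <- 0
  for (l in seq_len(L)) {
    if (J[l] < 1L) next
    g <- geno[((l - 1L) * ploidy + 1L):(l * ploidy)]
    g <- g[!is.na(g)]
    m <- length(g)
    if (m == 0L) next
    y <- if (is.null(counts)) rep(0L, J[l]) else counts[[l]]
    ytot <- sum(y)
    lam <- lambda[l]
    lp <- lp + lgamma(ytot + J[l] * lam) - lgamma(ytot + J[l] * lam + m)
    ch <- tabulate(g, nbins = J[l])
    hit <- which(ch > 0L)
    lp <- lp + sum(lgamma(y[hit] + lam + ch[hit]) - lgamma(y[hit] + lam))
    if (m == 2L && g[1L] != g[2L]) lp <- lp + log(2)
  }
  lp
}

#' Log marginal likelihood of a set of individuals as one cluster
#'
#' Chain product of [log_predictive_individual()] as the members are added
#' one at a time to an initially empty cluster. By exchangeability of the
#' Dirichlet-multinomial the value does not depend on the order of addition.
#'
#' @param x a [genotype_table()].
#' @param idx indices of the individuals forming the set (non-empty).
#' @param lambda per-locus Dirichlet hyperparameter (recycled).
#' @return log marginal probability of the set's genotypes.
#' @export
log_marginal_set <- function(x, idx, lambda) {
  stopifnot(inherits(x, "genotype_table"))
  if (length(idx) == 0L) stop("the set must be non-empty")
  L <- n_loci(x); P <- x$ploidy
  lambda <- rep_len(lambda, L)
  counts <- lapply(x$J, function(j) rep(0L, max(j, 0L)))
  lp <- 0
  for (i in idx) {
    lp <- lp + log_predictive_individual(x$alleles[i, ], counts, lambda,
                                         x$J, ploidy = P)
    for (l in seq_len(L)) {
      if (x$J[l] < 1L) next
      g <- x$alleles[i, ((l - 1L) * P + 1L):(l * P)]
      g <- g[!is.na(g)]
      if (length(g)) counts[[l]] <- counts[[l]] + tabulate(g, nbins = x$J[l])
    }
  }
  lp
}

#' Prior distribution of the number of clusters K
#'
#' Monte Carlo draws of K under the CRP prior by sequential assignment of
#' `n` individuals, together with the closed-form expectation
#' `sum_{i=1..n} alpha / (alpha + i - 1)` for cross-checking.
#'
#' @param n number of individuals.
#' @param alpha concentration parameter.
#' @param draws number of Monte Carlo replicates.
#' @return list with `distribution` (data.frame of K, count, prob),
#'   `mean_mc`, `mean_closed_form`, `draws`.
#' @export
prior_k_distribution <- function(n, alpha, draws = 10000L) {
  if (alpha <= 0) stop("alpha must be positive")
  if (draws < 1L) stop("draws must be >= 1")
  ks <- crp_prior_K(as.integer(n), alpha, as.integer(draws))
  tab <- table(ks)
  list(distribution = data.frame(K = as.integer(names(tab)),
                                 count = as.vector(tab),
                                 prob = as.vector(tab) / draws),
       mean_mc = mean(ks),
       mean_closed_form = crp_expected_k(n, alpha),
       draws = draws)
}

#' Closed-form prior expectation of K under the CRP
#'
#' @param n number of individuals.
#' @param alpha concentration parameter.
#' @return `sum_{i=1..n} alpha/(alpha + i - 1)`.
#' @export
crp_expected_k <- function(n, alpha) sum(alpha / (alpha + seq_len(n) - 1))

#' Concentration parameter giving a target prior mean of K
#'
#' Solves `E[K] = k` for `alpha` by root finding; used to match the prior
#' expected number of populations to a working hypothesis (e.g. 2).
#'
#' @param n number of individuals.
#' @param k target prior mean number of clusters, in `(1, n)`.
#' @return alpha value.
#' @export
crp_alpha_for_k <- function(n, k) {
  if (k <= 1 || k >= n) stop("target mean K must lie in (1, n)")
  stats::uniroot(function(a) crp_expected_k(n, a) - k,
                 lower = 1e-8, upper = 1e6, tol = 1e-10)$root
}

#' Canonical cluster labels
#'
#' Renumbers labels by order of first appearance so that equal partitions
#' compare bit-exactly.
#'
#' @param labels cluster labels (any coding).
#' @return integer labels `1..K` in first-appearance order.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}
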
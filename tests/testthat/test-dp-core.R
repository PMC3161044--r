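test_that("CRP weights follow size-proportional / alpha-proportional form", {
  expect_equal(crp_weights(c(2, 3), 1), c(2, 3, 1) / 6)
  expect_equal(crp_weights(integer(0), 0.7), 1)
  w <- crp_weights(5, 1e-12)
  expect_gt(w[1], 1 - 1e-10)
  expect_lt(w[2], 1e-10)
  expect_error(crp_weights(c(2, 3), 0), "alpha")
})

test_that("partition prior normalises over all set partitions and matches
           the product of sequential CRP weights in any order", {
  for (alpha in c(0.3, 1, 2.7)) {
    tot <- sum(vapply(enum_partitions(6), function(p)
      exp(log_partition_prior(p, alpha)), 0))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  expect_equal(log_partition_prior(1L, 2), 0)
  expect_equal(exp(log_partition_prior(c(1, 1), 1)), 0.5)
  expect_equal(exp(log_partition_prior(c(1, 2), 1)), 0.5)
  # exchangeability: sequential product over random insertion orders
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    labs <- sample(1:3, n, TRUE)
    alpha <- runif(1, 0.2, 3)
    ord <- sample(n)
    lp <- 0
    sizes <- integer(0)
    assigned <- integer(0)
    for (i in ord) {
      # cluster of i among already-inserted individuals
      prev <- canonicalize_labels(labs[c(assigned, i)])
      j <- prev[length(prev)]
      w <- crp_weights(sizes, alpha)
      lp <- lp + log(if (j > length(sizes)) w[length(w)] else w[j])
      if (j > length(sizes)) sizes <- c(sizes, 1L) else sizes[j] <- sizes[j] + 1L
      assigned <- c(assigned, i)
    }
    expect_equal(lp, log_partition_prior(labs, alpha), tolerance = 1e-12)
  }
})

test_that("predictive closed form matches hand values and numeric integration", {
  # empty cluster, one locus, J=2, flat prior: heterozygote has probability 1/3
  het <- c(1L, 2L)
  expect_equal(exp(log_predictive_individual(het, NULL, 1, 2L)), 1 / 3,
               tolerance = 1e-12)
  p_homA <- exp(log_predictive_individual(c(1L, 1L), NULL, 1, 2L))
  p_homB <- exp(log_predictive_individual(c(2L, 2L), NULL, 1, 2L))
  expect_equal(p_homA + p_homB + 1 / 3, 1, tolerance = 1e-12)

  # counts y = (3,1), lambda = 0.5: closed form 0.35 for the heterozygote,
  # cross-checked by quadrature over the Dirichlet(3.5, 1.5) posterior
  counts <- list(c(3L, 1L))
  expect_equal(exp(log_predictive_individual(het, counts, 0.5, 2L)), 0.35,
               tolerance = 1e-12)
  dens <- function(p) 2 * p * (1 - p) * stats::dbeta(p, 3.5, 1.5)
  expect_equal(stats::integrate(dens, 0, 1, rel.tol = 1e-10)$value, 0.35,
               tolerance = 1e-8)

  # haploid copy: single-draw predictive
  expect_equal(exp(log_predictive_individual(1L, counts, 0.5, 2L, ploidy = 1L)),
               3.5 / 5, tolerance = 1e-12)
  expect_error(log_predictive_individual(het, counts, -1, 2L), "lambda")
})

test_that("predictive normalises over the full genotype space", {
  set.seed(21)
  for (rep in 1:20) {
    J <- sample(2:4, 1)
    lam <- runif(1, 0.1, 5)
    y <- list(as.integer(rpois(J, 3)))
    genos <- rbind(t(utils::combn(J, 2)), cbind(1:J, 1:J))
    tot <- sum(apply(genos, 1, function(g)
      exp(log_predictive_individual(as.integer(g), y, lam, J))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("set marginal is order-invariant and matches quadrature", {
  tab <- random_snp_table(6, 3, seed = 31)
  base <- log_marginal_set(tab, 1:6, lambda = 0.8)
  set.seed(32)
  for (rep in 1:20)
    expect_equal(log_marginal_set(tab, sample(6), lambda = 0.8), base,
                 tolerance = 1e-9)
  expect_equal(log_marginal_set(tab, 2, 1.3),
               log_predictive_individual(tab$alleles[2, ], NULL, 1.3, tab$J))

  # 3 individuals at one SNP locus, lambda = 1: integrate the binomial
  # likelihood over the flat frequency prior directly
  tab1 <- make_table(rbind(c(1L, 2L), c(1L, 1L), c(2L, 1L)))
  counts <- c(4, 2)  # copies of allele 1 and 2; two heterozygotes
  oracle <- stats::integrate(function(p) 2 * 2 * p^counts[1] * (1 - p)^counts[2],
                             0, 1, rel.tol = 1e-10)$value
  expect_equal(log_marginal_set(tab1, 1:3, 1), log(oracle), tolerance = 1e-8)
})

test_that("fully missing loci contribute a factor of one", {
  raw <- rbind(c(1L, 2L, NA, NA), c(2L, 2L, NA, NA))
  tab <- make_table(raw)
  tab1 <- make_table(raw[, 1:2, drop = FALSE])
  expect_equal(log_marginal_set(tab, 1:2, 1), log_marginal_set(tab1, 1:2, 1))
})

test_that("Monte-Carlo prior mean of K matches the closed form within 3 SE", {
  for (cfg in list(c(50, 0.3), c(100, 0.2), c(30, 1.5))) {
    pk <- prior_k_distribution(cfg[1], cfg[2], draws = 20000)
    se <- stats::sd(rep(pk$distribution$K, pk$distribution$count)) / sqrt(pk$draws)
    expect_lt(abs(pk$mean_mc - pk$mean_closed_form), 3 * se + 1e-9)
    expect_equal(sum(pk$distribution$prob), 1)
  }
  pk1 <- prior_k_distribution(1, 0.5, draws = 100)
  expect_equal(pk1$distribution$K, 1L)
  expect_equal(pk1$distribution$prob, 1)
})

test_that("alpha solver inverts the closed-form prior mean of K", {
  a <- crp_alpha_for_k(100, 2)
  expect_equal(crp_expected_k(100, a), 2, tolerance = 1e-6)
  expect_error(crp_alpha_for_k(10, 0.5), "target")
})

test_that("cluster counts aggregate copies and restore after remove/re-add", {
  tab <- random_snp_table(8, 4, seed = 41)
  labs <- c(1, 1, 2, 2, 2, 3, 3, 1)
  cc <- cluster_allele_counts(tab, labs)
  for (l in 1:4) {
    tot <- Reduce(`+`, lapply(cc, function(cj) cj[[l]]))
    v <- tab$alleles[, c(2 * l - 1, 2 * l)]
    expect_equal(tot, as.vector(table(factor(v, levels = 1:2))))
  }
  # moving one individual out of its cluster and back restores the counts
  labs2 <- labs
  labs2[1] <- 4  # park individual 1 in its own cluster
  cc2 <- cluster_allele_counts(tab, labs2)
  # canonical numbering: {1} is cluster 1, the rest of old cluster 1 is 2
  restored <- lapply(seq_along(cc2[[1]]), function(l)
    cc2[[1]][[l]] + cc2[[2]][[l]])
  expect_equal(restored, cc[[1]])
})
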
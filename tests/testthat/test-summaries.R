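test_that("partition distance reproduces the worked examples", {
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 1, 2, 2))$distance, 0)
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 1, 1, 1))$distance, 2)
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 1, 1, 1))$normalized, 0.5)
  # unbalanced 10/310 collapse: unweighted distance understates the failure
  truth <- rep(1:2, c(10, 300))
  merged <- rep(1, 310)
  expect_equal(partition_distance(truth, merged)$normalized, 10 / 310)
  expect_error(partition_distance(1:3, 1:4), "different")
})

test_that("partition distance is label-free and a metric, matching the
           brute-force minimal-removal oracle", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    a <- sample(1:3, n, TRUE)
    b <- sample(1:3, n, TRUE)
    cc <- sample(1:4, n, TRUE)
    dab <- partition_distance(a, b)$distance
    expect_equal(dab, brute_partition_distance(a, b))
    # label permutation invariance
    pa <- sample(3)[a]
    expect_equal(partition_distance(pa, b)$distance, dab)
    # metric properties
    expect_equal(partition_distance(a, a)$distance, 0)
    expect_equal(partition_distance(b, a)$distance, dab)
    dac <- partition_distance(a, cc)$distance
    dcb <- partition_distance(cc, b)$distance
    expect_lte(dab, dac + dcb)
  }
})

test_that("Hungarian matching equals brute force over all cluster matchings", {
  set.seed(92)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    a <- sample(1:5, n, TRUE)
    b <- sample(1:4, n, TRUE)
    ov <- dpmixpop:::partition_overlap_cpp(canonicalize_labels(a),
                                           canonicalize_labels(b), numeric(0))
    expect_equal(ov, brute_max_overlap(a, b))
  }
})

test_that("weighted distance reproduces the 30:1 unbalanced-design examples", {
  truth <- rep(1:2, c(10, 300))
  # total collapse: every small individual counts as 30 large ones
  expect_equal(weighted_partition_distance(truth, rep(1, 310))$normalized, 0.5)
  # one small individual misassigned to the large cluster
  inferred <- truth
  inferred[1] <- 2
  expect_equal(weighted_partition_distance(truth, inferred)$normalized,
               30 / 600)
  expect_equal(partition_distance(truth, inferred)$normalized, 1 / 310)
  # uniform weights reduce to the plain normalised distance
  set.seed(93)
  a <- sample(1:3, 12, TRUE)
  b <- sample(1:3, 12, TRUE)
  expect_equal(weighted_partition_distance(a, b, weights = rep(1, 12))$normalized,
               partition_distance(a, b)$normalized)
  expect_error(weighted_partition_distance(a, b, weights = rep(-1, 12)),
               "positive")
})

test_that("mean partition matches exhaustive search on tiny sample sets", {
  # identical samples: the mean is that partition with D = 0
  samples <- matrix(rep(c(1, 1, 2), 3), 3, byrow = TRUE)
  mp <- mean_partition(samples)
  expect_equal(mp$partition, c(1, 1, 2))
  expect_equal(mp$D, 0)
  # {12|3, 12|3, 1|2|3}: the mean is 12|3
  samples <- rbind(c(1, 1, 2), c(1, 1, 2), c(1, 2, 3))
  mp <- mean_partition(samples)
  expect_equal(mp$partition, c(1, 1, 2))
  exhaustive_D <- function(smp, u) sum(apply(smp, 1, function(s)
    partition_distance(u, s)$distance))
  best <- min(vapply(enum_partitions(3), function(u) exhaustive_D(samples, u), 0))
  expect_equal(mp$D, best)
  # random sample sets, n <= 6: greedy attains the exhaustive minimum in
  # at least 95% of trials
  set.seed(94)
  hits <- 0L
  trials <- 20L
  for (rep in seq_len(trials)) {
    n <- sample(4:6, 1)
    smp <- matrix(sample(1:3, 5 * n, TRUE), 5, n)
    smp <- t(apply(smp, 1, canonicalize_labels))
    mp <- mean_partition(smp)
    best <- min(vapply(enum_partitions(n), function(u) exhaustive_D(smp, u), 0))
    expect_gte(mp$D, best)  # never better than the true optimum
    if (mp$D <= best + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * trials))
})

test_that("co-assignment matrix is a proper similarity and summaries are
           label-permutation invariant", {
  set.seed(95)
  smp <- matrix(sample(1:3, 40, TRUE), 4, 10)
  smp <- t(apply(smp, 1, canonicalize_labels))
  C <- coassignment_matrix(smp)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 10))
  expect_true(all(C >= 0 & C <= 1))
  # permuting cluster labels within samples changes nothing
  smp_p <- t(apply(smp, 1, function(z) sample(3)[z]))
  expect_equal(coassignment_matrix(smp_p), C)
  expect_equal(mean_partition(smp_p)$D, mean_partition(smp)$D)
})

test_that("dendrogram from a single sampled partition separates its clusters
           at height one", {
  smp <- matrix(c(1, 1, 2, 2, 3), 1)
  dd <- coassign_dendrogram(smp)
  expect_true(all(dd$coassign %in% c(0, 1)))
  expect_equal(sort(unique(dd$hclust$height)), c(0, 1))
  # pairs always co-assigned merge at height 0
  expect_equal(stats::cutree(dd$hclust, h = 0.5),
               stats::setNames(c(1, 1, 2, 2, 3), paste0("ind", 1:5)))
  expect_match(dd$newick, "^\\(")
})

test_that("cutting the co-assignment tree recovers planted clusters", {
  sim <- sim_correlated(pa = rep(0.2, 5), fst = 0.15, loci = 40,
                        n_per_pop = rep(10, 5), seed = 96)
  a <- crp_alpha_for_k(50, 5)
  tr <- run_dp_mcmc(sim$table, alpha = a, lambda = 1, iterations = 4000,
                    burnin = 2000, thin = 10, seed = 97)
  dd <- coassign_dendrogram(tr)
  cut5 <- stats::cutree(dd$hclust, h = 0.5)
  expect_equal(partition_distance(sim$truth, cut5)$distance, 0)
})

test_that("posterior K histogram and mean", {
  expect_equal(attr(posterior_k(rep(2L, 10)), "mean"), 2)
  pk <- posterior_k(c(2L, 3L, 2L, 3L))
  expect_equal(attr(pk, "mean"), 2.5)
  expect_equal(pk$prob, c(0.5, 0.5))
  smp <- rbind(c(1, 1, 2), c(1, 2, 3))
  expect_equal(posterior_k(smp)$K, c(2L, 3L))
})
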
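test_that("a single individual always resettles in a singleton", {
  tab <- random_snp_table(1, 2, seed = 51)
  tr <- run_dp_mcmc(tab, alpha = 0.5, lambda = 1, iterations = 200,
                    burnin = 100, thin = 1, sams = 0, gibbs = 1, seed = 1)
  expect_true(all(tr$labels == 1L))
  expect_true(all(tr$K == 1L))
})

test_that("trace bookkeeping: stored sample count, determinism, consistency", {
  tab <- random_snp_table(8, 3, seed = 52)
  tr <- run_dp_mcmc(tab, alpha = 1, lambda = 1, iterations = 2000,
                    burnin = 1000, thin = 10, seed = 99,
                    check_consistency = TRUE)
  expect_equal(nrow(tr$labels), (2000 - 1000) / 10)
  tr2 <- run_dp_mcmc(tab, alpha = 1, lambda = 1, iterations = 2000,
                     burnin = 1000, thin = 10, seed = 99)
  expect_identical(tr$labels, tr2$labels)
  # canonical labels: first individual always labelled 1
  expect_true(all(tr$labels[, 1] == 1L))
  expect_error(run_dp_mcmc(tab, alpha = 1, iterations = 100, burnin = 100),
               "burnin")
})

test_that("identical individuals co-assign more often than the prior alone", {
  # two copies of the same informative multilocus genotype
  set.seed(53)
  g <- sample(1:2, 40, TRUE)
  tab <- genotype_table(rbind(g, g))
  alpha <- 1
  tr <- run_dp_mcmc(tab, alpha = alpha, lambda = 1, iterations = 20000,
                    burnin = 2000, thin = 2, sams = 0, gibbs = 1, seed = 2)
  co <- mean(tr$labels[, 1] == tr$labels[, 2])
  prior_co <- 1 / (1 + alpha)
  expect_gt(co, prior_co)
})

test_that("Gibbs-only chain matches the enumerated posterior (n=4)", {
  tab <- random_snp_table(4, 2, seed = 54)
  ex <- exact_posterior(tab, alpha = 1, lambda = 1)
  tr <- run_dp_mcmc(tab, alpha = 1, lambda = 1, iterations = 40000,
                    burnin = 2000, thin = 1, sams = 0, gibbs = 1, seed = 3,
                    check_consistency = TRUE)
  emp <- empirical_partition_dist(tr$labels, ex$key)
  tv <- sum(abs(emp - ex$prob)) / 2
  expect_lt(tv, 0.02)
})

test_that("SAMS+Gibbs chain has the same stationary distribution (n=6)", {
  tab <- random_snp_table(6, 2, seed = 55)
  ex <- exact_posterior(tab, alpha = 0.8, lambda = 1)
  expect_equal(length(ex$prob), 203)
  tr <- run_dp_mcmc(tab, alpha = 0.8, lambda = 1, iterations = 120000,
                    burnin = 5000, thin = 1, sams = 4, gibbs = 1, seed = 4,
                    check_consistency = TRUE)
  emp <- empirical_partition_dist(tr$labels, ex$key)
  tv <- sum(abs(emp - ex$prob)) / 2
  expect_lt(tv, 0.02)
  # both split and merge proposals were exercised and sometimes accepted
  expect_gt(tr$acceptance$sams_split["accepted"], 0)
  expect_gt(tr$acceptance$sams_merge["accepted"], 0)
})

test_that("split allocation probabilities replay to the merge transition
           probability (reverse-move identity)", {
  tab <- random_snp_table(7, 3, seed = 56)
  labels <- c(1L, 1L, 1L, 1L, 1L, 2L, 2L)
  set.seed(57)
  ord <- sample(c(2L, 3L, 4L, 5L))
  sp <- dpmixpop:::sams_split_reference(tab, labels, i = 1L, j = 5L, order = ord,
                             lambda = 1)
  # replaying the same allocations as a merge reverse move reproduces log q
  lq <- dpmixpop:::sams_merge_replay_reference(tab, sp$members_i, sp$members_j, ord,
                                    lambda = 1)
  expect_equal(lq, sp$log_q, tolerance = 1e-10)
  expect_lte(sp$log_q, 0)  # a probability
})

test_that("merge of two singletons has prior ratio 1/alpha", {
  for (alpha in c(0.3, 1, 2)) {
    lp_merged <- log_partition_prior(c(1, 1), alpha)
    lp_split <- log_partition_prior(c(1, 2), alpha)
    expect_equal(exp(lp_merged - lp_split), 1 / alpha, tolerance = 1e-12)
  }
})

test_that("sampled lambda values stay inside the uniform prior support", {
  tab <- random_snp_table(10, 4, seed = 58)
  tr <- run_dp_mcmc(tab, alpha = 1, lambda = 9.9, lambda_mode = "single",
                    iterations = 3000, burnin = 500, thin = 5, delta = 0.5,
                    seed = 5)
  expect_true(all(tr$lambda > 0 & tr$lambda <= 10))
  expect_gt(tr$acceptance$lambda["proposed"], 0)
  # unique mode: one lambda per locus, all within support
  tru <- run_dp_mcmc(tab, alpha = 1, lambda = 1, lambda_mode = "unique",
                     iterations = 2000, burnin = 500, thin = 5, delta = 0.5,
                     seed = 6)
  expect_equal(ncol(tru$lambda), n_loci(tab))
  expect_true(all(tru$lambda > 0 & tru$lambda <= 10))
  expect_error(run_dp_mcmc(tab, alpha = 1, lambda_mode = "single", delta = 0),
               "delta")
})

test_that("single-lambda posterior sits higher for uniform than skewed
           allele frequencies", {
  sim_u <- sim_correlated(pa = rep(0.2, 5), fst = 0.05, loci = 30,
                          n_per_pop = c(15, 15), seed = 61)
  sim_s <- sim_correlated(pa = c(0.8, 0.05, 0.05, 0.05, 0.05), fst = 0.05,
                          loci = 30, n_per_pop = c(15, 15), seed = 62)
  a <- crp_alpha_for_k(30, 2)
  tr_u <- run_dp_mcmc(sim_u$table, alpha = a, lambda = 1,
                      lambda_mode = "single", iterations = 4000,
                      burnin = 2000, thin = 5, delta = 0.3, seed = 63)
  tr_s <- run_dp_mcmc(sim_s$table, alpha = a, lambda = 1,
                      lambda_mode = "single", iterations = 4000,
                      burnin = 2000, thin = 5, delta = 0.3, seed = 64)
  expect_gt(mean(tr_u$lambda), mean(tr_s$lambda))
})

test_that("adding SAMS moves reaches the true-K mode no later than Gibbs
           alone on multi-population island data", {
  wins <- 0L
  n_seeds <- 4L
  for (s in seq_len(n_seeds)) {
    isl <- sim_island(demes = 8, deme_size = 1000, generations = 5000,
                      loci = 50, states = 10, mu = 5e-4, migration = 0.003,
                      seed = 3000 + s)
    smp <- draw_island_sample(isl, sizes = rep(25, 4), seed = 3100 + s)
    a <- crp_alpha_for_k(100, 4)
    first_hit <- function(sams, gibbs) {
      tr <- run_dp_mcmc(smp$table, alpha = a, lambda = 1, iterations = 6000,
                        burnin = 0, thin = 10, sams = sams, gibbs = gibbs,
                        seed = 3200 + s)
      d <- apply(tr$labels, 1, function(z)
        partition_distance(smp$truth, z)$normalized)
      hit <- which(d <= 0.1)
      if (length(hit)) hit[1] else nrow(tr$labels) + 1L
    }
    if (first_hit(4, 1) <= first_hit(0, 1)) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_seeds)
})
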
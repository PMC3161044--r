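sim_to_dir <- function(dir, seed = 201) {
  sim <- sim_correlated(pa = c(0.7, 0.1, 0.1, 0.1), fst = 0.2, loci = 40,
                        n_per_pop = c(12, 12), seed = seed)
  write_genotype_table(sim$table, file.path(dir, "genotypes.txt"))
  utils::write.table(data.frame(individual = sim$table$individuals,
                                population = sim$truth),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sim
}

test_that("dp pipeline writes all artifacts and is manifest-reproducible", {
  dir <- withr::local_tempdir()
  sim <- sim_to_dir(dir)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  suppressMessages({
    r1 <- pipeline_dp(file.path(dir, "genotypes.txt"), out1,
                      alpha = crp_alpha_for_k(24, 2), lambda = 1,
                      iterations = 3000, burnin = 1500, thin = 10, seed = 7)
    r2 <- pipeline_dp(file.path(dir, "genotypes.txt"), out2,
                      alpha = crp_alpha_for_k(24, 2), lambda = 1,
                      iterations = 3000, burnin = 1500, thin = 10, seed = 7)
  })
  for (f in c("trace.tsv", "posterior_k.tsv", "mean_partition.tsv",
              "coassign.tsv", "dendrogram.nwk", "manifest.txt"))
    expect_true(file.exists(file.path(out1, f)), label = f)
  # identical seed + config => identical artifacts
  expect_identical(readLines(file.path(out1, "trace.tsv")),
                   readLines(file.path(out2, "trace.tsv")))
  expect_identical(readLines(file.path(out1, "mean_partition.tsv")),
                   readLines(file.path(out2, "mean_partition.tsv")))
  # default settings arithmetic: (20000 - 10000) / 10 = 1000 stored samples
  expect_equal((20000 - 20000 %/% 2) / 10, 1000)
  expect_equal(nrow(r1$trace$labels), 150)
  # the planted structure is recovered on this easy fixture
  mp <- utils::read.delim(file.path(out1, "mean_partition.tsv"))
  expect_equal(partition_distance(sim$truth, mp$cluster)$distance, 0)
})

test_that("fixed-K pipeline writes per-seed artifacts", {
  dir <- withr::local_tempdir()
  sim_to_dir(dir)
  out <- file.path(dir, "fk")
  suppressMessages(
    pipeline_fixed_k(file.path(dir, "genotypes.txt"), out, K = 2,
                     model = "FUM", iterations = 1500, burnin = 800,
                     thin = 10, seeds = c(3, 4)))
  for (f in c("assign_prob_seed3.tsv", "partition_seed3.tsv",
              "assign_prob_seed4.tsv", "partition_seed4.tsv", "manifest.txt"))
    expect_true(file.exists(file.path(out, f)), label = f)
  probs <- utils::read.delim(file.path(out, "assign_prob_seed3.tsv"))
  expect_equal(rowSums(probs[, -1]), rep(1, 24), tolerance = 1e-4)
})

test_that("simulate + summarize pipelines compose, including weighted mode", {
  dir <- withr::local_tempdir()
  out_sim <- file.path(dir, "sim")
  suppressMessages(
    pipeline_simulate(out_sim, "correlated", seed = 11,
                      pa = c(0.7, 0.1, 0.1, 0.1), fst = 0.12, loci = 25,
                      n_per_pop = c(10, 30)))
  expect_true(file.exists(file.path(out_sim, "genotypes.txt")))
  truth <- utils::read.delim(file.path(out_sim, "truth.tsv"))
  expect_equal(nrow(truth), 40)
  # make an inferred partition file: the truth with one small-pop error
  part <- truth
  names(part) <- c("individual", "cluster")
  part$cluster[1] <- 2
  pf <- file.path(dir, "part.tsv")
  utils::write.table(part, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  out_rep <- file.path(dir, "rep")
  suppressMessages(
    pipeline_summarize(pf, file.path(out_sim, "truth.tsv"), out_rep,
                       weighted = TRUE))
  rep_df <- utils::read.delim(file.path(out_rep, "summary.tsv"))
  # weights 3:1 (pops 10 and 30): one small error costs 3 of 60
  expect_equal(rep_df$mean_distance, 3 / 60, tolerance = 1e-9)
  expect_equal(rep_df$n_at_most_0.1, 1)
})

test_that("command-line front end runs end to end", {
  script <- system.file("exec", "dpmix", package = "dpmixpop")
  if (!nzchar(script)) script <- file.path(find.package("dpmixpop"), "exec", "dpmix")
  expect_true(file.exists(script))
  dir <- withr::local_tempdir()
  sim_to_dir(dir)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(script, "dp",
                            "--input", file.path(dir, "genotypes.txt"),
                            "--outdir", file.path(dir, "cli_run"),
                            "--iterations", "1000", "--burnin", "500",
                            "--thin", "10", "--seed", "5"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "cli_run", "mean_partition.tsv")))
  # missing input: non-zero exit
  bad <- system2(rscript, c(script, "dp", "--input", "no_such_file.txt",
                            "--outdir", file.path(dir, "x")),
                 stdout = FALSE, stderr = FALSE)
  expect_true(bad != 0)
})
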
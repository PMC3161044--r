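# End-to-end pipelines behind the command-line front end (exec/dpmix).
# Each pipeline reads plain-text inputs, runs the corresponding sampler or
# simulator, and writes TSV/Newick artifacts plus a key=value run manifest
# into an output directory, so a run is reproducible from manifest + seed.

write_manifest <- function(outdir, config) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, file.path(outdir, "manifest.txt"))
}

#' Dirichlet-process clustering pipeline
#'
#' Reads a genotype file, runs [run_dp_mcmc()], and writes the sampled
#' trace, the posterior distribution of K, the mean partition, the
#' co-assignment matrix, a Newick dendrogram, and a run manifest.
#'
#' @param input genotype file path ([read_genotype_table()] dialect).
#' @param outdir output directory (created if needed).
#' @param alpha,lambda,lambda_mode,iterations,burnin,thin,sams,gibbs,delta
#'   passed to [run_dp_mcmc()].
#' @param missing_code,ploidy,two_rows passed to [read_genotype_table()].
#' @param seed integer seed (required: pipelines must be reproducible).
#' @return Invisibly, a list with the trace and summary objects.
#' @export
pipeline_dp <- function(input, outdir, alpha = 0.5, lambda = 1,
                        lambda_mode = "fixed", iterations = 20000L,
                        burnin = iterations %/% 2L, thin = 10L,
                        sams = 4L, gibbs = 1L, delta = 0.02,
                        missing_code = -9L, ploidy = 2L, two_rows = FALSE,
                        seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_genotype_table(input, missing_code = missing_code,
                             ploidy = ploidy, two_rows = two_rows)
  tab <- summarize_loci(tab, drop_monomorphic = TRUE)$table
  trace <- run_dp_mcmc(tab, alpha = alpha, lambda = lambda,
                       lambda_mode = lambda_mode, iterations = iterations,
                       burnin = burnin, thin = thin, sams = sams,
                       gibbs = gibbs, delta = delta, seed = seed)
  write_trace(trace, file.path(outdir, "trace.tsv"))
  pk <- posterior_k(trace)
  utils::write.table(pk, file.path(outdir, "posterior_k.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mp <- mean_partition(trace)
  utils::write.table(data.frame(individual = tab$individuals,
                                cluster = mp$partition),
                     file.path(outdir, "mean_partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dd <- coassign_dendrogram(trace, labels = tab$individuals)
  utils::write.table(round(dd$coassign, 4), file.path(outdir, "coassign.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = tab$individuals, col.names = tab$individuals)
  writeLines(dd$newick, file.path(outdir, "dendrogram.nwk"))
  write_manifest(outdir, list(command = "dp", input = input, alpha = alpha,
                              lambda = paste(signif(trace$settings$lambda, 6), collapse = ";"),
                              lambda_mode = lambda_mode,
                              iterations = iterations, burnin = burnin,
                              thin = thin, sams = sams, gibbs = gibbs,
                              delta = delta, missing_code = missing_code,
                              ploidy = ploidy, two_rows = two_rows, seed = seed))
  message(sprintf("dp: %d samples, posterior mean K = %.2f, mean partition K = %d",
                  nrow(trace$labels), attr(pk, "mean"), mp$K))
  invisible(list(trace = trace, posterior_k = pk, mean_partition = mp,
                 dendrogram = dd))
}

#' Fixed-K clustering pipeline
#'
#' Reads a genotype file, runs [run_fixed_k()] (FUM or FCM) for one or more
#' seeds, and writes per-seed assignment probabilities and max-probability
#' partitions.
#'
#' @param input genotype file path.
#' @param outdir output directory.
#' @param K fixed number of clusters.
#' @param model `"FUM"` or `"FCM"`.
#' @param iterations,burnin,thin passed to [run_fixed_k()].
#' @param missing_code,ploidy,two_rows passed to [read_genotype_table()].
#' @param seeds integer vector; one independent run per seed.
#' @return Invisibly, the list of fits.
#' @export
pipeline_fixed_k <- function(input, outdir, K, model = "FUM",
                             iterations = 20000L, burnin = iterations %/% 2L,
                             thin = 10L, missing_code = -9L, ploidy = 2L,
                             two_rows = FALSE, seeds = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_genotype_table(input, missing_code = missing_code,
                             ploidy = ploidy, two_rows = two_rows)
  tab <- summarize_loci(tab, drop_monomorphic = TRUE)$table
  fits <- list()
  for (s in seeds) {
    fit <- run_fixed_k(tab, K = K, model = model, iterations = iterations,
                       burnin = burnin, thin = thin, seed = s)
    tag <- if (length(seeds) > 1L) paste0("_seed", s) else ""
    probs <- as.data.frame(fit$assign_prob)
    names(probs) <- paste0("cluster", seq_len(K))
    utils::write.table(cbind(individual = tab$individuals, round(probs, 4)),
                       file.path(outdir, paste0("assign_prob", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(individual = tab$individuals,
                                  cluster = fit$partition),
                       file.path(outdir, paste0("partition", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("fixedk (%s, K=%d, seed %d): cluster sizes %s", model, K, s,
                    paste(table(fit$partition), collapse = ", ")))
    fits[[as.character(s)]] <- fit
  }
  write_manifest(outdir, list(command = "fixedk", input = input, K = K,
                              model = model, iterations = iterations,
                              burnin = burnin, thin = thin,
                              missing_code = missing_code, ploidy = ploidy,
                              two_rows = two_rows,
                              seeds = paste(seeds, collapse = ";")))
  invisible(fits)
}

#' Simulation pipeline
#'
#' Generates a genotype data set with either the correlated-Dirichlet model
#' or the island Wright-Fisher model and writes `genotypes.txt` (genotype
#' dialect), `truth.tsv` (true labels) and a manifest.
#'
#' @param outdir output directory.
#' @param method `"correlated"` or `"island"`.
#' @param seed integer seed.
#' @param ... parameters forwarded to [sim_correlated()] or to
#'   [sim_island()]/[draw_island_sample()] (`demes_sampled`, `sizes`,
#'   `sample_loci` select the island sample).
#' @return Invisibly, the simulated table and truth.
#' @export
pipeline_simulate <- function(outdir, method = c("correlated", "island"),
                              seed = 1L, ...) {
  method <- match.arg(method)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  if (method == "correlated") {
    keep <- intersect(names(args), names(formals(sim_correlated)))
    sim <- do.call(sim_correlated, c(args[keep], list(seed = seed)))
  } else {
    keep <- intersect(names(args), names(formals(sim_island)))
    isl <- do.call(sim_island, c(args[keep], list(seed = seed)))
    sim <- draw_island_sample(isl,
                              demes = args$demes_sampled,
                              sizes = if (is.null(args$sizes)) c(25L, 25L) else args$sizes,
                              loci = args$sample_loci)
  }
  write_genotype_table(sim$table, file.path(outdir, "genotypes.txt"))
  utils::write.table(data.frame(individual = sim$table$individuals,
                                population = sim$truth),
                     file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(outdir, c(list(command = "simulate", method = method,
                                seed = seed),
                           args[vapply(args, is.atomic, TRUE)]))
  message(sprintf("simulate (%s): %d individuals, %d loci", method,
                  n_individuals(sim$table), n_loci(sim$table)))
  invisible(sim)
}

#' Summarisation pipeline
#'
#' Compares inferred partitions against a truth file and writes a report
#' with the (optionally size-weighted) normalised partition distance per
#' partition file, their mean, and the count of partitions at distance
#' 0.1 or less.
#'
#' @param partition_files TSV files with columns `individual`, `cluster`
#'   (as written by [pipeline_dp()]/[pipeline_fixed_k()]).
#' @param truth_file TSV with columns `individual`, `population`.
#' @param outdir output directory.
#' @param weighted use [weighted_partition_distance()] with equal-total
#'   population weights (the unbalanced-design convention).
#' @return Invisibly, the report data.frame.
#' @export
pipeline_summarize <- function(partition_files, truth_file, outdir,
                               weighted = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- utils::read.delim(truth_file)
  dists <- vapply(partition_files, function(f) {
    part <- utils::read.delim(f)
    ord <- match(truth$individual, part$individual)
    if (anyNA(ord)) stop("individuals in ", f, " do not match the truth file")
    if (weighted)
      weighted_partition_distance(truth$population, part$cluster[ord])$normalized
    else
      partition_distance(truth$population, part$cluster[ord])$normalized
  }, 0)
  report <- data.frame(file = basename(partition_files),
                       distance = round(dists, 4), row.names = NULL)
  utils::write.table(report, file.path(outdir, "distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary_df <- data.frame(mean_distance = mean(dists),
                           n = length(dists),
                           n_at_most_0.1 = sum(dists <= 0.1))
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("summarize: mean distance %.4f over %d partitions (%d <= 0.1)",
                  mean(dists), length(dists), sum(dists <= 0.1)))
  invisible(cbind(report, mean = mean(dists)))
}
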
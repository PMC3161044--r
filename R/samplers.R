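#' Run the Dirichlet-process clustering chain
#'
#' Samples partitions of the individuals from the posterior induced by a
#' Chinese restaurant process prior (concentration `alpha`) and the
#' Dirichlet-multinomial genotype likelihood with allele frequencies
#' integrated out. Each MCMC iteration is either one sequentially-allocated
#' merge-split (SAMS) proposal or one full Gibbs scan; by default four SAMS
#' iterations are followed by one Gibbs scan. The allele-frequency
#' hyperparameter `lambda` can be held fixed, sampled as a single value
#' shared by all loci, or sampled per locus, by Metropolis-Hastings with a
#' `N(lambda, delta^2)` proposal under a uniform `U(0, lambda_upper)` prior.
#'
#' @param x a [genotype_table()].
#' @param alpha DP concentration parameter (> 0); see [crp_alpha_for_k()] to
#'   pick a value from a prior guess at the number of populations.
#' @param lambda initial (or fixed) per-locus Dirichlet hyperparameter;
#'   scalar values are recycled across loci.
#' @param lambda_mode `"fixed"`, `"single"` (one shared sampled value) or
#'   `"unique"` (one sampled value per locus).
#' @param iterations total MCMC iterations.
#' @param burnin iterations discarded before sampling (default half).
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param sams,gibbs cycle composition: `sams` SAMS iterations followed by
#'   `gibbs` Gibbs scans, repeated. `sams = 0` gives a pure Gibbs sampler.
#' @param delta standard deviation of the lambda proposal.
#' @param lambda_upper upper bound of the uniform lambda prior.
#' @param init `"single"` (all individuals in one cluster) or `"random"`
#'   (one CRP prior draw), or an explicit label vector.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param check_consistency verify the incremental sufficient statistics
#'   against a full recount every 1000 iterations (testing aid).
#' @return A `dp_trace` object: `labels` (samples x n matrix of canonical
#'   1-based partitions), `K`, `lambda` (samples x L matrix when sampled),
#'   `acceptance` (per-move acceptance counts), and the run settings.
#' @export
run_dp_mcmc <- function(x, alpha, lambda = 1, lambda_mode = c("fixed", "single", "unique"),
                        iterations = 20000L, burnin = iterations %/% 2L,
                        thin = 10L, sams = 4L, gibbs = 1L, delta = 0.02,
                        lambda_upper = 10, init = c("single", "random"),
                        seed = NULL, check_consistency = FALSE) {
  stopifnot(inherits(x, "genotype_table"))
  lambda_mode <- match.arg(lambda_mode)
  if (alpha <= 0) stop("alpha must be positive")
  if (delta <= 0) stop("delta must be positive")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (gibbs < 1L && sams < 1L) stop("the cycle needs at least one move")
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(x); L <- n_loci(x)
  lambda <- rep_len(lambda, L)
  if (any(lambda <= 0) || any(lambda > lambda_upper))
    stop("lambda must lie in (0, lambda_upper]")
  if (is.character(init)) {
    init <- match.arg(init)
    init_lab <- if (init == "single") rep(0L, n) else {
      labs <- integer(n)
      sizes <- integer(0)
      for (i in seq_len(n)) {
        w <- crp_weights(sizes, alpha)
        j <- sample.int(length(w), 1L, prob = w)
        if (j > length(sizes)) sizes <- c(sizes, 1L) else sizes[j] <- sizes[j] + 1L
        labs[i] <- j
      }
      labs - 1L
    }
  } else {
    init_lab <- canonicalize_labels(init) - 1L
  }
  mode_code <- match(lambda_mode, c("fixed", "single", "unique")) - 1L
  res <- run_dp_chain(geno_cpp(x), as.integer(x$J), x$ploidy, alpha, lambda,
                      mode_code, delta, lambda_upper,
                      as.integer(iterations), as.integer(burnin), as.integer(thin),
                      as.integer(sams), as.integer(gibbs),
                      as.integer(init_lab),
                      if (isTRUE(check_consistency)) 1000L else 0L)
  acc <- lapply(res$accept, function(v) c(accepted = v[1], proposed = v[2]))
  structure(list(labels = res$labels, K = res$K,
                 lambda = if (mode_code > 0L) res$lambda else NULL,
                 acceptance = acc, n = n,
                 settings = list(alpha = alpha, lambda = lambda,
                                 lambda_mode = lambda_mode,
                                 iterations = iterations, burnin = burnin,
                                 thin = thin, sams = sams, gibbs = gibbs,
                                 delta = delta, lambda_upper = lambda_upper)),
            class = "dp_trace")
}

#' @export
print.dp_trace <- function(x, ...) {
  cat(sprintf("dp_trace: %d sampled partitions of %d individuals\n",
              nrow(x$labels), x$n))
  pk <- posterior_k(x)
  cat(sprintf("  posterior mean K: %.2f (mode %d)\n",
              attr(pk, "mean"), pk$K[which.max(pk$prob)]))
  for (mv in names(x$acceptance)) {
    a <- x$acceptance[[mv]]
    if (a["proposed"] > 0)
      cat(sprintf("  %s acceptance: %.4f (%d/%d)\n", mv,
                  a["accepted"] / a["proposed"], a["accepted"], a["proposed"]))
  }
  invisible(x)
}

#' Write a sampled-partition trace as TSV
#'
#' One row per stored sample: sample index, K, sampled lambda values (when
#' present), then one label column per individual.
#'
#' @param trace a `dp_trace` (or the aligned label samples of a fixed-K fit).
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  labs <- if (inherits(trace, "dp_trace")) trace$labels else trace
  df <- data.frame(sample = seq_len(nrow(labs)),
                   K = apply(labs, 1L, max))
  if (inherits(trace, "dp_trace") && !is.null(trace$lambda))
    df <- cbind(df, stats::setNames(as.data.frame(trace$lambda),
                                    paste0("lambda", seq_len(ncol(trace$lambda)))))
  colnames(labs) <- paste0("ind", seq_len(ncol(labs)))
  utils::write.table(cbind(df, labs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal R replica of one SAMS split proposal (testing aid): returns the
# proposed labels and the log allocation probability q(eta'|eta) for a given
# allocation order
sams_split_reference <- function(x, labels, i, j, order, lambda) {
  stopifnot(labels[i] == labels[j])
  L <- n_loci(x); P <- x$ploidy
  lambda <- rep_len(lambda, L)
  empty <- lapply(x$J, function(jj) rep(0L, max(jj, 0L)))
  addc <- function(counts, ind) {
    for (l in seq_len(L)) {
      g <- x$alleles[ind, ((l - 1L) * P + 1L):(l * P)]
      g <- g[!is.na(g)]
      if (length(g)) counts[[l]] <- counts[[l]] + tabulate(g, nbins = x$J[l])
    }
    counts
  }
  ci <- addc(empty, i); cj <- addc(empty, j)
  memi <- i; memj <- j
  logq <- 0
  for (k in order) {
    li <- log(length(memi)) +
      log_predictive_individual(x$alleles[k, ], ci, lambda, x$J, P)
    lj <- log(length(memj)) +
      log_predictive_individual(x$alleles[k, ], cj, lambda, x$J, P)
    lse <- max(li, lj) + log(exp(li - max(li, lj)) + exp(lj - max(li, lj)))
    if (stats::runif(1) < exp(li - lse)) {
      logq <- logq + (li - lse); memi <- c(memi, k); ci <- addc(ci, k)
    } else {
      logq <- logq + (lj - lse); memj <- c(memj, k); cj <- addc(cj, k)
    }
  }
  new_labels <- labels
  new_labels[memj] <- max(labels) + 1L
  list(labels = canonicalize_labels(new_labels), log_q = logq,
       members_i = memi, members_j = memj)
}

# internal: replay the split of a merged cluster into two given subsets in a
# given order, returning log q(eta | eta') for the reverse move
sams_merge_replay_reference <- function(x, members_i, members_j, order, lambda) {
  L <- n_loci(x); P <- x$ploidy
  lambda <- rep_len(lambda, L)
  empty <- lapply(x$J, function(jj) rep(0L, max(jj, 0L)))
  addc <- function(counts, ind) {
    for (l in seq_len(L)) {
      g <- x$alleles[ind, ((l - 1L) * P + 1L):(l * P)]
      g <- g[!is.na(g)]
      if (length(g)) counts[[l]] <- counts[[l]] + tabulate(g, nbins = x$J[l])
    }
    counts
  }
  i <- members_i[1L]; j <- members_j[1L]
  ci <- addc(empty, i); cj <- addc(empty, j)
  szi <- 1L; szj <- 1L
  logq <- 0
  for (k in order) {
    li <- log(szi) + log_predictive_individual(x$alleles[k, ], ci, lambda, x$J, P)
    lj <- log(szj) + log_predictive_individual(x$alleles[k, ], cj, lambda, x$J, P)
    lse <- max(li, lj) + log(exp(li - max(li, lj)) + exp(lj - max(li, lj)))
    if (k %in% members_i) {
      logq <- logq + (li - lse); ci <- addc(ci, k); szi <- szi + 1L
    } else {
      logq <- logq + (lj - lse); cj <- addc(cj, k); szj <- szj + 1L
    }
  }
  logq
}
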
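#' Fixed-K Gibbs samplers with uncorrelated (FUM) or correlated (FCM)
#' allele-frequency priors
#'
#' Baseline no-admixture samplers in which the number of clusters `K` is
#' fixed and the prior probability that an individual belongs to each
#' cluster is `1/K`. Individuals are reassigned according to the genotype
#' likelihood under the current cluster allele frequencies, which are then
#' redrawn from their conditional posteriors:
#'
#' * `FUM` (uncorrelated model): flat `Dirichlet(1)` prior, posterior
#'   `Dirichlet(y_jl + 1)` independently per cluster and locus.
#' * `FCM` (correlated model): `Dirichlet(Pa_l * f_j)` prior around shared
#'   ancestral frequencies `Pa` with per-cluster drift `F_j` (uniform prior
#'   on (0,1), `f_j = (1 - F_j)/F_j`), posterior
#'   `Dirichlet(y_jlh + Pa_lh * f_j)`. `Pa` is updated by a
#'   Dirichlet-neighbourhood Metropolis step and `F_j` by a logit-scale
#'   random walk.
#'
#' During the first half of burn-in the two allele copies of an individual
#' may be assigned to different clusters (an admixture-style warm-up with
#' flat per-individual mixture weights); this keeps early sweeps from
#' stranding empty clusters. Strict whole-individual sweeps follow.
#'
#' Cluster labels of stored samples are aligned to a running reference by
#' greedy maximum shared membership before assignment probabilities are
#' averaged, so label switching cannot smear the posterior means.
#'
#' @param x a [genotype_table()].
#' @param K fixed number of clusters (>= 1).
#' @param model `"FUM"` or `"FCM"`.
#' @param iterations,burnin,thin MCMC schedule (warm-up ends at `burnin/2`).
#' @param pa_conc concentration of the Dirichlet proposal for `Pa`.
#' @param f_sd standard deviation of the logit-scale proposal for `F_j`.
#' @param pa_fixed optional list of per-locus ancestral frequency vectors;
#'   when given, `Pa` is held fixed (testing aid).
#' @param f_fixed optional fixed drift value(s) recycled over clusters.
#' @param seed optional integer seed.
#' @return A `fixedk_fit`: `assign_prob` (n x K posterior assignment
#'   probabilities), `partition` (maximum-probability cluster per
#'   individual), `labels` (aligned sampled label matrix), `acceptance`,
#'   and settings.
#' @export
run_fixed_k <- function(x, K, model = c("FUM", "FCM"),
                        iterations = 20000L, burnin = iterations %/% 2L,
                        thin = 10L, pa_conc = 2000, f_sd = 0.5,
                        pa_fixed = NULL, f_fixed = NULL, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  model <- match.arg(model)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(x)
  # ancestral frequencies initialised at the pooled sample frequencies
  pooled <- summarize_loci(x)$frequencies
  pa <- if (is.null(pa_fixed)) pooled else pa_fixed
  pa_vec <- unlist(lapply(seq_len(L), function(l) {
    f <- pa[[l]]
    if (length(f) != x$J[l]) stop("pa_fixed must match J per locus")
    pmax(f, 1e-6) / sum(pmax(f, 1e-6))
  }))
  f_init <- rep_len(if (is.null(f_fixed)) 0.05 else f_fixed, K)
  res <- run_fixedk_chain(geno_cpp(x), as.integer(x$J), x$ploidy, K,
                          match(model, c("FUM", "FCM")) - 1L,
                          as.integer(iterations), as.integer(burnin),
                          as.integer(thin), as.integer(burnin %/% 2L),
                          pa_conc, f_sd, pa_vec, f_init,
                          !is.null(pa_fixed), !is.null(f_fixed))
  part <- apply(res$assign_prob, 1L, which.max)
  acc <- lapply(res$accept, function(v) c(accepted = v[1], proposed = v[2]))
  structure(list(assign_prob = res$assign_prob,
                 partition = canonicalize_labels(part),
                 labels = res$labels, acceptance = acc,
                 settings = list(K = K, model = model, iterations = iterations,
                                 burnin = burnin, thin = thin,
                                 warmup_end = burnin %/% 2L)),
            class = "fixedk_fit")
}

#' @export
print.fixedk_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("fixedk_fit: %s, K = %d, %d stored samples\n",
              s$model, s$K, nrow(x$labels)))
  cat(sprintf("  cluster sizes of max-probability partition: %s\n",
              paste(table(x$partition), collapse = ", ")))
  if (s$model == "FCM")
    for (mv in names(x$acceptance)) {
      a <- x$acceptance[[mv]]
      if (a["proposed"] > 0)
        cat(sprintf("  %s acceptance: %.3f\n", mv, a["accepted"] / a["proposed"]))
    }
  invisible(x)
}
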
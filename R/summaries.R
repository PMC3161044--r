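#' Partition distance
#'
#' The minimum number of individuals that must be removed from both
#' partitions so that they become identical. Computed as `n` minus the
#' maximum total cluster overlap over one-to-one matchings of the clusters
#' (a linear sum assignment problem solved by the Hungarian algorithm).
#'
#' @param a,b cluster label vectors over the same `n` individuals (any
#'   coding).
#' @return list with `distance` (integer) and `normalized` (`distance/n`).
#' @export
partition_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions cover different numbers of individuals")
  n <- length(a)
  ov <- partition_overlap_cpp(canonicalize_labels(a), canonicalize_labels(b),
                              numeric(0))
  d <- as.integer(round(n - ov))
  list(distance = d, normalized = d / n)
}

#' Size-weighted partition distance
#'
#' Partition distance in which removing individual `i` costs `weights[i]`
#' instead of 1, normalised by the total weight. The default weighting gives
#' every true population the same total weight (`w_i = 1 / n_{pop(i)}` up to
#' scale), so that with sizes 10 and 300 one small-population individual
#' counts as much as 30 large-population individuals.
#'
#' @param truth true cluster labels (weights are derived from these).
#' @param inferred inferred cluster labels.
#' @param weights optional positive per-individual weights overriding the
#'   equal-total-weight rule.
#' @return list with `distance` (weighted), `total_weight`, and `normalized`.
#' @export
weighted_partition_distance <- function(truth, inferred, weights = NULL) {
  if (length(truth) != length(inferred))
    stop("partitions cover different numbers of individuals")
  if (is.null(weights)) {
    sizes <- table(truth)
    weights <- as.vector(1 / sizes[as.character(truth)])
    weights <- weights / min(weights)   # smallest weight 1 (cosmetic scale)
  }
  if (any(weights <= 0)) stop("weights must be positive")
  ov <- partition_overlap_cpp(canonicalize_labels(truth),
                              canonicalize_labels(inferred),
                              as.numeric(weights))
  tot <- sum(weights)
  list(distance = tot - ov, total_weight = tot, normalized = (tot - ov) / tot)
}

#' Mean partition of a set of sampled partitions
#'
#' The partition minimising the total partition distance to all samples,
#' located by greedy coordinate descent: starting from a sampled partition,
#' each individual in turn is tentatively moved to every other cluster and
#' to a new singleton, and the move is kept only if it strictly decreases
#' the total distance; sweeps repeat until no move helps.
#'
#' @param samples matrix of sampled partitions (one row per sample, 1-based
#'   labels) or a `dp_trace`.
#' @param init optional initial partition. By default the starting point is
#'   the sampled partition with the smallest total distance among the most
#'   frequent distinct samples, which makes the greedy search deterministic
#'   and robust to shallow local minima.
#' @param n_starts number of distinct high-frequency samples scored as
#'   candidate starting points.
#' @param max_sweeps safety cap on coordinate-descent sweeps.
#' @return list with `partition` (canonical labels), `K`, `D` (total
#'   distance to all samples), and `mean_normalized` (`D/(v*n)`).
#' @export
mean_partition <- function(samples, init = NULL, max_sweeps = 100L,
                           n_starts = 20L) {
  labs <- if (inherits(samples, "dp_trace")) samples$labels else as.matrix(samples)
  if (nrow(labs) < 1L) stop("at least one sampled partition is required")
  v <- nrow(labs); n <- ncol(labs)
  key <- apply(labs, 1L, paste, collapse = ",")
  tab <- table(key)
  uniq <- labs[match(names(tab), key), , drop = FALSE]
  wt <- as.numeric(tab)
  if (is.null(init)) {
    cand <- order(wt, decreasing = TRUE)[seq_len(min(n_starts, length(wt)))]
    scores <- vapply(cand, function(ci) {
      sum(wt * vapply(seq_len(nrow(uniq)), function(s)
        n - partition_overlap_cpp(uniq[ci, ], uniq[s, ], numeric(0)), 0))
    }, 0)
    init <- uniq[cand[which.min(scores)], ]
  }
  init <- canonicalize_labels(init)
  res <- mean_partition_cpp(uniq, wt, as.integer(init), as.integer(max_sweeps))
  part <- canonicalize_labels(res$partition)
  list(partition = part, K = max(part), D = res$D,
       mean_normalized = res$D / (v * n))
}

#' Pairwise co-assignment probabilities
#'
#' For every pair of individuals, the fraction of sampled partitions in
#' which the two share a cluster.
#'
#' @param samples sampled partition matrix or `dp_trace`.
#' @return symmetric n x n matrix with unit diagonal.
#' @export
coassignment_matrix <- function(samples) {
  labs <- if (inherits(samples, "dp_trace")) samples$labels else as.matrix(samples)
  v <- nrow(labs); n <- ncol(labs)
  C <- matrix(0, n, n)
  for (s in seq_len(v)) {
    Z <- outer(labs[s, ], labs[s, ], "==")
    C <- C + Z
  }
  C / v
}

#' Complete-linkage dendrogram from co-assignment probabilities
#'
#' Agglomerative complete-linkage clustering on the dissimilarity
#' `1 - coassignment`; the merge tree is also rendered in Newick form with
#' branch lengths carrying the merge heights.
#'
#' @param samples sampled partition matrix, `dp_trace`, or a precomputed
#'   co-assignment matrix.
#' @param labels optional tip labels.
#' @return list with `coassign` (the matrix), `hclust`, `phylo` (an
#'   [ape::as.phylo()] tree) and `newick` (string).
#' @export
coassign_dendrogram <- function(samples, labels = NULL) {
  C <- if (is.matrix(samples) && nrow(samples) == ncol(samples) &&
           all(abs(diag(samples) - 1) < 1e-8)) samples
       else coassignment_matrix(samples)
  n <- nrow(C)
  if (is.null(labels)) labels <- paste0("ind", seq_len(n))
  D <- stats::as.dist(1 - C)
  attr(D, "Labels") <- labels
  hc <- stats::hclust(D, method = "complete")
  ph <- ape::as.phylo(hc)
  nw <- ape::write.tree(ph)
  list(coassign = C, hclust = hc, phylo = ph, newick = nw)
}

#' Posterior distribution of the number of clusters
#'
#' @param samples a `dp_trace`, a sampled partition matrix, or an integer
#'   vector of per-sample K values.
#' @return data.frame of K, count, prob with the posterior mean K as
#'   attribute `"mean"`.
#' @export
posterior_k <- function(samples) {
  ks <- if (inherits(samples, "dp_trace")) samples$K
        else if (is.matrix(samples)) apply(samples, 1L, function(z) length(unique(z)))
        else as.integer(samples)
  tab <- table(ks)
  out <- data.frame(K = as.integer(names(tab)), count = as.vector(tab),
                    prob = as.vector(tab) / length(ks))
  attr(out, "mean") <- mean(ks)
  out
}
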
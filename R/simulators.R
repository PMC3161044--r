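# Genotype simulators: a correlated-Dirichlet drift model for generating
# diverged populations around known ancestral frequencies, and an
# island-model Wright-Fisher simulator at allele-frequency resolution.

# internal: dense first-seen recoding of a raw integer allele matrix
recode_dense <- function(raw, ploidy, locus_names = NULL, individuals = NULL) {
  L <- ncol(raw) %/% ploidy
  codes <- matrix(NA_integer_, nrow(raw), ncol(raw))
  allele_labels <- vector("list", L)
  for (l in seq_len(L)) {
    cols <- ((l - 1L) * ploidy + 1L):(l * ploidy)
    block <- raw[, cols, drop = FALSE]
    seen <- unique(as.vector(t(block)))
    seen <- seen[!is.na(seen)]
    allele_labels[[l]] <- as.character(seen)
    codes[, cols] <- match(block, seen)
  }
  genotype_table(codes, ploidy = ploidy, locus_names = locus_names,
                 individuals = individuals, allele_labels = allele_labels)
}

#' Simulate diverged populations under the correlated-Dirichlet drift model
#'
#' For each population and locus, allele frequencies are drawn from
#' `Dirichlet(Pa * (1 - F) / F)` around ancestral frequencies `Pa` with
#' drift parameter `F` (equivalent to Wright's Fst), and genotypes are two
#' independent allele draws per individual (random mating). Loci at which a
#' single allele is observed across the whole data set are excluded.
#'
#' Several locus classes with different ancestral frequency vectors can be
#' mixed by passing a list for `pa` and a vector of per-class locus counts.
#'
#' @param pa ancestral allele frequency vector (sums to 1, all entries > 0),
#'   or a list of such vectors, one per locus class.
#' @param fst drift parameter `F` in (0, 1).
#' @param loci number of loci, or per-class locus counts matching `pa`.
#' @param n_per_pop individuals per population; a vector gives one entry per
#'   population (default two populations of 25).
#' @param drop_monomorphic exclude loci with a single observed allele.
#' @param seed optional integer seed.
#' @return list with `table` (a [genotype_table()]), `truth` (true
#'   population labels) and `freqs` (the drawn per-population frequencies).
#' @export
sim_correlated <- function(pa, fst, loci, n_per_pop = c(25L, 25L),
                           drop_monomorphic = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(pa)) pa <- list(pa)
  if (length(loci) != length(pa))
    stop("loci must give one count per ancestral frequency vector")
  for (p in pa) {
    if (any(p <= 0)) stop("ancestral frequencies must be strictly positive")
    if (abs(sum(p) - 1) > 1e-8) stop("ancestral frequencies must sum to 1")
  }
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  n_per_pop <- as.integer(n_per_pop)
  K <- length(n_per_pop)
  n <- sum(n_per_pop)
  truth <- rep(seq_len(K), n_per_pop)
  f <- (1 - fst) / fst
  class_of <- rep(seq_along(pa), loci)
  L <- length(class_of)
  raw <- matrix(NA_integer_, n, 2L * L)
  freqs <- vector("list", K)
  for (j in seq_len(K)) freqs[[j]] <- vector("list", L)
  for (l in seq_len(L)) {
    p0 <- pa[[class_of[l]]]
    J <- length(p0)
    for (j in seq_len(K)) {
      gam <- stats::rgamma(J, shape = p0 * f)
      phi <- gam / sum(gam)
      if (any(!is.finite(phi)) || sum(gam) <= 0) phi <- p0
      freqs[[j]][[l]] <- phi
      rows <- which(truth == j)
      draws <- sample.int(J, 2L * length(rows), replace = TRUE, prob = phi)
      raw[rows, 2L * l - 1L] <- draws[seq_along(rows)]
      raw[rows, 2L * l] <- draws[length(rows) + seq_along(rows)]
    }
  }
  tab <- recode_dense(raw, ploidy = 2L)
  if (drop_monomorphic) {
    poly <- tab$J > 1L
    if (!any(poly)) stop("all simulated loci are monomorphic")
    tab <- summarize_loci(tab, drop_monomorphic = TRUE)$table
  }
  list(table = tab, truth = truth, freqs = freqs)
}

#' Simulate island-model base populations under the Wright-Fisher model
#'
#' A finite-island model of `demes` populations of constant diploid size.
#' Each generation every deme receives a fraction `migration` of its gene
#' pool from the average of the other demes, alleles mutate at rate `mu` to
#' one of `states` allelic states chosen uniformly (K-allele model), and the
#' next generation's `2N` allele copies are drawn multinomially. The first
#' generation assigns allele copies uniformly at random over the possible
#' states. Unlinked loci evolve independently, so the model is simulated at
#' allele-frequency resolution, which is distributionally equivalent to an
#' individual-based model for the unlinked random-mating statistics used
#' here.
#'
#' @param demes number of populations.
#' @param deme_size diploid individuals per population.
#' @param generations generations to evolve.
#' @param loci number of loci.
#' @param states possible allelic states (K-allele model).
#' @param mu mutation rate per copy per generation.
#' @param migration immigrant fraction per generation, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return An `island_freqs` object: array `freq` of dimension
#'   `states x demes x loci` plus the scenario parameters.
#' @seealso [draw_island_sample()] to genotype individuals from the final
#'   frequencies.
#' @export
sim_island <- function(demes = 8L, deme_size = 1000L, generations = 5000L,
                       loci = 50L, states = 10L, mu = 5e-4,
                       migration = 0.003, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (demes < 2L) stop("at least two demes are required")
  if (migration < 0 || migration > 1) stop("migration must lie in [0, 1]")
  if (any(c(deme_size, generations, loci, states) < 1L)) stop("all sizes must be positive")
  freq <- sim_island_chain(as.integer(demes), as.integer(deme_size),
                           as.integer(generations), as.integer(loci),
                           as.integer(states), mu, migration)
  structure(list(freq = freq, demes = demes, deme_size = deme_size,
                 generations = generations, loci = loci, states = states,
                 mu = mu, migration = migration),
            class = "island_freqs")
}

#' @export
print.island_freqs <- function(x, ...) {
  cat(sprintf("island_freqs: %d demes x %d, %d loci, %d states, %d generations\n",
              x$demes, x$deme_size, x$loci, x$states, x$generations))
  cat(sprintf("  mu = %g, migration = %g\n", x$mu, x$migration))
  invisible(x)
}

#' Draw a genotype sample from island-model base populations
#'
#' Genotypes individuals by two independent allele draws per locus from the
#' final allele frequencies of their source deme (random mating).
#'
#' @param island an `island_freqs` object from [sim_island()].
#' @param demes which demes to sample (default: `length(sizes)` demes chosen
#'   at random).
#' @param sizes individuals to draw from each sampled deme.
#' @param loci number of loci to subsample at random, or an explicit index
#'   vector; `NULL` keeps all loci.
#' @param drop_monomorphic exclude loci with one observed allele in the
#'   sample.
#' @param seed optional integer seed.
#' @return list with `table`, `truth` (source deme of each individual, as
#'   1..length(demes)), and `demes`/`loci` actually used.
#' @export
draw_island_sample <- function(island, demes = NULL, sizes = c(25L, 25L),
                               loci = NULL, drop_monomorphic = TRUE,
                               seed = NULL) {
  stopifnot(inherits(island, "island_freqs"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(demes)) demes <- sample.int(island$demes, length(sizes))
  if (length(demes) != length(sizes)) stop("demes and sizes must match")
  loci_idx <- if (is.null(loci)) seq_len(island$loci)
              else if (length(loci) == 1L) sort(sample.int(island$loci, loci))
              else as.integer(loci)
  n <- sum(sizes)
  L <- length(loci_idx)
  truth <- rep(seq_along(demes), sizes)
  raw <- matrix(NA_integer_, n, 2L * L)
  row0 <- 0L
  for (k in seq_along(demes)) {
    d <- demes[k]
    rows <- row0 + seq_len(sizes[k])
    for (li in seq_len(L)) {
      p <- island$freq[, d, loci_idx[li]]
      draws <- sample.int(island$states, 2L * sizes[k], replace = TRUE, prob = p)
      raw[rows, 2L * li - 1L] <- draws[seq_len(sizes[k])]
      raw[rows, 2L * li] <- draws[sizes[k] + seq_len(sizes[k])]
    }
    row0 <- row0 + sizes[k]
  }
  tab <- recode_dense(raw, ploidy = 2L,
                      locus_names = paste0("L", loci_idx))
  if (drop_monomorphic && any(tab$J > 1L) && any(tab$J <= 1L))
    tab <- summarize_loci(tab, drop_monomorphic = TRUE)$table
  list(table = tab, truth = truth, demes = demes, loci = loci_idx)
}

#' Pairwise Weir-Cockerham Fst
#'
#' Multilocus Weir-Cockerham (1984) theta for every pair of populations,
#' computed as the ratio of summed variance components over loci and
#' alleles.
#'
#' @param x a diploid [genotype_table()].
#' @param labels population labels (>= 2 populations, each with >= 2
#'   individuals).
#' @return K x K symmetric matrix of pairwise theta (diagonal `NA`).
#' @export
pairwise_fst <- function(x, labels) {
  stopifnot(inherits(x, "genotype_table"))
  labs <- canonicalize_labels(labels)
  K <- max(labs)
  if (K < 2L) stop("at least two populations are required")
  if (any(table(labs) < 2L)) stop("each population needs >= 2 individuals")
  out <- matrix(NA_real_, K, K)
  for (a in seq_len(K - 1L))
    for (b in (a + 1L):K) {
      rows <- labs %in% c(a, b)
      out[a, b] <- out[b, a] <- wc_theta(x, labs[rows], rows_idx = which(rows))
    }
  out
}

#' Multilocus Weir-Cockerham theta
#'
#' @param x a diploid [genotype_table()].
#' @param labels population labels for the rows used.
#' @param rows_idx optional row subset of `x` matching `labels`.
#' @return theta (ratio of summed `a` over summed `a + b + c` components).
#' @export
wc_theta <- function(x, labels, rows_idx = NULL) {
  if (x$ploidy != 2L) stop("theta requires diploid data")
  if (is.null(rows_idx)) rows_idx <- seq_len(n_individuals(x))
  labs <- canonicalize_labels(labels)
  r <- max(labs)
  num <- 0; den <- 0
  for (l in seq_len(n_loci(x))) {
    if (x$J[l] < 2L) next
    c1 <- x$alleles[rows_idx, 2L * l - 1L]
    c2 <- x$alleles[rows_idx, 2L * l]
    ok <- !is.na(c1) & !is.na(c2)
    if (!any(ok)) next
    ni <- tabulate(labs[ok], nbins = r)
    if (any(ni < 1L)) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (h in seq_len(x$J[l])) {
      cnt1 <- (c1 == h) + (c2 == h)          # copies of allele h per individual
      het <- (cnt1 == 1L)
      pih <- vapply(seq_len(r), function(j) {
        w <- ok & labs == j
        sum(cnt1[w]) / (2 * sum(w))
      }, 0)
      hih <- vapply(seq_len(r), function(j) {
        w <- ok & labs == j
        sum(het[w]) / sum(w)
      }, 0)
      pbar <- sum(ni * pih) / (r * nbar)
      if (pbar <= 0 || pbar >= 1) next
      s2 <- sum(ni * (pih - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hih) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}
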
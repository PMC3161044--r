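# Independent oracles and small fixtures used across the suite.

# all set partitions of 1..n as canonical label vectors (restricted growth)
enum_partitions <- function(n) {
  out <- list()
  rec <- function(labs, mx) {
    i <- length(labs) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labs
      return(invisible())
    }
    for (j in seq_len(mx + 1L)) rec(c(labs, j), max(mx, j))
  }
  rec(integer(0), 0L)
  out
}

# exact posterior over all set partitions: CRP prior x Dirichlet-multinomial
# marginal per cluster
exact_posterior <- function(tab, alpha, lambda) {
  parts <- enum_partitions(n_individuals(tab))
  logp <- vapply(parts, function(p) {
    lp <- log_partition_prior(p, alpha)
    for (j in unique(p)) lp <- lp + log_marginal_set(tab, which(p == j), lambda)
    lp
  }, 0)
  w <- exp(logp - max(logp))
  list(partitions = parts, prob = w / sum(w),
       key = vapply(parts, paste, "", collapse = ","))
}

empirical_partition_dist <- function(labels_matrix, key) {
  emp <- table(factor(apply(labels_matrix, 1L, paste, collapse = ","),
                      levels = key))
  as.vector(emp) / nrow(labels_matrix)
}

# brute-force partition distance: smallest set of individuals whose removal
# makes the two induced partitions identical (independent of the
# assignment-problem route)
brute_partition_distance <- function(a, b) {
  n <- length(a)
  same_induced <- function(keep) {
    if (length(keep) == 0L) return(TRUE)
    identical(canonicalize_labels(a[keep]), canonicalize_labels(b[keep]))
  }
  for (s in 0:n) {
    if (s == 0L && same_induced(seq_len(n))) return(0L)
    if (s > 0L) {
      combs <- utils::combn(n, s)
      for (cix in seq_len(ncol(combs)))
        if (same_induced(setdiff(seq_len(n), combs[, cix]))) return(s)
    }
  }
  n
}

# brute-force maximum cluster-overlap matching (all injective matchings)
brute_max_overlap <- function(a, b) {
  a <- canonicalize_labels(a); b <- canonicalize_labels(b)
  Ka <- max(a); Kb <- max(b)
  ov <- matrix(0, Ka, Kb)
  for (i in seq_along(a)) ov[a[i], b[i]] <- ov[a[i], b[i]] + 1
  small <- min(Ka, Kb); big <- max(Ka, Kb)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(big))) {
    m <- p[seq_len(small)]
    tot <- sum(vapply(seq_len(small), function(i)
      if (Ka <= Kb) ov[i, m[i]] else ov[m[i], i], 0))
    best <- max(best, tot)
  }
  best
}

# deterministic small diploid table from a raw allele matrix
make_table <- function(raw, ploidy = 2L) genotype_table(as.matrix(raw), ploidy = ploidy)

# random SNP table with a fixed seed
random_snp_table <- function(n, L, seed) {
  set.seed(seed)
  genotype_table(matrix(sample(1:2, n * 2L * L, TRUE), n, 2L * L))
}

# genotype file on disk for io tests
write_geno_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
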
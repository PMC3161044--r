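#' Construct a genotype table
#'
#' A `genotype_table` holds multilocus genotypes for `n` individuals at `L`
#' loci as dense 0-based allele codes recoded per locus, stored 1-based on the
#' R side. For diploid data each locus occupies two adjacent columns whose
#' order carries no meaning; missing allele copies are `NA`.
#'
#' @param alleles integer matrix, `n x (ploidy*L)`, 1-based allele codes with
#'   `NA` for missing copies. Codes at locus `l` must lie in `1..J[l]`.
#' @param ploidy 1 or 2.
#' @param locus_names character vector of length `L`.
#' @param individuals character vector of row labels.
#' @param allele_labels list of length `L`; element `l` gives the original
#'   on-disk allele labels in code order (used to round-trip files). Defaults
#'   to the codes themselves.
#' @return An object of class `genotype_table` with elements `alleles`,
#'   `ploidy`, `J` (observed alleles per locus), `locus_names`,
#'   `individuals`, `allele_labels`.
#' @export
genotype_table <- function(alleles, ploidy = 2L, locus_names = NULL,
                           individuals = NULL, allele_labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (nrow(alleles) < 1L) stop("empty input: no individuals")
  if (ncol(alleles) %% ploidy != 0L) stop("allele matrix width is not a multiple of ploidy")
  L <- ncol(alleles) %/% ploidy
  if (L < 1L) stop("empty input: no loci")
  if (any(alleles < 1L, na.rm = TRUE)) stop("allele codes must be >= 1")
  J <- integer(L)
  for (l in seq_len(L)) {
    cols <- ((l - 1L) * ploidy + 1L):(l * ploidy)
    v <- alleles[, cols]
    J[l] <- if (all(is.na(v))) 0L else max(v, na.rm = TRUE)
  }
  if (is.null(locus_names)) locus_names <- paste0("L", seq_len(L))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(alleles)))
  if (is.null(allele_labels)) allele_labels <- lapply(J, function(j) as.character(seq_len(max(j, 0L))))
  structure(list(alleles = alleles, ploidy = ploidy, J = J,
                 locus_names = as.character(locus_names),
                 individuals = as.character(individuals),
                 allele_labels = allele_labels),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, ploidy %d\n",
              n_individuals(x), n_loci(x), x$ploidy))
  cat(sprintf("  alleles per locus: %s\n",
              paste(range(x$J), collapse = "-")))
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing allele copies: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`
#' @export
n_individuals <- function(x) nrow(x$alleles)

#' @rdname genotype_table
#' @export
n_loci <- function(x) length(x$J)

#' Read a genotype table from a whitespace-delimited text file
#'
#' The expected dialect is one row per individual: a label followed by
#' `ploidy * L` integer allele columns (two adjacent columns per locus for
#' diploids). The STRUCTURE-style two-rows-per-individual layout (label plus
#' `L` columns on each of two consecutive rows) is accepted via
#' `two_rows = TRUE`. Raw allele labels are recoded to dense per-locus codes
#' in first-seen order; the recode map is retained so [write_genotype_table()]
#' round-trips files exactly.
#'
#' @param path path to the genotype file.
#' @param missing_code integer sentinel marking a missing allele copy
#'   (default -9).
#' @param ploidy 1 or 2.
#' @param two_rows logical; parse the two-rows-per-individual dialect.
#' @param locus_names optional locus names (default `L1..LL`).
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, missing_code = -9L, ploidy = 2L,
                                two_rows = FALSE, locus_names = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: no individuals in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ploidy <- as.integer(ploidy)

  if (two_rows) {
    if (length(toks) %% 2L != 0L)
      stop("two-row dialect needs an even number of data lines, got ", length(toks))
    if (ploidy != 2L) stop("two-row dialect implies ploidy 2")
    merged <- vector("list", length(toks) %/% 2L)
    for (i in seq_along(merged)) {
      r1 <- toks[[2L * i - 1L]]
      r2 <- toks[[2L * i]]
      if (length(r1) != length(r2))
        stop("parse error at line ", 2L * i,
             ": row pair differs in column count (", length(r1), " vs ", length(r2), ")")
      L <- length(r1) - 1L
      g <- character(2L * L)
      g[seq(1L, 2L * L, by = 2L)] <- r1[-1L]
      g[seq(2L, 2L * L, by = 2L)] <- r2[-1L]
      merged[[i]] <- c(r1[1L], g)
    }
    toks <- merged
  }

  width <- length(toks[[1L]])
  if (width < 1L + ploidy) stop("parse error at line 1: too few columns")
  if ((width - 1L) %% ploidy != 0L)
    stop("parse error at line 1: ", width - 1L,
         " allele columns is not a multiple of ploidy ", ploidy)
  L <- (width - 1L) %/% ploidy
  n <- length(toks)
  labels <- character(n)
  raw <- matrix(NA_integer_, n, ploidy * L)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != width)
      stop("parse error at line ", i, ": expected ", width,
           " columns, found ", length(tk))
    labels[i] <- tk[1L]
    v <- suppressWarnings(as.integer(tk[-1L]))
    if (anyNA(v))
      stop("parse error at line ", i, ": non-integer allele value")
    raw[i, ] <- v
  }
  raw[raw == as.integer(missing_code)] <- NA_integer_

  codes <- matrix(NA_integer_, n, ploidy * L)
  allele_labels <- vector("list", L)
  for (l in seq_len(L)) {
    cols <- ((l - 1L) * ploidy + 1L):(l * ploidy)
    block <- raw[, cols, drop = FALSE]
    seen <- unique(as.vector(t(block)))   # first-seen order, row-major by slot
    seen <- seen[!is.na(seen)]
    allele_labels[[l]] <- as.character(seen)
    codes[, cols] <- match(block, seen)
  }
  genotype_table(codes, ploidy = ploidy, locus_names = locus_names,
                 individuals = labels, allele_labels = allele_labels)
}

#' Write a genotype table back to the on-disk dialect
#'
#' Inverse of [read_genotype_table()]: allele codes are mapped back through
#' the stored recode map and missing copies become `missing_code`.
#'
#' @param x a [genotype_table()].
#' @param path output path.
#' @param missing_code sentinel for missing copies.
#' @export
write_genotype_table <- function(x, path, missing_code = -9L) {
  stopifnot(inherits(x, "genotype_table"))
  n <- n_individuals(x); L <- n_loci(x); P <- x$ploidy
  out <- matrix("", n, P * L)
  for (l in seq_len(L)) {
    cols <- ((l - 1L) * P + 1L):(l * P)
    lab <- x$allele_labels[[l]]
    v <- x$alleles[, cols, drop = FALSE]
    ch <- matrix(lab[v], nrow = n)
    ch[is.na(v)] <- as.character(missing_code)
    out[, cols] <- ch
  }
  writeLines(paste(x$individuals, apply(out, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' Per-locus allele summaries
#'
#' Computes the number of observed alleles `J_l`, allele frequencies over
#' non-missing copies, observed heterozygosity, and flags monomorphic loci.
#' With `drop_monomorphic = TRUE` a filtered table excluding loci with a
#' single observed allele is returned alongside the summary, following the
#' convention that uninformative loci are removed before clustering.
#'
#' @param x a [genotype_table()].
#' @param drop_monomorphic drop loci with `J_l <= 1` from the returned table.
#' @return A list with `summary` (data.frame: locus, J, monomorphic, het_obs,
#'   maj_freq), `frequencies` (list of per-locus frequency vectors),
#'   `mean_het` (mean observed heterozygosity across loci), and `table`
#'   (the input, filtered when requested).
#' @export
summarize_loci <- function(x, drop_monomorphic = FALSE) {
  stopifnot(inherits(x, "genotype_table"))
  L <- n_loci(x); P <- x$ploidy
  freqs <- vector("list", L)
  het <- numeric(L)
  for (l in seq_len(L)) {
    cols <- ((l - 1L) * P + 1L):(l * P)
    v <- x$alleles[, cols, drop = FALSE]
    obs <- v[!is.na(v)]
    freqs[[l]] <- if (length(obs)) as.vector(table(factor(obs, levels = seq_len(x$J[l])))) / length(obs)
                  else numeric(0)
    names(freqs[[l]]) <- x$allele_labels[[l]]
    if (P == 2L) {
      ok <- !is.na(v[, 1L]) & !is.na(v[, 2L])
      het[l] <- if (any(ok)) mean(v[ok, 1L] != v[ok, 2L]) else NA_real_
    } else het[l] <- NA_real_
  }
  summ <- data.frame(
    locus = x$locus_names,
    J = x$J,
    monomorphic = x$J <= 1L,
    het_obs = het,
    maj_freq = vapply(freqs, function(f) if (length(f)) max(f) else NA_real_, 0),
    stringsAsFactors = FALSE)
  tab <- x
  if (drop_monomorphic) {
    keep <- which(x$J > 1L)
    if (length(keep) == 0L)
      stop("empty table: all loci are monomorphic")
    cols <- as.vector(vapply(keep, function(l) ((l - 1L) * P + 1L):(l * P),
                             integer(P)))
    tab <- genotype_table(x$alleles[, cols, drop = FALSE], ploidy = P,
                          locus_names = x$locus_names[keep],
                          individuals = x$individuals,
                          allele_labels = x$allele_labels[keep])
  }
  list(summary = summ, frequencies = freqs,
       mean_het = mean(het, na.rm = TRUE), table = tab)
}

#' Observed heterozygosity
#'
#' Fraction of heterozygous genotypes among fully observed diploid genotypes,
#' per locus and averaged across loci.
#'
#' @param x a diploid [genotype_table()].
#' @return list with `per_locus` and `mean`.
#' @export
observed_heterozygosity <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (x$ploidy != 2L) stop("observed heterozygosity requires diploid data")
  s <- summarize_loci(x)
  list(per_locus = stats::setNames(s$summary$het_obs, s$summary$locus),
       mean = s$mean_het)
}

# internal: 0-based matrix with -1 sentinel for the compiled core
geno_cpp <- function(x) {
  m <- x$alleles - 1L
  m[is.na(m)] <- -1L
  storage.mode(m) <- "integer"
  m
}
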
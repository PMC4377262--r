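#' Diploid codominant genotype matrix
#'
#' The central container of the package: diploid allele calls for a set of
#' individuals at a set of loci, with one population (sample) label per
#' individual. Allele codes are positive integers (microsatellite allele
#' sizes or arbitrary codes); a missing call is missing for the whole diploid
#' genotype, never for a single allele, matching GENEPOP semantics.
#'
#' @param calls integer array of dimension `n_individuals x n_loci x 2`;
#'   `NA` marks a missing call (both gene copies must be `NA` together).
#' @param pop character or factor of population labels, one per individual.
#' @param individuals optional character vector of individual ids. Ids need
#'   not be unique across populations; the internal key is (population, row).
#' @param loci optional character vector of locus names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, pop, individuals = NULL, loci = NULL) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an n x L x 2 array")
  n <- dim(calls)[1]
  L <- dim(calls)[2]
  if (n < 1L || L < 1L) stop("empty input: need at least one individual and one locus")
  if (length(pop) != n) stop("`pop` must have one label per individual")
  half_missing <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half_missing)) stop("half-missing calls are not allowed: a call is missing as a whole")
  if (any(calls <= 0, na.rm = TRUE)) stop("allele codes must be positive integers")
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  if (length(loci) != L) stop("`loci` must name every locus")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(NULL, loci, NULL)
  structure(
    list(calls = calls,
         pop = factor(pop, levels = unique(as.character(pop))),
         individuals = as.character(individuals),
         loci = as.character(loci)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_ind(x), "individuals,", n_loci(x), "loci,",
      nlevels(x$pop), "populations\n")
  cat("populations:",
      paste(sprintf("%s (%d)", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_ind <- function(x) dim(x$calls)[1]

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) dim(x$calls)[2]

#' @rdname genotype_matrix
#' @export
pop_names <- function(x) levels(x$pop)

#' Subset a genotype matrix by population and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param pops populations to keep (labels); `NULL` keeps all.
#' @param loci loci to keep (names or indices); `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_geno <- function(x, pops = NULL, loci = NULL) {
  keep_i <- if (is.null(pops)) seq_len(n_ind(x)) else which(x$pop %in% pops)
  keep_l <- if (is.null(loci)) seq_len(n_loci(x)) else {
    if (is.character(loci)) match(loci, x$loci) else loci
  }
  if (anyNA(keep_l)) stop("unknown locus name")
  if (length(keep_i) == 0L) stop("no individuals left after subsetting")
  genotype_matrix(x$calls[keep_i, keep_l, , drop = FALSE],
                  pop = as.character(x$pop[keep_i]),
                  individuals = x$individuals[keep_i],
                  loci = x$loci[keep_l])
}

## Per-locus, per-population sufficient statistics used by every estimator:
## n[i]      typed diploids in population i
## counts    population x allele matrix of gene counts
## het       population x allele matrix of counts of heterozygous individuals
##           carrying that allele
locus_stats <- function(x, locus, pops = NULL) {
  if (is.character(locus)) locus <- match(locus, x$loci)
  a1 <- x$calls[, locus, 1]
  a2 <- x$calls[, locus, 2]
  pop <- x$pop
  if (!is.null(pops)) {
    keep <- pop %in% pops
    a1 <- a1[keep]; a2 <- a2[keep]
    pop <- factor(as.character(pop[keep]), levels = pops)
  }
  typed <- !is.na(a1)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  r <- nlevels(pop)
  counts <- matrix(0L, r, length(alleles), dimnames = list(levels(pop), alleles))
  het <- matrix(0L, r, length(alleles), dimnames = list(levels(pop), alleles))
  n <- integer(r)
  for (i in seq_len(r)) {
    sel <- typed & (as.integer(pop) == i)
    n[i] <- sum(sel)
    if (n[i] == 0L) next
    counts[i, ] <- tabulate(match(c(a1[sel], a2[sel]), alleles), length(alleles))
    is_het <- a1[sel] != a2[sel]
    if (any(is_het)) {
      hh <- c(a1[sel][is_het], a2[sel][is_het])
      het[i, ] <- tabulate(match(hh, alleles), length(alleles))
    }
  }
  list(alleles = alleles, n = n, counts = counts, het = het)
}

## Allele frequencies per population for one locus (rows sum to 1 where typed)
locus_freqs <- function(x, locus, pops = NULL) {
  st <- locus_stats(x, locus, pops)
  freq <- st$counts / pmax(2 * st$n, 1L)
  freq[st$n == 0L, ] <- NA_real_
  list(alleles = st$alleles, n = st$n, freq = freq)
}
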
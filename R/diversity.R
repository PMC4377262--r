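#' Observed and unbiased expected heterozygosity per locus
#'
#' Computes, for one sample (population), per-locus observed heterozygosity
#' (fraction of heterozygous individuals among the typed ones) and Nei's
#' unbiased gene diversity `He = (2n/(2n-1)) (1 - sum p_u^2)` with `n` the
#' number of typed diploids.
#'
#' Loci typed in fewer than 2 individuals are returned as `NA` (flagged
#' absent) and should be excluded from means.
#'
#' @param geno a [genotype_matrix()].
#' @param sample population label.
#' @return a data.frame with columns `locus`, `n`, `Ho`, `He`.
#' @export
heterozygosity <- function(geno, sample) {
  if (!sample %in% levels(geno$pop)) stop("unknown sample: ", sample)
  out <- data.frame(locus = geno$loci, n = NA_integer_,
                    Ho = NA_real_, He = NA_real_)
  for (l in seq_len(n_loci(geno))) {
    st <- locus_stats(geno, l, pops = sample)
    n <- st$n[1]
    out$n[l] <- n
    if (n < 2L) next
    p <- st$counts[1, ] / (2 * n)
    n_het <- sum(st$het[1, ]) / 2  # each het individual counted for 2 alleles
    out$Ho[l] <- n_het / n
    out$He[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }
  out
}

## Weir & Cockerham within-sample components (b, c) for a single population,
## per locus, summed over alleles. f = sum(b) / sum(b + c).
fis_components <- function(geno, sample) {
  L <- n_loci(geno)
  b <- numeric(L); cc <- numeric(L)
  for (l in seq_len(L)) {
    st <- locus_stats(geno, l, pops = sample)
    n <- st$n[1]
    if (n < 2L || length(st$alleles) < 2L) { b[l] <- NA; cc[l] <- NA; next }
    p <- st$counts[1, ] / (2 * n)
    h <- st$het[1, ] / n
    b[l] <- sum((n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h))
    cc[l] <- sum(h / 2)
  }
  data.frame(locus = geno$loci, b = b, c = cc)
}

#' Weir-Cockerham f (F_IS) with a permutation test for panmixia
#'
#' The multi-locus f is the ratio of sums of the Weir-Cockerham
#' within-sample variance components over loci and alleles. The null
#' distribution is obtained by shuffling alleles among individuals within
#' the sample and locus (which enforces Hardy-Weinberg proportions while
#' preserving allele frequencies); the two-sided p-value uses |f| with the
#' add-one rule.
#'
#' @param geno a [genotype_matrix()].
#' @param sample population label.
#' @param n_perm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return list with `f`, `p`, `n_perm`, `per_locus` (component table).
#' @export
fis_test <- function(geno, sample, n_perm = 999, seed = NULL) {
  comp <- fis_components(geno, sample)
  ok <- !is.na(comp$b)
  if (!any(ok)) stop("f is undefined: all loci monomorphic or untyped in ", sample)
  f_obs <- sum(comp$b[ok]) / sum(comp$b[ok] + comp$c[ok])

  ## Per-locus allele pools: under the within-sample permutation the allele
  ## frequencies are fixed, only the heterozygote frequencies h_u change, so
  ## each permutation just re-pairs the pooled gene copies.
  sub <- subset_geno(geno, pops = sample)
  prep <- list()
  for (l in seq_len(n_loci(sub))) {
    a1 <- sub$calls[, l, 1]; a2 <- sub$calls[, l, 2]
    typed <- which(!is.na(a1))
    if (length(typed) < 2L) next
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    if (length(alleles) < 2L) next
    m <- length(typed)
    pool <- match(c(a1[typed], a2[typed]), alleles)
    p <- tabulate(pool, length(alleles)) / (2 * m)
    prep[[length(prep) + 1L]] <- list(pool = pool, m = m, p = p,
                                      K = length(alleles))
  }
  f_perm <- numeric(n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      bs <- cs <- 0
      for (pr in prep) {
        pl <- pr$pool[sample.int(2L * pr$m)]
        a1p <- pl[seq_len(pr$m)]; a2p <- pl[pr$m + seq_len(pr$m)]
        hets <- a1p != a2p
        h <- (tabulate(a1p[hets], pr$K) + tabulate(a2p[hets], pr$K)) / pr$m
        m <- pr$m; p <- pr$p
        bs <- bs + sum((m / (m - 1)) * (p * (1 - p) - (2 * m - 1) / (4 * m) * h))
        cs <- cs + sum(h / 2)
      }
      f_perm[k] <- bs / (bs + cs)
    }
  })
  list(f = f_obs, p = perm_pvalue(abs(f_obs), abs(f_perm)),
       n_perm = n_perm, per_locus = comp)
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction of the allele count to a standard number of
#' gene copies `g`:
#' `Ar(g) = sum_u [1 - C(N - N_u, g) / C(N, g)]`
#' with `N` the typed gene copies at the locus in the sample and `N_u` the
#' copies of allele `u`. `Ar(g)` is the expected number of distinct alleles
#' in a random subsample of `g` gene copies, which makes samples of unequal
#' size comparable.
#'
#' @param geno a [genotype_matrix()].
#' @param sample population label.
#' @param g number of gene copies to rarefy to (e.g. 64 genes = 32 diploids).
#' @return data.frame with columns `locus`, `N`, `Ar`; loci with fewer than
#'   `g` typed gene copies get `NA` with a warning.
#' @export
allelic_richness <- function(geno, sample, g) {
  if (g < 1) stop("g must be at least 1")
  out <- data.frame(locus = geno$loci, N = NA_integer_, Ar = NA_real_)
  skipped <- character(0)
  for (l in seq_len(n_loci(geno))) {
    st <- locus_stats(geno, l, pops = sample)
    N <- 2L * st$n[1]
    out$N[l] <- N
    if (N < g) { skipped <- c(skipped, geno$loci[l]); next }
    Nu <- st$counts[1, ]
    Nu <- Nu[Nu > 0]
    out$Ar[l] <- sum(1 - exp(lchoose(N - Nu, g) - lchoose(N, g)))
  }
  if (length(skipped))
    warning("excluded loci with fewer than g typed genes: ",
            paste(skipped, collapse = ", "))
  out
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotype contingency
#' table within one sample, with the null distribution generated by shuffling
#' one locus's genotypes among individuals (breaking any association while
#' preserving both single-locus genotype distributions).
#'
#' @param geno a [genotype_matrix()].
#' @param sample population label.
#' @param locus_a,locus_b locus names or indices.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `p`, `G`, `n`, `testable`.
#' @export
ld_test <- function(geno, sample, locus_a, locus_b, n_perm = 999, seed = NULL) {
  sub <- subset_geno(geno, pops = sample)
  la <- if (is.character(locus_a)) match(locus_a, sub$loci) else locus_a
  lb <- if (is.character(locus_b)) match(locus_b, sub$loci) else locus_b
  if (anyNA(c(la, lb))) stop("unknown locus name")
  ga <- geno_codes(sub, la)
  gb <- geno_codes(sub, lb)
  keep <- !is.na(ga) & !is.na(gb)
  if (sum(keep) < 5L)
    return(list(p = NA_real_, G = NA_real_, n = sum(keep), testable = FALSE))
  ga <- factor(ga[keep]); gb <- factor(gb[keep])
  if (nlevels(ga) < 2L || nlevels(gb) < 2L)
    stop("both loci must be polymorphic in ", sample)
  g_obs <- g_statistic(table(ga, gb))
  g_perm <- numeric(n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm))
      g_perm[k] <- g_statistic(table(ga, sample(gb)))
  })
  list(p = perm_pvalue(g_obs, g_perm), G = g_obs, n = length(ga),
       testable = TRUE)
}

## Unordered diploid genotype code per individual at one locus ("a/b", a<=b).
geno_codes <- function(x, locus) {
  a1 <- x$calls[, locus, 1]; a2 <- x$calls[, locus, 2]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  ifelse(is.na(a1), NA_character_, paste(lo, hi, sep = "/"))
}

## G statistic (2 * sum O log(O/E)) on a contingency table, zero cells skipped.
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / E[idx]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone in rank), as used for
#' the per-sample Hardy-Weinberg and linkage-disequilibrium test batteries.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-sample diversity summary table
#'
#' Assembles the per-sample genetic characterisation: mean (SD) observed
#' heterozygosity and unbiased gene diversity over loci, the multi-locus
#' Weir-Cockerham f with its permutation p-value, and mean (SD) allelic
#' richness rarefied to `g` gene copies.
#'
#' @param geno a [genotype_matrix()].
#' @param g gene copies for rarefaction; default is twice the smallest
#'   per-locus diploid count across samples (so every locus qualifies).
#' @param n_perm permutations for the f test.
#' @param seed RNG seed.
#' @return data.frame, one row per sample.
#' @export
diversity_summary <- function(geno, g = NULL, n_perm = 999, seed = NULL) {
  if (is.null(g)) {
    n_min <- Inf
    for (s in levels(geno$pop)) for (l in seq_len(n_loci(geno))) {
      n_min <- min(n_min, locus_stats(geno, l, pops = s)$n[1])
    }
    g <- 2L * as.integer(n_min)
  }
  rows <- lapply(seq_along(levels(geno$pop)), function(si) {
    s <- levels(geno$pop)[si]
    het <- heterozygosity(geno, s)
    ar <- suppressWarnings(allelic_richness(geno, s, g))
    ft <- fis_test(geno, s, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else child_seed(seed, si))
    data.frame(sample = s, n = max(het$n, na.rm = TRUE),
               Ho_mean = mean(het$Ho, na.rm = TRUE),
               Ho_sd = stats::sd(het$Ho, na.rm = TRUE),
               He_mean = mean(het$He, na.rm = TRUE),
               He_sd = stats::sd(het$He, na.rm = TRUE),
               f = ft$f, f_p = ft$p,
               Ar_g = g,
               Ar_mean = mean(ar$Ar, na.rm = TRUE),
               Ar_sd = stats::sd(ar$Ar, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Linkage-disequilibrium test battery with FDR correction
#'
#' Runs [ld_test()] for every locus pair within every sample and adjusts the
#' battery of raw p-values with [fdr_adjust()].
#'
#' @param geno a [genotype_matrix()].
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @param alpha decision level applied to adjusted p-values.
#' @return data.frame with one row per (sample, locus pair).
#' @export
ld_battery <- function(geno, n_perm = 999, seed = NULL, alpha = 0.05) {
  rows <- list()
  k <- 0L
  for (s in levels(geno$pop)) {
    for (i in seq_len(n_loci(geno) - 1L)) for (j in (i + 1L):n_loci(geno)) {
      k <- k + 1L
      res <- tryCatch(
        ld_test(geno, s, i, j, n_perm = n_perm,
                seed = if (is.null(seed)) NULL else child_seed(seed, k)),
        error = function(e) list(p = NA_real_, testable = FALSE))
      rows[[k]] <- data.frame(sample = s, locus_a = geno$loci[i],
                              locus_b = geno$loci[j], p_raw = res$p,
                              testable = isTRUE(res$testable))
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- out$testable & !is.na(out$p_raw)
  out$p_fdr[ok] <- fdr_adjust(out$p_raw[ok])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}
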
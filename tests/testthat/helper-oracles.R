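## Independent oracles used across the suite. Deliberately written as plain
## scalar loops over the raw genotype calls, so they share no code path with
## the package's vectorised estimators.

## Brute-force transcription of the Weir-Cockerham (1984) multilocus theta.
oracle_wc_theta <- function(geno, samples = NULL) {
  if (is.null(samples)) samples <- levels(geno$pop)
  num <- 0; den <- 0
  for (l in seq_len(n_loci(geno))) {
    a1 <- geno$calls[, l, 1]; a2 <- geno$calls[, l, 2]
    keep <- as.character(geno$pop) %in% samples & !is.na(a1)
    if (!any(keep)) next
    alleles <- sort(unique(c(a1[keep], a2[keep])))
    if (length(alleles) < 2L) next
    pops <- samples[vapply(samples,
                           function(s) any(keep & geno$pop == s), logical(1))]
    r <- length(pops)
    if (r < 2L) next
    n_i <- vapply(pops, function(s) sum(keep & geno$pop == s), numeric(1))
    N <- sum(n_i)
    nbar <- N / r
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    for (u in alleles) {
      p_iu <- numeric(r); h_iu <- numeric(r)
      for (i in seq_len(r)) {
        rows <- which(keep & geno$pop == pops[i])
        p_iu[i] <- (sum(a1[rows] == u) + sum(a2[rows] == u)) / (2 * n_i[i])
        h_iu[i] <- sum(a1[rows] != a2[rows] &
                         (a1[rows] == u | a2[rows] == u)) / n_i[i]
      }
      pbar <- sum(n_i * p_iu) / N
      s2 <- sum(n_i * (p_iu - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_iu) / N
      a_u <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    hbar / 4) / (nbar - 1))
      b_u <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
      c_u <- hbar / 2
      num <- num + a_u
      den <- den + a_u + b_u + c_u
    }
  }
  num / den
}

## Exhaustive rarefaction: mean number of distinct alleles over all C(N, g)
## subsamples of the gene pool described by allele copy counts.
oracle_rarefied_richness <- function(copy_counts, g) {
  genes <- rep(seq_along(copy_counts), copy_counts)
  subsets <- utils::combn(length(genes), g)
  mean(apply(subsets, 2, function(ix) length(unique(genes[ix]))))
}

## Hand transcription of the Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

## Classical ANOVA oracle for the univariate PERMANOVA equivalence.
oracle_anova2 <- function(y, a, b) {
  tab <- stats::anova(stats::lm(y ~ a * b))
  list(F = tab$`F value`[1:3], SS = tab$`Sum Sq`, df = tab$Df)
}

## One-way random-effects components via the closed-form ANOVA table.
oracle_varcomp <- function(y, g) {
  g <- factor(g)
  tab <- stats::anova(stats::lm(y ~ g))
  msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
  ni <- tabulate(g); N <- sum(ni); k <- nlevels(g)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  list(sigma2_B = max(0, (msb - msw) / n0), sigma2_W = msw)
}

## Burrows composite disequilibrium from explicit two-locus genotype counts
## (one allele pair), following the textbook count formula.
oracle_burrows_delta <- function(xa, ya) {
  n <- length(xa)
  s <- sum(xa * ya) / 2
  p <- sum(xa) / (2 * n); q <- sum(ya) / (2 * n)
  (n / (n - 1)) * (s / n - 2 * p * q)
}
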
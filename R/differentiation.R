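## Weir & Cockerham (1984) variance components for one locus.
## Inputs per population i (rows): typed diploids n[i], allele frequencies
## p[i, u], and h[i, u] = observed frequency of heterozygous individuals
## carrying allele u. Returns the per-allele components summed over alleles:
## a (among populations), b (among individuals within populations),
## c (within individuals).
wc_components_locus <- function(n, p, h) {
  keep <- n > 0
  n <- n[keep]; p <- p[keep, , drop = FALSE]; h <- h[keep, , drop = FALSE]
  r <- length(n)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (u in seq_len(ncol(p))) {
    pbar <- sum(n * p[, u]) / (r * nbar)
    s2 <- sum(n * (p[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[, u]) / (r * nbar)
    a_u <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b_u <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_u <- hbar / 2
    a_tot <- a_tot + a_u; b_tot <- b_tot + b_u; c_tot <- c_tot + c_u
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

## Per-locus (a, b, c) for a set of samples; rows of the result are loci.
wc_locus_table <- function(geno, samples) {
  L <- n_loci(geno)
  out <- matrix(NA_real_, L, 3, dimnames = list(geno$loci, c("a", "b", "c")))
  for (l in seq_len(L)) {
    st <- locus_stats(geno, l, pops = samples)
    if (length(st$alleles) < 2L) next  # monomorphic: no information
    n <- st$n
    p <- st$counts / pmax(2 * n, 1L)
    h <- st$het / pmax(n, 1L)
    out[l, ] <- wc_components_locus(n, p, h)
  }
  out
}

#' Weir-Cockerham theta (F_ST)
#'
#' Multi-locus moment estimator of F_ST from the Weir-Cockerham (1984)
#' hierarchical variance components: per locus and allele the among-
#' population (a), among-individual-within-population (b) and within-
#' individual (c) components are computed from locus-specific sample sizes,
#' allele frequencies and heterozygote frequencies; the multi-locus theta is
#' the ratio of sums `sum(a) / sum(a + b + c)` over loci (never an average
#' of per-locus ratios). Per-locus sample sizes count the diploids actually
#' typed at that locus, so missing data are used maximally.
#'
#' @param geno a [genotype_matrix()].
#' @param samples population labels to include (default: all); give two
#'   labels for a pairwise theta.
#' @param include_loci loci to include (names or indices; default all).
#' @return an object of class `fst_result`: list with `theta`, `per_locus`
#'   (a, b, c and per-locus theta), `scope`, `samples`.
#' @export
wc_theta <- function(geno, samples = NULL, include_loci = NULL) {
  if (is.null(samples)) samples <- levels(geno$pop)
  if (length(samples) < 2L) stop("need at least 2 samples for theta")
  sub <- geno
  if (!is.null(include_loci)) sub <- subset_geno(geno, loci = include_loci)
  tab <- wc_locus_table(sub, samples)
  ok <- !is.na(tab[, "a"])
  if (!any(ok)) stop("theta undefined: all loci monomorphic across the samples")
  denom <- sum(tab[ok, ])
  if (denom <= 0) stop("theta undefined: zero total variance")
  theta <- sum(tab[ok, "a"]) / denom
  per_locus <- data.frame(locus = rownames(tab), a = tab[, "a"], b = tab[, "b"],
                          c = tab[, "c"],
                          theta = tab[, "a"] / rowSums(tab),
                          row.names = NULL)
  structure(list(theta = theta, per_locus = per_locus,
                 scope = if (length(samples) == nlevels(geno$pop)) "global" else "pair",
                 samples = samples),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta (%s: %s): %.4f\n", x$scope,
              paste(x$samples, collapse = ", "), x$theta))
  if (!is.null(x$ci95))
    cat(sprintf("95%% CI (bootstrap over %d loci, %d replicates): %.4f-%.4f\n",
                sum(!is.na(x$per_locus$a)), x$n_boot, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Bootstrap confidence interval for theta over loci
#'
#' Percentile 2.5/97.5 bounds of theta recomputed on `n_boot` resamples of
#' loci drawn with replacement. The per-locus variance components are
#' computed once; each bootstrap replicate only re-sums them, so the CI is
#' cheap even for many replicates. With a single informative locus the CI is
#' degenerate `(theta, theta)` and a warning is issued.
#'
#' @param geno a [genotype_matrix()].
#' @param samples population labels (default all).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return an `fst_result` with elements `ci95`, `n_boot` and `boot_thetas`
#'   added.
#' @export
wc_theta_ci <- function(geno, samples = NULL, n_boot = 1000, seed = NULL) {
  res <- wc_theta(geno, samples)
  tab <- as.matrix(res$per_locus[, c("a", "b", "c")])
  ok <- which(!is.na(tab[, "a"]))
  if (length(ok) < 2L) {
    warning("only one informative locus: degenerate CI")
    res$ci95 <- c(res$theta, res$theta)
    res$n_boot <- n_boot
    res$boot_thetas <- rep(res$theta, n_boot)
    return(res)
  }
  boot <- numeric(n_boot)
  with_seed(seed, {
    for (k in seq_len(n_boot)) {
      pick <- sample(ok, length(ok), replace = TRUE)
      boot[k] <- sum(tab[pick, "a"]) / sum(tab[pick, ])
    }
  })
  res$ci95 <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  res$n_boot <- n_boot
  res$boot_thetas <- boot
  res
}

#' Pairwise theta matrix
#'
#' @param geno a [genotype_matrix()].
#' @param n_boot if > 0, also compute bootstrap CIs per pair.
#' @param seed RNG seed.
#' @return data.frame with one row per ordered pair (s1 < s2): `theta` and,
#'   if requested, `ci_lo`, `ci_hi`.
#' @export
pairwise_theta <- function(geno, n_boot = 0, seed = NULL) {
  pops <- levels(geno$pop)
  rows <- list(); k <- 0L
  for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
    k <- k + 1L
    if (n_boot > 0) {
      r <- wc_theta_ci(geno, samples = c(pops[i], pops[j]), n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else child_seed(seed, k))
      rows[[k]] <- data.frame(sample1 = pops[i], sample2 = pops[j],
                              theta = r$theta, ci_lo = r$ci95[1],
                              ci_hi = r$ci95[2])
    } else {
      r <- wc_theta(geno, samples = c(pops[i], pops[j]))
      rows[[k]] <- data.frame(sample1 = pops[i], sample2 = pops[j],
                              theta = r$theta)
    }
  }
  do.call(rbind, rows)
}

#' Permutation test of genotypic differentiation
#'
#' Per-locus G statistic on the genotype x population contingency table,
#' combined over loci by summing G (default) or by Fisher's method on the
#' per-locus permutation p-values; the null distribution permutes
#' individuals (with their full multilocus genotypes) among populations.
#' P-values use the add-one rule.
#'
#' @param geno a [genotype_matrix()].
#' @param samples population labels (default: all; give two for a pairwise
#'   test).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param combine `"sum"` (sum of per-locus G) or `"fisher"`.
#' @return list with `p`, `statistic`, `per_locus_p`, `combine`, `n_perm`.
#' @export
genotypic_diff_test <- function(geno, samples = NULL, n_perm = 999,
                                seed = NULL, combine = c("sum", "fisher")) {
  combine <- match.arg(combine)
  if (is.null(samples)) samples <- levels(geno$pop)
  sub <- subset_geno(geno, pops = samples)
  if (nlevels(sub$pop) < 2L) stop("need at least 2 samples with typed individuals")
  L <- n_loci(sub)
  codes <- lapply(seq_len(L), function(l) geno_codes(sub, l))
  poly <- vapply(codes, function(g) length(unique(stats::na.omit(g))) > 1L,
                 logical(1))
  if (!any(poly)) stop("not testable: no polymorphic locus among the samples")

  g_locus <- function(pop_labels) {
    vapply(which(poly), function(l) {
      keep <- !is.na(codes[[l]])
      tab <- table(factor(codes[[l]][keep]), pop_labels[keep])
      if (ncol(tab) < 2L) return(0) else g_statistic(tab)
    }, numeric(1))
  }

  g_obs <- g_locus(sub$pop)
  g_perm <- matrix(0, n_perm, length(g_obs))
  with_seed(seed, {
    for (k in seq_len(n_perm)) g_perm[k, ] <- g_locus(sample(sub$pop))
  })
  per_locus_p <- vapply(seq_along(g_obs),
                        function(j) perm_pvalue(g_obs[j], g_perm[, j]),
                        numeric(1))
  names(per_locus_p) <- sub$loci[poly]
  if (combine == "sum") {
    stat <- sum(g_obs)
    p <- perm_pvalue(stat, rowSums(g_perm))
  } else {
    ## Fisher's combination of per-locus permutation p-values; the null
    ## distribution of the combined statistic is built from the same
    ## permutation set (each permutation's per-locus p computed against the
    ## full null sample).
    p_of <- function(gv) {
      vapply(seq_along(gv),
             function(j) (1 + sum(g_perm[, j] >= gv[j])) / (1 + n_perm),
             numeric(1))
    }
    stat <- -2 * sum(log(p_of(g_obs)))
    stat_perm <- vapply(seq_len(n_perm),
                        function(k) -2 * sum(log(p_of(g_perm[k, ]))),
                        numeric(1))
    p <- perm_pvalue(stat, stat_perm)
  }
  list(p = p, statistic = stat, per_locus_p = per_locus_p,
       combine = combine, n_perm = n_perm)
}

#' Nei et al. (1983) Da distance matrix between samples
#'
#' `Da = 1 - (1/L) sum_loci sum_alleles sqrt(x_u * y_u)` from per-sample
#' allele frequencies. Loci untyped in either member of a pair are excluded
#' pairwise; a pair sharing no typed locus is an error.
#'
#' @param geno a [genotype_matrix()].
#' @param samples population labels (default all).
#' @return a symmetric matrix of class `dist_da` with zero diagonal.
#' @export
nei_da <- function(geno, samples = NULL) {
  if (is.null(samples)) samples <- levels(geno$pop)
  k <- length(samples)
  L <- n_loci(geno)
  freqs <- lapply(seq_len(L), function(l) locus_freqs(geno, l, pops = samples))
  D <- matrix(0, k, k, dimnames = list(samples, samples))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    shared <- 0L
    acc <- 0
    for (l in seq_len(L)) {
      fr <- freqs[[l]]
      if (fr$n[i] == 0L || fr$n[j] == 0L) next
      shared <- shared + 1L
      acc <- acc + sum(sqrt(fr$freq[i, ] * fr$freq[j, ]))
    }
    if (shared == 0L) stop("no shared typed locus for pair ", samples[i],
                           " / ", samples[j])
    D[i, j] <- D[j, i] <- 1 - acc / shared
  }
  class(D) <- c("dist_da", "matrix")
  D
}

#' Neighbor-joining phenogram from a Da matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) of the among-sample Da
#' distances. Negative branch lengths, which NJ can produce on non-additive
#' data, are by default clamped to zero with the deficit transferred to the
#' adjacent branch so that path lengths are preserved. Node support can be
#' assessed by bootstrap over loci: loci are resampled with replacement, the
#' Da matrix and NJ tree recomputed, and each internal edge of the original
#' tree scored by the number of replicates containing its bipartition.
#'
#' @param geno a [genotype_matrix()] (needed when `n_boot > 0`); may be
#'   `NULL` when `dist` is supplied and no bootstrap is requested.
#' @param dist optional precomputed distance matrix (e.g. from [nei_da()]).
#' @param n_boot bootstrap replicates over loci (0 = none).
#' @param seed RNG seed.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return list with `tree` (an \pkg{ape} `phylo`), `newick` (string) and,
#'   when bootstrapped, `support` (counts out of `n_boot` per internal node).
#' @export
nj_phenogram <- function(geno = NULL, dist = NULL, n_boot = 0, seed = NULL,
                         clamp_negative = TRUE) {
  if (is.null(dist)) {
    if (is.null(geno)) stop("supply `geno` or `dist`")
    dist <- nei_da(geno)
  }
  D <- unclass(dist)
  if (nrow(D) < 3L) stop("need at least 3 taxa for a neighbor-joining tree")
  if (any(!is.finite(D))) stop("distances must be finite")
  tree <- ape::nj(stats::as.dist(D))
  if (clamp_negative) tree <- clamp_nj_branches(tree)
  out <- list(tree = tree, newick = ape::write.tree(tree))
  if (n_boot > 0) {
    if (is.null(geno)) stop("bootstrap over loci needs `geno`")
    L <- n_loci(geno)
    boot_trees <- vector("list", n_boot)
    with_seed(seed, {
      for (k in seq_len(n_boot)) {
        pick <- sample.int(L, L, replace = TRUE)
        sub <- subset_geno(geno, loci = pick)
        boot_trees[[k]] <- ape::nj(stats::as.dist(unclass(nei_da(sub))))
      }
    })
    out$support <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    out$n_boot <- n_boot
  }
  out
}

## Clamp negative NJ branch lengths to zero, transferring the deficit to the
## adjacent branch (the standard correction, preserving tip-to-tip path
## lengths through the affected node where possible).
clamp_nj_branches <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    deficit <- el[e]
    el[e] <- 0
    ## transfer to the branch incident to the child node (if internal) or
    ## to the sibling branch at the parent
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj) == 0L)
      adj <- setdiff(which(tree$edge[, 1] == tree$edge[e, 1]), e)
    if (length(adj) > 0L) el[adj] <- el[adj] + deficit / length(adj)
  }
  tree$edge.length <- el
  tree
}
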
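#' Mean of the k greatest growth distances
#'
#' Aggregates the per-section growth measurements of one colony to its
#' response value: the mean of the `k` greatest distances between the
#' calcein mark and the section periphery (default k = 10).
#'
#' @param distances nonnegative growth distances for one colony.
#' @param k number of largest values to average.
#' @return the mean of the `k` largest values; if fewer than `k` values are
#'   supplied, all are used with a warning.
#' @export
mean_max_growth <- function(distances, k = 10) {
  if (length(distances) == 0L) stop("no distances supplied")
  if (any(distances < 0)) stop("distances must be nonnegative")
  if (length(distances) < k) {
    warning("fewer than ", k, " measurements; using all ", length(distances))
    k <- length(distances)
  }
  mean(sort(distances, decreasing = TRUE)[seq_len(k)])
}

## Group indicator matrix (n x k) for fast sums of squares; permutation
## null distributions are computed as one matrix product across all
## permuted responses at once.
indicator <- function(g) {
  M <- matrix(0, length(g), nlevels(g))
  M[cbind(seq_along(g), as.integer(g))] <- 1
  M
}

## Among-group SS for each column of the response matrix Y (n x P):
## sum_g n_g (mean_g - grand)^2, vectorised over columns.
ss_between_cols <- function(M, ns, Y, grand) {
  means <- crossprod(M, Y) / ns           # k x P
  unname(colSums(ns * sweep(means, 2, grand, "-")^2))
}

## Sums of squares for a one-way layout. y numeric, g factor.
ss_oneway <- function(y, g) {
  M <- indicator(g)
  ns <- colSums(M)
  gm <- mean(y)
  ss_a <- ss_between_cols(M, ns, cbind(y), gm)
  ss_t <- sum((y - gm)^2)
  c(A = ss_a, R = ss_t - ss_a, T = ss_t)
}

#' One-way univariate PERMANOVA on Euclidean distance
#'
#' Partitions the total sum of squared Euclidean distances of a univariate
#' response into an among-group and a residual term; for a univariate
#' Euclidean response the pseudo-F is identical to the classical one-way
#' ANOVA F. The p-value is obtained by permuting the raw observations among
#' groups (add-one rule), so no normality assumption is needed.
#'
#' @param values numeric response (one value per experimental unit).
#' @param group factor of group membership (>= 2 levels, each with >= 2
#'   observations).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return an object of class `permanova_result`.
#' @export
permanova_oneway <- function(values, group, n_perm = 9999, seed = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(tabulate(group) < 2L)) stop("every group needs at least 2 observations")
  n <- length(values)
  ss <- ss_oneway(values, group)
  df_a <- nlevels(group) - 1L
  df_r <- n - nlevels(group)
  ms_a <- ss["A"] / df_a
  ms_r <- ss["R"] / df_r
  degenerate <- ss["T"] < .Machine$double.eps * n
  f_obs <- if (degenerate) 0 else if (ms_r == 0) Inf else ms_a / ms_r

  p <- if (degenerate) 1 else {
    M <- indicator(group); ns <- colSums(M)
    Yp <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) sample(values), numeric(n))
    })
    ssa <- ss_between_cols(M, ns, Yp, rep(mean(values), n_perm))
    ssr <- pmax(ss["T"] - ssa, 0)
    f_perm <- ifelse(ssr == 0, Inf, (ssa / df_a) / (ssr / df_r))
    perm_pvalue(f_obs, f_perm)
  }
  tab <- data.frame(
    term = c("group", "residual", "total"),
    df = c(df_a, df_r, n - 1L),
    SS = unname(c(ss["A"], ss["R"], ss["T"])),
    MS = c(ms_a, ms_r, NA),
    pseudo_F = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 design = "one-way", degenerate = degenerate),
            class = "permanova_result")
}

## Sums of squares for a balanced two-way crossed layout with interaction.
ss_twoway <- function(y, a, b, cell) {
  gm <- mean(y)
  Ma <- indicator(a); Mb <- indicator(b); Mc <- indicator(cell)
  ss_a <- ss_between_cols(Ma, colSums(Ma), cbind(y), gm)
  ss_b <- ss_between_cols(Mb, colSums(Mb), cbind(y), gm)
  ss_cells <- ss_between_cols(Mc, colSums(Mc), cbind(y), gm)
  ss_t <- sum((y - gm)^2)
  c(A = ss_a, B = ss_b, AB = ss_cells - ss_a - ss_b, R = ss_t - ss_cells,
    T = ss_t)
}

#' Two-factorial univariate PERMANOVA on Euclidean distance
#'
#' Fully crossed two-fixed-factor design with interaction, analysed on the
#' squared Euclidean distances of a univariate response; on a balanced
#' design the pseudo-F of every term equals the classical two-way ANOVA F.
#' Main-effect p-values permute the raw observations; the interaction
#' p-value permutes the residuals of the reduced additive model (the fitted
#' additive values are kept fixed and the residuals shuffled before the
#' interaction F is recomputed). Unbalanced designs are refused: with
#' unequal cell counts the sums of squares of crossed factors are no longer
#' order-invariant, and the experimental designs this analysis is meant for
#' are balanced by construction.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed fixed factors (e.g. origin depth and
#'   treatment depth), each with >= 2 levels and >= 2 replicates per cell.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @param labels term labels for the output table.
#' @return an object of class `permanova_result`.
#' @export
permanova_twoway <- function(values, factor_a, factor_b, n_perm = 9999,
                             seed = NULL,
                             labels = c("origin", "depth", "origin x depth")) {
  a <- droplevels(factor(factor_a)); b <- droplevels(factor(factor_b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) stop("both factors need >= 2 levels")
  cell <- interaction(a, b, drop = FALSE)
  ncell <- table(cell)
  if (any(ncell == 0L))
    stop("unbalanced design: empty cell ", names(ncell)[which(ncell == 0L)[1]])
  if (length(unique(ncell)) != 1L)
    stop("unbalanced design: unequal cell sizes (",
         paste(ncell, collapse = ", "), "); this analysis requires balance")
  if (any(ncell < 2L)) stop("every cell needs at least 2 replicates")

  n <- length(values)
  ss <- ss_twoway(values, a, b, cell)
  df <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
          AB = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  df_r <- n - nlevels(a) * nlevels(b)
  ms <- ss[c("A", "B", "AB")] / df
  ms_r <- ss["R"] / df_r
  degenerate <- ss["T"] < .Machine$double.eps * n
  f_obs <- if (degenerate) c(A = 0, B = 0, AB = 0)
           else if (ms_r == 0) rep(Inf, 3) else ms / ms_r
  names(f_obs) <- c("A", "B", "AB")

  if (degenerate) {
    p <- c(A = 1, B = 1, AB = 1)
  } else {
    Ma <- indicator(a); na_ <- colSums(Ma)
    Mb <- indicator(b); nb_ <- colSums(Mb)
    Mc <- indicator(cell); nc_ <- colSums(Mc)
    gm <- mean(values)
    ## reduced (additive) model fit for the interaction permutation
    ma <- tapply(values, a, mean); mb <- tapply(values, b, mean)
    fit_add <- as.vector(ma[a] + mb[b] - gm)
    res_add <- values - fit_add
    perms <- with_seed(seed, {
      list(raw = vapply(seq_len(n_perm), function(k) sample(values), numeric(n)),
           res = vapply(seq_len(n_perm), function(k) sample(res_add), numeric(n)))
    })
    ## main effects: permute raw observations (total SS invariant)
    ssa <- ss_between_cols(Ma, na_, perms$raw, rep(gm, n_perm))
    ssb <- ss_between_cols(Mb, nb_, perms$raw, rep(gm, n_perm))
    ssc <- ss_between_cols(Mc, nc_, perms$raw, rep(gm, n_perm))
    ssr <- pmax(ss["T"] - ssc, 0)
    msr <- ssr / df_r
    fA <- ifelse(msr == 0, Inf, (ssa / df["A"]) / msr)
    fB <- ifelse(msr == 0, Inf, (ssb / df["B"]) / msr)
    ## interaction: reduced-model fit plus permuted residuals
    Yi <- fit_add + perms$res
    gmi <- colMeans(Yi)
    ssa_i <- ss_between_cols(Ma, na_, Yi, gmi)
    ssb_i <- ss_between_cols(Mb, nb_, Yi, gmi)
    ssc_i <- ss_between_cols(Mc, nc_, Yi, gmi)
    sst_i <- colSums(sweep(Yi, 2, gmi, "-")^2)
    ssab_i <- ssc_i - ssa_i - ssb_i
    ssr_i <- pmax(sst_i - ssc_i, 0)
    msr_i <- ssr_i / df_r
    fAB <- ifelse(msr_i == 0, Inf, (ssab_i / df["AB"]) / msr_i)
    p <- c(A = perm_pvalue(f_obs["A"], fA),
           B = perm_pvalue(f_obs["B"], fB),
           AB = perm_pvalue(f_obs["AB"], fAB))
  }

  tab <- data.frame(
    term = c(labels, "residual", "total"),
    df = c(unname(df), df_r, n - 1L),
    SS = unname(c(ss["A"], ss["B"], ss["AB"], ss["R"], ss["T"])),
    MS = c(unname(ms), unname(ms_r), NA),
    pseudo_F = c(unname(f_obs), NA, NA),
    p = c(unname(p), NA, NA))
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 design = "two-way", degenerate = degenerate),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Permutational univariate ANOVA (Euclidean distance), ",
      x$design, " design, ", x$n_perm, " permutations\n", sep = "")
  tab <- x$table
  tab$SS <- signif(tab$SS, 4); tab$MS <- signif(tab$MS, 4)
  tab$pseudo_F <- signif(tab$pseudo_F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the transplant-experiment PERMANOVA from a phenotype table
#'
#' Convenience wrapper: extracts one trait from a [phenotype_table()] and
#' dispatches to the one-way (factor = origin depth) or two-way (origin x
#' treatment depth) analysis.
#'
#' @param pheno a `phenotype_table`.
#' @param design `"two-way"` or `"one-way"`.
#' @param trait trait name to analyse.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return a `permanova_result`.
#' @export
permanova_pheno <- function(pheno, design = c("two-way", "one-way"),
                            trait = NULL, n_perm = 9999, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(trait)) pheno <- pheno[pheno$trait == trait, , drop = FALSE]
  if ("time" %in% names(pheno) && length(unique(pheno$time)) > 1L) {
    last <- max(pheno$time)  # analyse the final level of a time series
    pheno <- pheno[pheno$time == last, , drop = FALSE]
  }
  if (nrow(pheno) == 0L) stop("no records to analyse")
  if (design == "two-way")
    permanova_twoway(pheno$value, pheno$origin_depth, pheno$treatment_depth,
                     n_perm = n_perm, seed = seed)
  else
    permanova_oneway(pheno$value, pheno$origin_depth, n_perm = n_perm,
                     seed = seed)
}

#' Survival and never-necrosed percentages from a necrosis time series
#'
#' A colony survives when its final necrosis record is below 100%; it counts
#' as never-necrosed when all its records are 0.
#'
#' @param pheno a `phenotype_table` of `necrosis_pct` records with a `time`
#'   column (one trajectory per colony).
#' @return data.frame per sample: `n`, `survival_pct`, `never_necrosed_pct`.
#' @export
survival_summary <- function(pheno) {
  pheno <- pheno[pheno$trait == "necrosis_pct", , drop = FALSE]
  if (nrow(pheno) == 0L) stop("no necrosis records")
  if (!"time" %in% names(pheno)) pheno$time <- 0
  rows <- lapply(split(pheno, pheno$sample), function(d) {
    per_col <- split(d, d$individual)
    per_col <- per_col[vapply(per_col, nrow, integer(1)) > 0L]
    if (length(per_col) == 0L) stop("empty sample in survival summary")
    final <- vapply(per_col, function(x) x$value[which.max(x$time)], numeric(1))
    never <- vapply(per_col, function(x) all(x$value == 0), logical(1))
    data.frame(sample = d$sample[1], n = length(per_col),
               survival_pct = 100 * mean(final < 100),
               never_necrosed_pct = 100 * mean(never))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
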
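#' One-way variance components of a trait grouped by sample
#'
#' Method-of-moments (ANOVA) estimates: the within-sample component is the
#' within-group mean square; the among-sample component is
#' `max(0, (MS_between - MS_within) / n0)` with
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)` the standard coefficient for
#' (possibly) unbalanced one-way designs. Negative moment estimates are
#' truncated at zero so that P_ST stays in \[0, 1\].
#'
#' @param values numeric trait values.
#' @param group sample labels (>= 2 samples, each with >= 2 observations).
#' @return list with `sigma2_B`, `sigma2_W`, `ms_between`, `ms_within`,
#'   `n0`, `k`, `N`.
#' @export
variance_components <- function(values, group) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 samples")
  ni <- tabulate(group)
  if (any(ni < 2L)) stop("every sample needs at least 2 observations")
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  sigma2_B <- max(0, (msb - msw) / n0)
  list(sigma2_B = sigma2_B, sigma2_W = msw, ms_between = msb,
       ms_within = msw, n0 = n0, k = k, N = N)
}

#' The P_ST curve over c/h2
#'
#' `P_ST(r) = r * sigma2_B / (r * sigma2_B + 2 * sigma2_W)` with
#' `r = c/h2`: `c` is the assumed additive-genetic proportion of the
#' among-population phenotypic variance and `h2` the within-population
#' narrow-sense heritability. At the null assumption `r = 1`, P_ST is the
#' usual phenotypic analogue of Q_ST; the conservative sensitivity range is
#' `0 < r <= 1`.
#'
#' @param sigma2_B,sigma2_W nonnegative variance components (not both 0).
#' @param r_grid values of c/h2 in (0, 1].
#' @return numeric vector `pst(r)` along `r_grid`.
#' @export
pst_curve <- function(sigma2_B, sigma2_W, r_grid) {
  if (sigma2_B < 0 || sigma2_W < 0) stop("variance components must be >= 0")
  if (sigma2_B == 0 && sigma2_W == 0)
    stop("P_ST undefined: both variance components are zero")
  if (any(r_grid <= 0)) stop("r values must be positive")
  r_grid * sigma2_B / (r_grid * sigma2_B + 2 * sigma2_W)
}

#' Default log-spaced c/h2 grid
#'
#' 200 points log-spaced on (0.001, 1], always containing r = 1.
#' @param n number of grid points.
#' @param lo smallest r.
#' @return numeric vector.
#' @export
default_r_grid <- function(n = 200, lo = 0.001) {
  exp(seq(log(lo), log(1), length.out = n))
}

#' P_ST point estimate, curve and bootstrap confidence band
#'
#' Estimates the variance components of a trait grouped by sample, the
#' P_ST(r) curve on a c/h2 grid, and percentile 95% confidence bands by
#' bootstrap: each replicate resamples individuals with replacement within
#' each sample (sample sizes preserved), recomputes the components and the
#' whole curve. A replicate whose within-sample variance vanishes in every
#' sample is degenerate (P_ST = 1 for all r); such replicates are counted
#' and flagged when they exceed 1% of the draws.
#'
#' @param values numeric trait values.
#' @param group sample labels.
#' @param r_grid c/h2 grid (default [default_r_grid()]).
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed RNG seed.
#' @return an object of class `pst_result`: list with `sigma2_B`,
#'   `sigma2_W`, `r_grid`, `pst`, `boot_draws` (replicate x r matrix),
#'   `ci_lo`, `ci_hi`, `n_boot`, `seed`, `n_degenerate`,
#'   `degenerate_flag`.
#' @export
pst_bootstrap <- function(values, group, r_grid = default_r_grid(),
                          n_boot = 1000, seed = NULL) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  group <- droplevels(factor(group))
  vc <- variance_components(values, group)
  pst_hat <- pst_curve(vc$sigma2_B, vc$sigma2_W, r_grid)

  idx_by_group <- split(seq_along(values), group)
  boot <- matrix(NA_real_, n_boot, length(r_grid))
  n_degenerate <- 0L
  with_seed(seed, {
    for (kk in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_group,
                            function(ix) ix[sample.int(length(ix),
                                                       length(ix),
                                                       replace = TRUE)]),
                     use.names = FALSE)
      vb <- variance_components(values[take], group[take])
      if (vb$sigma2_W == 0) {
        n_degenerate <- n_degenerate + 1L
        boot[kk, ] <- if (vb$sigma2_B > 0) 1 else 0
      } else {
        boot[kk, ] <- pst_curve(vb$sigma2_B, vb$sigma2_W, r_grid)
      }
    }
  })
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(sigma2_B = vc$sigma2_B, sigma2_W = vc$sigma2_W,
                 r_grid = r_grid, pst = pst_hat, boot_draws = boot,
                 ci_lo = ci[1, ], ci_hi = ci[2, ], n_boot = n_boot,
                 seed = seed, n_degenerate = n_degenerate,
                 degenerate_flag = n_degenerate > 0.01 * n_boot),
            class = "pst_result")
}

#' @export
print.pst_result <- function(x, ...) {
  i1 <- which.min(abs(x$r_grid - 1))
  cat(sprintf("P_ST at c/h2 = 1: %.3f (95%% CI %.3f-%.3f), %d bootstraps\n",
              x$pst[i1], x$ci_lo[i1], x$ci_hi[i1], x$n_boot))
  cat(sprintf("variance components: sigma2_B = %.4g, sigma2_W = %.4g\n",
              x$sigma2_B, x$sigma2_W))
  if (x$degenerate_flag)
    cat("warning: >1% of bootstrap replicates had zero within-sample variance\n")
  invisible(x)
}

#' Compare P_ST with F_ST references and locate (c/h2)_crit
#'
#' For each neutral-differentiation reference (e.g. the upper bound of the
#' bootstrap 95% CI of theta, or an external allozyme F_ST), decides whether
#' P_ST is significantly higher at the null assumption c/h2 = 1 (the lower
#' 95% percentile bound of P_ST(1) exceeds the reference), and computes
#' `(c/h2)_crit`: the smallest r at which the lower bound of P_ST(r)
#' exceeds the reference, linearly interpolated between the bracketing grid
#' points. Following the published guideline, a comparison is flagged
#' robust when crit_r < 0.2.
#'
#' @param pst a `pst_result` whose grid contains r = 1.
#' @param fst_refs named numeric vector of reference values, e.g.
#'   `c(theta_upper_CI = 0.13, F_STall = 0.1)`.
#' @return an object of class `pst_fst_comparison`: data.frame with one row
#'   per reference (`ref`, `value`, `significant_at_null`, `crit_r`,
#'   `robust`), where `crit_r` is `NA` when no r <= 1 reaches significance
#'   ("none <= 1").
#' @export
pst_fst_compare <- function(pst, fst_refs) {
  if (length(fst_refs) == 0L) stop("empty fst_refs")
  if (is.null(names(fst_refs)) || any(!nzchar(names(fst_refs))))
    names(fst_refs) <- paste0("ref", seq_along(fst_refs))
  i1 <- which.min(abs(pst$r_grid - 1))
  if (abs(pst$r_grid[i1] - 1) > 1e-8) stop("r grid must contain r = 1")
  lo <- pst$ci_lo
  rows <- lapply(seq_along(fst_refs), function(j) {
    ref <- fst_refs[j]
    sig <- lo[i1] > ref
    above <- which(lo > ref)
    if (length(above) == 0L) {
      crit <- NA_real_
    } else {
      jx <- min(above)
      if (jx == 1L) {
        crit <- pst$r_grid[1]
      } else {
        r0 <- pst$r_grid[jx - 1L]; r1 <- pst$r_grid[jx]
        l0 <- lo[jx - 1L]; l1 <- lo[jx]
        crit <- if (l1 > l0) r0 + (ref - l0) * (r1 - r0) / (l1 - l0) else r1
      }
    }
    data.frame(ref = names(fst_refs)[j], value = unname(ref),
               significant_at_null = sig, crit_r = crit,
               robust = !is.na(crit) && crit < 0.2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pst_fst_comparison", "data.frame")
  out
}
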
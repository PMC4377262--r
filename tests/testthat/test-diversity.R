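test_that("Ho and He match direct substitution on toy samples", {
  ## all homozygous for one allele -> Ho = He = 0
  g <- geno_from_loci(cbind(c(1, 1, 1), c(1, 1, 1)))
  h <- heterozygosity(g, "s1")
  expect_equal(h$Ho, 0)
  expect_equal(h$He, 0)
  ## two individuals both 1/2 -> Ho = 1, He = (4/3)(1 - 0.5)
  g2 <- geno_from_loci(cbind(c(1, 1), c(2, 2)))
  h2 <- heterozygosity(g2, "s1")
  expect_equal(h2$Ho, 1)
  expect_equal(h2$He, 4 / 3 * 0.5, tolerance = 1e-12)
})

test_that("Ho/He match a per-genotype tally oracle on a random sample", {
  g <- random_geno(n_pops = 1, n_per_pop = 50, n_loci = 4, n_alleles = 6,
                   miss_rate = 0.08, seed = 11)
  h <- heterozygosity(g, "p1")
  for (l in 1:4) {
    a1 <- g$calls[, l, 1]; a2 <- g$calls[, l, 2]
    keep <- !is.na(a1)
    n <- sum(keep)
    ho <- sum(a1[keep] != a2[keep]) / n
    freqs <- table(c(a1[keep], a2[keep])) / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
    expect_equal(h$Ho[l], ho, tolerance = 1e-12)
    expect_equal(h$He[l], he, tolerance = 1e-12)
    expect_equal(h$n[l], n)
  }
})

test_that("unbiased He is at least the plug-in gene diversity", {
  for (seed in 1:5) {
    g <- random_geno(n_pops = 1, n_per_pop = 20, n_loci = 3, n_alleles = 5,
                     miss_rate = 0.1, seed = seed)
    h <- heterozygosity(g, "p1")
    for (l in 1:3) {
      a1 <- g$calls[, l, 1]; a2 <- g$calls[, l, 2]
      keep <- !is.na(a1)
      freqs <- table(c(a1[keep], a2[keep])) / (2 * sum(keep))
      expect_gte(h$He[l] + 1e-12, 1 - sum(freqs^2))
    }
  }
})

test_that("f is -1 for a perfectly heterozygous biallelic sample", {
  g <- geno_from_loci(cbind(rep(1, 10), rep(2, 10)))
  res <- fis_test(g, "s1", n_perm = 99, seed = 1)
  expect_equal(res$f, -1, tolerance = 1e-12)
})

test_that("f is undefined when all loci are monomorphic", {
  g <- geno_from_loci(cbind(rep(3, 6), rep(3, 6)))
  expect_error(fis_test(g, "s1", n_perm = 9), "monomorphic")
})

test_that("the f permutation test holds its size under Hardy-Weinberg", {
  n_sim <- 400
  set.seed(202)
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    calls <- array(NA_integer_, dim = c(50, 3, 2))
    for (l in 1:3) {
      p <- rdirich_probs(4)
      calls[, l, 1] <- sample.int(4, 50, TRUE, prob = p)
      calls[, l, 2] <- sample.int(4, 50, TRUE, prob = p)
    }
    g <- genotype_matrix(calls, pop = rep("s1", 50))
    rej[s] <- fis_test(g, "s1", n_perm = 199, seed = s)$p <= 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("f recovers a known inbreeding coefficient", {
  set.seed(77)
  fhat <- replicate(200, {
    calls <- array(NA_integer_, dim = c(50, 7, 2))
    for (l in 1:7) {
      p <- rdirich_probs(6)
      a1 <- sample.int(6, 50, TRUE, prob = p)
      a2 <- sample.int(6, 50, TRUE, prob = p)
      auto <- runif(50) < 0.15
      a2[auto] <- a1[auto]
      calls[, l, 1] <- a1; calls[, l, 2] <- a2
    }
    g <- genotype_matrix(calls, pop = rep("s1", 50))
    comp <- margadapt:::fis_components(g, "s1")
    ok <- !is.na(comp$b)
    sum(comp$b[ok]) / sum(comp$b[ok] + comp$c[ok])
  })
  expect_lt(abs(mean(fhat) - 0.15), 0.04)
})

test_that("rarefied allelic richness has its exact identities", {
  ## one locus with copy counts 6/3/1 in 5 diploids (N = 10)
  g <- geno_from_loci(cbind(c(1, 1, 1, 2, 3), c(1, 1, 1, 2, 2)))
  ar_full <- allelic_richness(g, "s1", g = 10)
  expect_equal(ar_full$Ar, 3)                  # g = N: observed count
  ar1 <- allelic_richness(g, "s1", g = 1)
  expect_equal(ar1$Ar, 1, tolerance = 1e-12)   # g = 1: one allele
})

test_that("rarefied richness matches exhaustive subsample enumeration", {
  g <- geno_from_loci(cbind(c(1, 1, 1, 2, 3), c(1, 1, 1, 2, 2)))
  for (gg in c(2, 4, 7)) {
    expect_equal(allelic_richness(g, "s1", g = gg)$Ar,
                 oracle_rarefied_richness(c(6, 3, 1), gg),
                 tolerance = 1e-9)
  }
})

test_that("rarefied richness is nondecreasing in g and label-invariant", {
  g <- random_geno(n_pops = 1, n_per_pop = 12, n_loci = 2, n_alleles = 5,
                   miss_rate = 0, seed = 4)
  ar <- vapply(1:24, function(gg) allelic_richness(g, "p1", gg)$Ar[1],
               numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  ## relabel alleles
  g2 <- g
  g2$calls[] <- 11L - g2$calls
  expect_equal(allelic_richness(g2, "p1", 10)$Ar,
               allelic_richness(g, "p1", 10)$Ar, tolerance = 1e-12)
})

test_that("the LD permutation test detects a duplicated locus", {
  set.seed(9)
  a <- cbind(sample.int(3, 40, TRUE), sample.int(3, 40, TRUE))
  g <- geno_from_loci(a, a)
  res <- ld_test(g, "s1", 1, 2, n_perm = 999, seed = 3)
  expect_lte(res$p, 0.001)
})

test_that("the LD permutation p agrees with exhaustive enumeration on tiny n", {
  ## 6 individuals, biallelic loci; enumerate all 6! shuffles of locus B
  set.seed(15)
  a <- cbind(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2))
  b <- cbind(c(1, 1, 2, 1, 2, 2), c(1, 2, 2, 2, 2, 1))
  g <- geno_from_loci(a, b)
  ga <- factor(apply(a, 1, function(x) paste(sort(x), collapse = "/")))
  gb <- factor(apply(b, 1, function(x) paste(sort(x), collapse = "/")))
  g_obs <- margadapt:::g_statistic(table(ga, gb))
  perms <- permutations6()
  g_null <- apply(perms, 1, function(ix) margadapt:::g_statistic(table(ga, gb[ix])))
  p_exact <- mean(g_null >= g_obs - 1e-12)
  res <- ld_test(g, "s1", 1, 2, n_perm = 1999, seed = 8)
  expect_lt(abs(res$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1e-3)
})

test_that("the LD test holds its size for independent loci", {
  n_sim <- 600
  set.seed(404)
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    a <- cbind(sample.int(2, 40, TRUE), sample.int(2, 40, TRUE))
    b <- cbind(sample.int(2, 40, TRUE), sample.int(2, 40, TRUE))
    g <- geno_from_loci(a, b)
    p <- tryCatch(ld_test(g, "s1", 1, 2, n_perm = 99, seed = s)$p,
                  error = function(e) NA_real_)
    rej[s] <- !is.na(p) && p <= 0.05
  }
  expect_gte(mean(rej, na.rm = TRUE), 0.03)
  expect_lte(mean(rej, na.rm = TRUE), 0.07)
})

test_that("insufficient joint calls yield a not-testable flag", {
  a <- cbind(c(1, 2, NA, NA, NA, NA), c(2, 2, NA, NA, NA, NA))
  b <- cbind(c(1, 1, 1, 2, 1, 2), c(2, 1, 2, 2, 1, 2))
  a[is.na(a)] <- NA_integer_
  g <- geno_from_loci(a, b)
  res <- ld_test(g, "s1", 1, 2, n_perm = 99, seed = 1)
  expect_false(res$testable)
  expect_true(is.na(res$p))
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(31)
  p <- runif(25)^2
  expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the diversity summary mirrors the per-locus statistics", {
  g <- random_geno(n_pops = 2, n_per_pop = 20, n_loci = 3, n_alleles = 6,
                   miss_rate = 0.05, seed = 21)
  ds <- diversity_summary(g, g = 20, n_perm = 99, seed = 5)
  expect_equal(nrow(ds), 2L)
  h <- heterozygosity(g, "p1")
  expect_equal(ds$Ho_mean[1], mean(h$Ho, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(ds$He_mean[1], mean(h$He, na.rm = TRUE), tolerance = 1e-12)
  expect_true(all(ds$Ho_mean >= 0 & ds$Ho_mean <= 1))
  expect_true(all(ds$He_mean >= 0 & ds$He_mean <= 1))
})
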
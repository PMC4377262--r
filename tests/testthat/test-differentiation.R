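test_that("theta is 1 when samples are fixed for different alleles", {
  g <- geno_from_loci(cbind(rep(1:2, each = 8), rep(1:2, each = 8)),
                      cbind(rep(3:4, each = 8), rep(3:4, each = 8)),
                      pop = rep(c("a", "b"), each = 8))
  expect_equal(wc_theta(g)$theta, 1, tolerance = 1e-12)
})

test_that("theta is small (and not positive) for identical samples", {
  set.seed(42)
  half <- cbind(sample.int(4, 20, TRUE), sample.int(4, 20, TRUE))
  g <- geno_from_loci(rbind(half, half), pop = rep(c("a", "b"), each = 20))
  th <- wc_theta(g)$theta
  expect_lte(th, 0)
  expect_lt(abs(th), 0.05)
})

test_that("theta matches the brute-force component transcription", {
  ## fixed 2-population x 2-locus toy table with unequal n (4 and 5)
  la <- rbind(cbind(c(1, 1, 2, 3), c(1, 2, 2, 3)),
              cbind(c(1, 2, 2, 2, 3), c(2, 2, 3, 3, 3)))
  lb <- rbind(cbind(c(5, 5, 6, 6), c(5, 6, 6, 6)),
              cbind(c(5, 5, 5, 6, 5), c(5, 5, 6, 6, 5)))
  g <- geno_from_loci(la, lb, pop = rep(c("a", "b"), c(4, 5)))
  expect_equal(wc_theta(g)$theta, oracle_wc_theta(g), tolerance = 1e-10)
})

test_that("theta is invariant to allele relabeling, locus order and pair order", {
  g <- random_geno(n_pops = 3, n_per_pop = 12, n_loci = 3, n_alleles = 4,
                   miss_rate = 0.1, seed = 3)
  th <- wc_theta(g)$theta
  relab <- g; relab$calls[] <- 9L - relab$calls
  expect_equal(wc_theta(relab)$theta, th, tolerance = 1e-12)
  reord <- subset_geno(g, loci = c(3, 1, 2))
  expect_equal(wc_theta(reord)$theta, th, tolerance = 1e-12)
  expect_equal(wc_theta(g, samples = c("p1", "p2"))$theta,
               wc_theta(g, samples = c("p2", "p1"))$theta, tolerance = 1e-12)
})

test_that("monomorphic data yield an undefined-theta error", {
  g <- geno_from_loci(cbind(rep(1, 8), rep(1, 8)),
                      pop = rep(c("a", "b"), each = 4))
  expect_error(wc_theta(g), "monomorphic")
})

test_that("the bootstrap CI over loci behaves at its edge cases", {
  ## identical allele tables at every locus -> zero-width CI
  locus <- cbind(rep(c(1, 1, 2, 2), 2), rep(c(1, 2, 1, 2), 2))
  g <- geno_from_loci(locus, locus, locus, pop = rep(c("a", "b"), each = 4))
  res <- wc_theta_ci(g, n_boot = 200, seed = 1)
  expect_equal(res$ci95[1], res$ci95[2], tolerance = 1e-12)
  ## a single informative locus -> degenerate CI with warning
  g1 <- geno_from_loci(locus, pop = rep(c("a", "b"), each = 4))
  expect_warning(res1 <- wc_theta_ci(g1, n_boot = 50, seed = 1), "degenerate")
  expect_equal(res1$ci95, c(res1$theta, res1$theta))
  ## fixed seed reproduces the CI bit for bit
  g2 <- random_geno(n_pops = 2, n_per_pop = 15, n_loci = 5, n_alleles = 5,
                    miss_rate = 0.05, seed = 7)
  a <- wc_theta_ci(g2, n_boot = 300, seed = 11)
  b <- wc_theta_ci(g2, n_boot = 300, seed = 11)
  expect_identical(a$ci95, b$ci95)
  expect_identical(a$boot_thetas, b$boot_thetas)
})

test_that("genotypic differentiation is maximal for fixed differences", {
  g <- geno_from_loci(cbind(rep(1:2, each = 20), rep(1:2, each = 20)),
                      pop = rep(c("a", "b"), each = 20))
  res <- genotypic_diff_test(g, n_perm = 199, seed = 2)
  expect_equal(res$p, 1 / 200)
})

test_that("genotypic differentiation p agrees with exhaustive label enumeration", {
  ## 6 individuals split 3/3; enumerate all 720 label orders
  a <- cbind(c(1, 1, 2, 2, 2, 1), c(1, 2, 2, 2, 1, 1))
  g <- geno_from_loci(a, pop = rep(c("x", "y"), each = 3))
  codes <- factor(apply(a, 1, function(z) paste(sort(z), collapse = "/")))
  labels <- rep(c("x", "y"), each = 3)
  g_obs <- margadapt:::g_statistic(table(codes, labels))
  perms <- permutations6()
  g_null <- apply(perms, 1, function(ix)
    margadapt:::g_statistic(table(codes, labels[ix])))
  p_exact <- mean(g_null >= g_obs - 1e-12)
  res <- genotypic_diff_test(g, n_perm = 1999, seed = 5)
  expect_lt(abs(res$p - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1e-3)
})

test_that("the genotypic test holds its size on a split panmictic sample", {
  n_sim <- 400
  set.seed(88)
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    pool <- cbind(sample.int(3, 40, TRUE), sample.int(3, 40, TRUE))
    g <- geno_from_loci(pool, pop = rep(c("a", "b"), each = 20))
    p <- tryCatch(genotypic_diff_test(g, n_perm = 99, seed = s)$p,
                  error = function(e) NA_real_)
    rej[s] <- !is.na(p) && p <= 0.05
  }
  expect_gte(mean(rej, na.rm = TRUE), 0.03)
  expect_lte(mean(rej, na.rm = TRUE), 0.07)
})

test_that("Nei Da has its exact endpoints and closed-form values", {
  ## identical frequency vectors -> 0
  locus <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  g <- geno_from_loci(rbind(locus, locus), pop = rep(c("a", "b"), each = 4))
  expect_equal(unclass(nei_da(g))["a", "b"], 0, tolerance = 1e-12)
  ## disjoint allele sets -> 1
  gd <- geno_from_loci(cbind(c(1, 1, 3, 3), c(1, 1, 3, 3)),
                       pop = rep(c("a", "b"), each = 2))
  expect_equal(unclass(nei_da(gd))["a", "b"], 1, tolerance = 1e-12)
  ## (0.5, 0.5) vs (1, 0) -> 1 - sqrt(0.5)
  gm <- geno_from_loci(cbind(c(1, 2, 1, 1), c(2, 1, 1, 1)),
                       pop = rep(c("a", "b"), each = 2))
  expect_equal(unclass(nei_da(gm))["a", "b"], 1 - sqrt(0.5), tolerance = 1e-12)
  ## symmetry and zero diagonal on random data
  g3 <- random_geno(n_pops = 3, n_per_pop = 10, n_loci = 3, n_alleles = 4,
                    miss_rate = 0.1, seed = 9)
  D <- unclass(nei_da(g3))
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), rownames(D)))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  ## tree: ((A:1,B:2):1.5,(C:3,D:4)); pairwise path lengths are additive
  tr_true <- ape::read.tree(text = "((A:1,B:2):0.75,(C:3,D:4):0.75);")
  D <- cophenetic(tr_true)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  res <- nj_phenogram(dist = D)
  expect_true(ape::is.monophyletic(res$tree, c("A", "B")) ||
                ape::is.monophyletic(res$tree, c("C", "D")))
  expect_equal(sort(cophenetic(res$tree)[c("A","B","C","D"), c("A","B","C","D")]),
               sort(D), tolerance = 1e-10)
})

test_that("three equidistant taxa give a star with branches d/2", {
  D <- matrix(0.4, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(D) <- 0
  res <- nj_phenogram(dist = D)
  expect_equal(sort(res$tree$edge.length), rep(0.2, 3), tolerance = 1e-12)
})

test_that("the NJ topology is invariant to taxon order", {
  g <- random_geno(n_pops = 4, n_per_pop = 12, n_loci = 4, n_alleles = 5,
                   miss_rate = 0.05, seed = 13)
  D <- unclass(nei_da(g))
  t1 <- nj_phenogram(dist = D)$tree
  perm <- c(3, 1, 4, 2)
  t2 <- nj_phenogram(dist = D[perm, perm])$tree
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("negative NJ branches are clamped without changing path lengths much", {
  ## non-additive distances force a negative branch in raw NJ
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 1,
                9, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 0.3; D["b", "a"] <- 0.3  # break additivity hard
  res <- nj_phenogram(dist = D)
  expect_true(all(res$tree$edge.length >= 0))
  raw <- ape::nj(as.dist(D))
  expect_equal(sum(res$tree$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap over loci gives full support for a clean split", {
  set.seed(50)
  mk <- function(allele) cbind(rep(allele, 24), rep(allele, 24))
  ## pops 1,2 fixed for allele sets {1},{1} vs pops 3,4 for {2},{2} at 4 loci,
  ## plus within-group noise loci
  calls <- array(NA_integer_, dim = c(24, 5, 2))
  popv <- rep(c("a", "b", "c", "d"), each = 6)
  for (l in 1:4) {
    base <- ifelse(popv %in% c("a", "b"), 1L, 2L)
    calls[, l, 1] <- base; calls[, l, 2] <- base
  }
  calls[, 5, 1] <- sample.int(4, 24, TRUE)
  calls[, 5, 2] <- sample.int(4, 24, TRUE)
  g <- genotype_matrix(calls, pop = popv)
  res <- nj_phenogram(g, n_boot = 100, seed = 4)
  expect_gte(max(res$support, na.rm = TRUE), 95)
})
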
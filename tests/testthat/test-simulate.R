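test_that("all generators are reproducible from (config, seed)", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_genotypes(cfg)$calls, simulate_genotypes(cfg)$calls)
  expect_identical(simulate_wf_cohort(cfg)$calls, simulate_wf_cohort(cfg)$calls)
  expect_identical(simulate_rte_phenotypes(cfg)$value,
                   simulate_rte_phenotypes(cfg)$value)
  expect_identical(simulate_cge_necrosis(cfg)$value,
                   simulate_cge_necrosis(cfg)$value)
})

test_that("config validation catches impossible parameters", {
  expect_error(sim_config(target_fst = 0), "target_fst")
  expect_error(sim_config(target_fst = 1.2), "target_fst")
  expect_error(sim_config(null_allele_rate = 1), "null_allele_rate")
  expect_error(sim_config(true_ne = 5), "true_ne")
})

test_that("the default configuration emulates the study design", {
  cfg <- sim_config()
  g <- simulate_genotypes(cfg)
  expect_equal(n_ind(g), 173L)
  expect_equal(n_loci(g), 7L)
  expect_equal(nlevels(g$pop), 4L)
  expect_equal(unname(tabulate(g$pop)), c(43L, 43L, 42L, 45L))
})

test_that("near-zero F gives near-zero theta on average", {
  set.seed(111)
  thetas <- replicate(30, {
    cfg <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 10,
                      alleles_per_locus = 6, target_fst = 1e-6,
                      seed = sample.int(1e6, 1))
    wc_theta(simulate_genotypes(cfg))$theta
  })
  expect_lt(abs(mean(thetas)), 0.01)
})

test_that("null alleles depress Ho and inflate f", {
  clean_f <- clean_ho <- null_f <- null_ho <- numeric(20)
  for (i in 1:20) {
    base <- sim_config(n_pops = 1, n_per_pop = 60, n_loci = 6,
                       alleles_per_locus = 8, seed = 1000 + i)
    nulls <- sim_config(n_pops = 1, n_per_pop = 60, n_loci = 6,
                        alleles_per_locus = 8, null_allele_rate = 0.3,
                        seed = 1000 + i)
    gc <- simulate_genotypes(base); gn <- simulate_genotypes(nulls)
    clean_ho[i] <- mean(heterozygosity(gc, "pop1")$Ho, na.rm = TRUE)
    null_ho[i] <- mean(heterozygosity(gn, "pop1")$Ho, na.rm = TRUE)
    fcomp <- function(g) {
      comp <- margadapt:::fis_components(g, "pop1")
      ok <- !is.na(comp$b)
      sum(comp$b[ok]) / sum(comp$b[ok] + comp$c[ok])
    }
    clean_f[i] <- fcomp(gc); null_f[i] <- fcomp(gn)
  }
  expect_lt(mean(null_ho), mean(clean_ho))
  expect_gt(mean(null_f), mean(clean_f) + 0.05)
})

test_that("simulated GENEPOP files round-trip through the parser", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 12, n_loci = 4,
                    alleles_per_locus = 30, seed = 7)
  g <- simulate_genotypes(cfg)
  path <- tempfile(fileext = ".gen")
  write_genepop(g, path)
  g2 <- read_genepop(path, pop_labels = levels(g$pop))
  expect_identical(g2$calls, g$calls)
  expect_identical(as.character(g2$pop), as.character(g$pop))
})

test_that("RTE phenotypes implement the local-vs-foreign pattern", {
  cfg <- sim_config(seed = 13)
  ph <- simulate_rte_phenotypes(cfg)
  expect_s3_class(ph, "phenotype_table")
  expect_equal(nrow(ph), 40L)
  agg <- tapply(ph$value, list(ph$origin_depth, ph$treatment_depth), mean)
  ## local sample grows fastest within each habitat
  expect_gt(agg["shallow", "shallow"], agg["mesophotic", "shallow"])
  expect_gt(agg["mesophotic", "mesophotic"], agg["shallow", "mesophotic"])
})

test_that("a strong simulated interaction is detected by the two-way analysis", {
  set.seed(222)
  hits <- replicate(20, {
    sd_w <- sqrt(4.1e-4)
    cm <- matrix(c(0.15, 0.15 - 3 * sd_w, 0.15 - 3 * sd_w, 0.15), 2, 2,
                 dimnames = list(origin = c("shallow", "mesophotic"),
                                 treatment = c("shallow", "mesophotic")))
    cfg <- sim_config(cell_means = cm, seed = sample.int(1e6, 1))
    ph <- simulate_rte_phenotypes(cfg)
    r <- permanova_pheno(ph, "two-way", n_perm = 199, seed = 1)
    r$table$p[3] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("equal cell means keep the interaction test at its nominal size", {
  set.seed(223)
  cm <- matrix(0.12, 2, 2, dimnames = list(origin = c("shallow", "mesophotic"),
                                           treatment = c("shallow", "mesophotic")))
  rej <- replicate(100, {
    cfg <- sim_config(cell_means = cm, seed = sample.int(1e6, 1))
    ph <- simulate_rte_phenotypes(cfg)
    permanova_pheno(ph, "two-way", n_perm = 99, seed = 1)$table$p[3] <= 0.05
  })
  expect_lt(mean(rej), 0.12)
  expect_gte(mean(rej), 0.0)
})

test_that("a temperature series below threshold produces no necrosis", {
  cfg <- sim_config(seed = 17)
  cool <- rep(20, 2000)
  ph <- simulate_cge_necrosis(cfg, temperature = cool)
  expect_true(all(ph$value == 0))
  ss <- survival_summary(ph)
  expect_equal(ss$survival_pct, c(100, 100))
  expect_equal(ss$never_necrosed_pct, c(100, 100))
})

test_that("differential necrosis slopes separate the origins", {
  cfg <- sim_config(seed = 19)
  ph <- simulate_cge_necrosis(cfg)
  r <- permanova_pheno(ph, "one-way", trait = "necrosis_pct", n_perm = 999,
                       seed = 2)
  expect_lt(r$table$p[1], 0.01)
  ## mesophotic-origin colonies end up more necrosed
  last <- ph[ph$time == max(ph$time), ]
  m <- tapply(last$value, last$origin_depth, mean)
  expect_gt(m["mesophotic"], m["shallow"])
})

test_that("identical necrosis parameters give symmetric survival", {
  set.seed(29)
  diffs <- replicate(20, {
    cfg <- sim_config(necrosis_lag_dh = c(shallow = 150, mesophotic = 150),
                      necrosis_slope = c(shallow = 0.2, mesophotic = 0.2),
                      seed = sample.int(1e6, 1))
    ph <- simulate_cge_necrosis(cfg)
    ss <- survival_summary(ph)
    diff(ss$survival_pct)
  })
  expect_lt(abs(mean(diffs)), 15)
})

test_that("the expected P_ST of simulated traits matches the components", {
  ## fixed sample means so the generating among-sample mean square is exact
  sB <- 2; sW <- 1
  target <- sB / (sB + 2 * sW)
  set.seed(37)
  ests <- replicate(20, {
    d <- simulate_trait_samples(2, 200, sigma2_B = 0, sigma2_W = sW,
                                fixed_means = c(-1, 1),
                                seed = sample.int(1e6, 1))
    vc <- variance_components(d$value, d$sample)
    pst_curve(vc$sigma2_B, vc$sigma2_W, 1)
  })
  expect_lt(abs(mean(ests) - target), 0.03)
})
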
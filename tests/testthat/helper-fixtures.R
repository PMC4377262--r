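## Programmatic fixtures.

## Random small genotype table for fuzzing/oracle checks.
random_geno <- function(n_pops = 2, n_per_pop = 8, n_loci = 2, n_alleles = 4,
                        miss_rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  n <- sum(n_per_pop)
  calls <- array(NA_integer_, dim = c(n, n_loci, 2))
  for (l in seq_len(n_loci)) {
    a1 <- sample.int(n_alleles, n, replace = TRUE)
    a2 <- sample.int(n_alleles, n, replace = TRUE)
    miss <- runif(n) < miss_rate
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    calls[, l, 1] <- a1; calls[, l, 2] <- a2
  }
  genotype_matrix(calls, pop = rep(paste0("p", seq_len(n_pops)), n_per_pop))
}

## Build a one-population genotype matrix from a list of loci, each a
## two-column matrix of allele calls (rows = individuals).
geno_from_loci <- function(..., pop = NULL) {
  loci <- list(...)
  n <- nrow(loci[[1]])
  calls <- array(NA_integer_, dim = c(n, length(loci), 2))
  for (l in seq_along(loci)) {
    calls[, l, 1] <- loci[[l]][, 1]
    calls[, l, 2] <- loci[[l]][, 2]
  }
  if (is.null(pop)) pop <- rep("s1", n)
  genotype_matrix(calls, pop = pop)
}

## Random allele-frequency vector (symmetric Dirichlet(1)).
rdirich_probs <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

## All 720 permutations of 1:6 (rows), for exhaustive shuffling oracles.
permutations6 <- function() {
  perm <- matrix(1L, 1, 1)
  for (m in 2:6) {
    out <- matrix(0L, nrow(perm) * m, m)
    r <- 0L
    for (i in seq_len(nrow(perm))) for (pos in seq_len(m)) {
      r <- r + 1L
      out[r, ] <- append(perm[i, ], m, after = pos - 1L)
    }
    perm <- out
  }
  perm
}

## A tiny GENEPOP file written to a temp path; returns the path.
write_tmp_genepop <- function(lines) {
  path <- tempfile(fileext = ".gen")
  writeLines(lines, path)
  path
}

## Minimal growth phenotype table for a balanced 2x2 design.
make_rte_pheno <- function(values, n_per_cell) {
  depths <- c("shallow", "mesophotic")
  grid <- expand.grid(rep = seq_len(n_per_cell), origin = depths,
                      treatment = depths, stringsAsFactors = FALSE)
  phenotype_table(data.frame(
    individual = paste0("c", seq_len(nrow(grid))),
    sample = paste0("S-", ifelse(grid$origin == "shallow", "20", "40")),
    origin_depth = grid$origin, treatment_depth = grid$treatment,
    trait = "growth_mm", value = values))
}
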
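#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' The defaults emulate the study design the package targets: 4 populations
#' of 43, 43, 42 and 45 genotyped diploids at 7 microsatellite loci with
#' island-model differentiation around theta = 0.1; a balanced 2 x 2
#' reciprocal-transplant phenotype design with 10 colonies per cell and a
#' local-vs-foreign growth pattern; a common-garden necrosis model with a
#' 24 degree C onset threshold and a faster necrosis slope for
#' mesophotic-origin colonies; and a Wright-Fisher cohort for effective-size
#' recovery.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploids per population (recycled to `n_pops`).
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param target_fst Balding-Nichols F in (0, 1).
#' @param inbreeding_f probability of autozygosity when drawing a genotype.
#' @param null_allele_rate frequency of a hidden null allele per locus.
#' @param cell_means named 2 x 2 matrix (origin x treatment) of growth
#'   means, rows/cols named `shallow`, `mesophotic` (units: mm).
#' @param sigma2_W within-cell (residual) trait variance.
#' @param sigma2_B among-sample trait variance (used by
#'   [simulate_trait_samples()]).
#' @param n_per_cell colonies per transplant cell.
#' @param cge_n colonies per origin in the common garden.
#' @param necrosis_threshold_C temperature above which degree-hours
#'   accumulate.
#' @param necrosis_lag_dh origin-specific degree-hour lag before necrosis
#'   onset (named vector: shallow, mesophotic).
#' @param necrosis_slope origin-specific necrosis increase (% per
#'   degree-hour past the lag).
#' @param true_ne Wright-Fisher parental pool size.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 4,
                       n_per_pop = c(43, 43, 42, 45),
                       n_loci = 7,
                       alleles_per_locus = 12,
                       target_fst = 0.1,
                       inbreeding_f = 0,
                       null_allele_rate = 0,
                       cell_means = matrix(c(0.15, 0.12, 0.10, 0.13), 2, 2,
                                           dimnames = list(
                                             origin = c("shallow", "mesophotic"),
                                             treatment = c("shallow", "mesophotic"))),
                       sigma2_W = 4.1e-4,
                       sigma2_B = 0,
                       n_per_cell = 10,
                       cge_n = 24,
                       necrosis_threshold_C = 24,
                       necrosis_lag_dh = c(shallow = 400, mesophotic = 60),
                       necrosis_slope = c(shallow = 0.05, mesophotic = 0.45),
                       true_ne = 50,
                       seed = 1) {
  n_per_pop <- rep_len(n_per_pop, n_pops)
  cfg <- list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
              alleles_per_locus = alleles_per_locus, target_fst = target_fst,
              inbreeding_f = inbreeding_f, null_allele_rate = null_allele_rate,
              cell_means = cell_means, sigma2_W = sigma2_W,
              sigma2_B = sigma2_B, n_per_cell = n_per_cell, cge_n = cge_n,
              necrosis_threshold_C = necrosis_threshold_C,
              necrosis_lag_dh = necrosis_lag_dh,
              necrosis_slope = necrosis_slope, true_ne = true_ne, seed = seed)
  stopifnot(cfg$n_pops >= 1, all(cfg$n_per_pop >= 1), cfg$n_loci >= 1,
            cfg$alleles_per_locus >= 2,
            cfg$target_fst > 0, cfg$target_fst < 1,
            cfg$inbreeding_f >= 0, cfg$inbreeding_f <= 1,
            cfg$null_allele_rate >= 0, cfg$null_allele_rate < 1,
            cfg$sigma2_W >= 0, cfg$sigma2_B >= 0,
            cfg$n_per_cell >= 2, cfg$cge_n >= 2, cfg$true_ne >= 10)
  class(cfg) <- "sim_config"
  cfg
}

## Symmetric-Dirichlet draw.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

## Draw one diploid genotype matrix (n x 2) at allele frequencies p with
## inbreeding f (probability of autozygosity).
draw_genotypes <- function(n, p, f = 0) {
  codes <- seq_along(p)
  a1 <- sample(codes, n, replace = TRUE, prob = p)
  a2 <- sample(codes, n, replace = TRUE, prob = p)
  if (f > 0) {
    auto <- stats::runif(n) < f
    a2[auto] <- a1[auto]
  }
  cbind(a1, a2)
}

#' Simulate island-model genotypes (Balding-Nichols)
#'
#' Ancestral allele frequencies are drawn from a symmetric Dirichlet(1);
#' population frequencies from the Balding-Nichols distribution
#' `Dirichlet(p_anc (1 - F) / F)`, which makes `F` the expected
#' Weir-Cockerham differentiation among populations. Diploid genotypes are
#' drawn with optional inbreeding (probability `inbreeding_f` of
#' autozygosity). An optional null allele (frequency `null_allele_rate`,
#' carved out of the ancestral simplex before the population draw) renders
#' heterozygous carriers apparently homozygous and null homozygotes
#' missing.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with populations `pop1..popK`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- sum(cfg$n_per_pop)
  calls <- array(NA_integer_, dim = c(n, cfg$n_loci, 2))
  popv <- rep(paste0("pop", seq_len(cfg$n_pops)), cfg$n_per_pop)
  F <- cfg$target_fst
  null_code <- cfg$alleles_per_locus + 1L
  for (l in seq_len(cfg$n_loci)) {
    p_anc <- rdirichlet1(rep(1, cfg$alleles_per_locus))
    if (cfg$null_allele_rate > 0)
      p_anc <- c(p_anc * (1 - cfg$null_allele_rate), cfg$null_allele_rate)
    row0 <- 0L
    for (i in seq_len(cfg$n_pops)) {
      p_i <- rdirichlet1(p_anc * (1 - F) / F)
      g <- draw_genotypes(cfg$n_per_pop[i], p_i, cfg$inbreeding_f)
      rows <- row0 + seq_len(cfg$n_per_pop[i])
      calls[rows, l, 1] <- g[, 1]
      calls[rows, l, 2] <- g[, 2]
      row0 <- row0 + cfg$n_per_pop[i]
    }
    if (cfg$null_allele_rate > 0) {
      a1 <- calls[, l, 1]; a2 <- calls[, l, 2]
      both_null <- a1 == null_code & a2 == null_code
      a1[a1 == null_code] <- a2[a1 == null_code]  # carrier looks homozygous
      a2[a2 == null_code] <- a1[a2 == null_code]
      a1[both_null] <- NA_integer_; a2[both_null] <- NA_integer_
      calls[, l, 1] <- a1; calls[, l, 2] <- a2
    }
  }
  genotype_matrix(calls, pop = popv,
                  individuals = paste0(popv, "_", sequence(cfg$n_per_pop)))
}

#' Simulate a one-generation Wright-Fisher cohort
#'
#' A parental pool of `true_ne` diploids is drawn at Dirichlet(1) allele
#' frequencies; each offspring is produced by picking two parents at random
#' (a new random pair for every birth) and one gamete from each. The
#' returned sample of `n_per_pop[1]` offspring carries the linkage
#' disequilibrium induced by drift in a parental population of effective
#' size `true_ne`, which is what the LD method of [ldne_estimate()] should
#' recover.
#'
#' @param cfg a [sim_config()]; relevant fields: `true_ne`, `n_per_pop[1]`,
#'   `n_loci`, `alleles_per_locus`, `seed`.
#' @return a [genotype_matrix()] with a single population `cohort`.
#' @export
simulate_wf_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ne <- cfg$true_ne
  n_off <- cfg$n_per_pop[1]
  L <- cfg$n_loci
  parents <- array(NA_integer_, dim = c(ne, L, 2))
  for (l in seq_len(L)) {
    p <- rdirichlet1(rep(1, cfg$alleles_per_locus))
    g <- draw_genotypes(ne, p)
    parents[, l, 1] <- g[, 1]; parents[, l, 2] <- g[, 2]
  }
  dams <- sample.int(ne, n_off, replace = TRUE)
  sires <- sample.int(ne, n_off, replace = TRUE)
  calls <- array(NA_integer_, dim = c(n_off, L, 2))
  for (l in seq_len(L)) {
    pick1 <- sample(c(1L, 2L), n_off, replace = TRUE)
    pick2 <- sample(c(1L, 2L), n_off, replace = TRUE)
    calls[, l, 1] <- parents[cbind(dams, l, pick1)]
    calls[, l, 2] <- parents[cbind(sires, l, pick2)]
  }
  genotype_matrix(calls, pop = rep("cohort", n_off),
                  individuals = paste0("off", seq_len(n_off)))
}

#' Simulate reciprocal-transplant growth phenotypes
#'
#' Balanced 2 x 2 design (origin depth x treatment depth) with
#' `n_per_cell` colonies per cell: each response is the cell mean plus
#' Normal(0, `sigma2_W`) noise. The default cell means implement a
#' local-vs-foreign pattern (each habitat's local sample grows fastest)
#' with a residual variance matching the scale of calcein-derived growth
#' increments in millimetres.
#'
#' @param cfg a [sim_config()].
#' @param locality sample-name prefix for the two origins.
#' @return a `phenotype_table` of `growth_mm` records.
#' @export
simulate_rte_phenotypes <- function(cfg, locality = "RI") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 2))
  depths <- c("shallow", "mesophotic")
  rows <- list(); k <- 0L
  for (o in depths) for (t in depths) {
    k <- k + 1L
    mu <- cfg$cell_means[o, t]
    vals <- mu + stats::rnorm(cfg$n_per_cell, 0, sqrt(cfg$sigma2_W))
    rows[[k]] <- data.frame(
      individual = sprintf("%s_%s_%s_%02d", locality, o, t,
                           seq_len(cfg$n_per_cell)),
      sample = paste0(locality, "-", ifelse(o == "shallow", "20", "40")),
      origin_depth = o, treatment_depth = t,
      trait = "growth_mm", value = pmax(vals, 0))
  }
  phenotype_table(do.call(rbind, rows))
}

#' Simulate trait samples with known variance components
#'
#' Draws `k` sample means from Normal(`mu`, `sigma2_B`) and `n_per_sample`
#' individual values per sample from Normal(mean_i, `sigma2_W`), the
#' random-effects structure whose method-of-moments estimates
#' [variance_components()] should recover. With `fixed_means` supplied the
#' sample means are taken as given instead (their mean-square around the
#' grand mean then plays the role of `sigma2_B`).
#'
#' @param k number of samples.
#' @param n_per_sample observations per sample (recycled).
#' @param sigma2_B,sigma2_W variance components.
#' @param mu grand mean.
#' @param fixed_means optional fixed sample means (overrides `sigma2_B`).
#' @param seed RNG seed.
#' @return data.frame with columns `value`, `sample`.
#' @export
simulate_trait_samples <- function(k, n_per_sample, sigma2_B, sigma2_W,
                                   mu = 0, fixed_means = NULL, seed = NULL) {
  with_seed(seed, {
    n_per_sample <- rep_len(n_per_sample, k)
    means <- if (is.null(fixed_means))
      stats::rnorm(k, mu, sqrt(sigma2_B)) else rep_len(fixed_means, k)
    value <- unlist(lapply(seq_len(k), function(i)
      stats::rnorm(n_per_sample[i], means[i], sqrt(sigma2_W))))
    data.frame(value = value,
               sample = rep(paste0("s", seq_len(k)), n_per_sample))
  })
}

#' Generate a common-garden temperature series
#'
#' Sinusoidal summer warming plus a sustained anomaly exceeding the
#' necrosis threshold, on an hourly grid: the shape of a shallow
#' Mediterranean summer with a positive thermal anomaly.
#'
#' @param n_hours length of the series.
#' @param base_C mean temperature.
#' @param amplitude_C seasonal amplitude.
#' @param anomaly_C extra warming during the anomaly window.
#' @param anomaly_window integer range of hours for the anomaly.
#' @return numeric vector of temperatures (degrees C).
#' @export
cge_temperature_series <- function(n_hours = 2160, base_C = 21,
                                   amplitude_C = 3, anomaly_C = 1.5,
                                   anomaly_window = 1000:1800) {
  h <- seq_len(n_hours)
  temp <- base_C + amplitude_C * sin(pi * h / n_hours)
  temp[anomaly_window] <- temp[anomaly_window] + anomaly_C
  temp
}

#' Simulate common-garden necrosis trajectories
#'
#' Phenomenological threshold model: per colony, necrosis stays at 0 until
#' the cumulative degree-hours above `necrosis_threshold_C` exceed an
#' origin-specific lag, then increases proportionally to the exceedance
#' (origin-specific slope, small colony-level noise), capped at 100%.
#' Survival is a final necrosis below 100%. The defaults give
#' mesophotic-origin colonies an earlier onset and a much steeper slope,
#' the differential-buffering pattern the one-way analysis should detect.
#'
#' @param cfg a [sim_config()].
#' @param temperature hourly temperature series (default
#'   [cge_temperature_series()]).
#' @param n_surveys number of survey time points.
#' @param locality sample-name prefix.
#' @return a `phenotype_table` of `necrosis_pct` records with a `time`
#'   column (survey index).
#' @export
simulate_cge_necrosis <- function(cfg, temperature = cge_temperature_series(),
                                  n_surveys = 10, locality = "RI") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 3))
  dh <- cumsum(pmax(temperature - cfg$necrosis_threshold_C, 0))
  survey_at <- round(seq(1, length(temperature), length.out = n_surveys))
  depths <- c("shallow", "mesophotic")
  rows <- list(); k <- 0L
  for (o in depths) {
    lag <- cfg$necrosis_lag_dh[[o]]
    slope <- cfg$necrosis_slope[[o]]
    for (i in seq_len(cfg$cge_n)) {
      lag_i <- lag * exp(stats::rnorm(1, 0, 0.3))
      slope_i <- slope * exp(stats::rnorm(1, 0, 0.4))
      nec <- pmin(100, pmax(0, slope_i * (dh[survey_at] - lag_i)))
      k <- k + 1L
      rows[[k]] <- data.frame(
        individual = sprintf("%s_cge_%s_%02d", locality, o, i),
        sample = paste0(locality, "-", ifelse(o == "shallow", "20", "40")),
        origin_depth = o, treatment_depth = "shallow",
        trait = "necrosis_pct", value = nec, time = seq_len(n_surveys))
    }
  }
  phenotype_table(do.call(rbind, rows))
}
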
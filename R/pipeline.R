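#' Run the full study analysis from one configuration
#'
#' Orchestrates the stages of the depth-adaptation analysis in dependency
#' order: per-sample diversity table, linkage-disequilibrium battery,
#' global and pairwise Weir-Cockerham theta with bootstrap CIs, genotypic
#' differentiation, Nei Da distances with a neighbor-joining phenogram,
#' LD-based effective population sizes, PERMANOVA of the transplant and
#' common-garden phenotypes, and the P_ST-F_ST comparisons with the
#' (c/h2)_crit sensitivity analysis. Stage failures are recorded and
#' dependent stages are skipped with an explanation; with only genotype
#' input the phenotype stages are skipped, and vice versa. One global seed
#' is expanded into fixed per-stage child seeds so any stage can be rerun
#' in isolation; rerunning with the same inputs and seed reproduces the
#' report exactly.
#'
#' @param config a list (or path to a YAML file, read with \pkg{yaml} when
#'   installed) with any of:
#'   \describe{
#'     \item{genepop}{path to a GENEPOP file, or a [genotype_matrix()].}
#'     \item{phenotypes}{path to a phenotype CSV, or a `phenotype_table`
#'       (growth records for the transplant analysis).}
#'     \item{necrosis}{optional `phenotype_table` (or path) of necrosis
#'       time series for the common-garden analysis.}
#'     \item{pairs}{list of 2-vectors of sample labels for pairwise P_ST;
#'       default: the sample pairs present in the phenotype table.}
#'     \item{fst_refs}{named numeric vector of external F_ST references
#'       (default `c(F_STall = 0.1)`); the pairwise theta upper CI bound is
#'       always added per comparison.}
#'     \item{seed}{integer global seed (default 1).}
#'     \item{n_boot, n_perm, ar_genes, freq_cutoff}{stage parameters;
#'       defaults 1000, 9999, NULL (auto), 0.02.}
#'   }
#' @param out_dir optional directory; when given, CSV tables, the newick
#'   tree and a JSON report are written there.
#' @return an object of class `run_report`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_boot <- if (is.null(config$n_boot)) 1000L else as.integer(config$n_boot)
  n_perm <- if (is.null(config$n_perm)) 9999L else as.integer(config$n_perm)
  cutoff <- if (is.null(config$freq_cutoff)) 0.02 else config$freq_cutoff

  report <- list(version = as.character(utils::packageVersion("margadapt")),
                 seed = seed, stages = list(), warnings = character(0))
  note <- function(stage, why) {
    report$warnings <<- c(report$warnings, paste0(stage, ": ", why))
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      note(name, conditionMessage(e)); NULL
    })
    report$stages[[name]] <<- if (is.null(res)) list(status = "failed")
                              else list(status = "ok", result = res)
    res
  }

  geno <- NULL
  if (!is.null(config$genepop)) {
    geno <- if (inherits(config$genepop, "genotype_matrix")) config$genepop
            else read_genepop(config$genepop)
  }
  pheno <- NULL
  if (!is.null(config$phenotypes)) {
    pheno <- if (inherits(config$phenotypes, "phenotype_table")) config$phenotypes
             else read_phenotypes(config$phenotypes)
  }
  necro <- NULL
  if (!is.null(config$necrosis)) {
    necro <- if (inherits(config$necrosis, "phenotype_table")) config$necrosis
             else read_phenotypes(config$necrosis)
  }
  if (is.null(geno) && is.null(pheno) && is.null(necro))
    stop("config names neither genotype nor phenotype input")

  ## --- genetic stages -----------------------------------------------------
  if (!is.null(geno)) {
    run_stage("diversity", diversity_summary(geno, g = config$ar_genes,
                                             n_perm = min(n_perm, 999),
                                             seed = child_seed(seed, 11)))
    run_stage("ld_battery", ld_battery(geno, n_perm = min(n_perm, 999),
                                       seed = child_seed(seed, 12)))
    theta_global <- run_stage("theta_global",
                              wc_theta_ci(geno, n_boot = n_boot,
                                          seed = child_seed(seed, 13)))
    theta_pairs <- run_stage("theta_pairwise",
                             pairwise_theta(geno, n_boot = n_boot,
                                            seed = child_seed(seed, 14)))
    run_stage("genotypic_differentiation",
              genotypic_diff_test(geno, n_perm = min(n_perm, 999),
                                  seed = child_seed(seed, 15)))
    run_stage("nei_da", nei_da(geno))
    if (nlevels(geno$pop) >= 3L)
      run_stage("nj_tree", nj_phenogram(geno, n_boot = n_boot,
                                        seed = child_seed(seed, 16)))
    else note("nj_tree", "skipped: fewer than 3 samples")
    run_stage("ne", {
      out <- lapply(levels(geno$pop), function(s)
        tryCatch(ldne_estimate(geno, s, freq_cutoff = cutoff),
                 error = function(e) { note("ne", paste0(s, ": ", conditionMessage(e))); NULL }))
      names(out) <- levels(geno$pop)
      out[!vapply(out, is.null, logical(1))]
    })
  } else {
    note("genetics", "skipped: no genotype input")
    theta_global <- NULL; theta_pairs <- NULL
  }

  ## --- phenotype stages ---------------------------------------------------
  if (!is.null(pheno)) {
    run_stage("permanova_rte",
              permanova_pheno(pheno, "two-way", trait = "growth_mm",
                              n_perm = n_perm, seed = child_seed(seed, 21)))
  } else note("permanova_rte", "skipped: no growth phenotype input")
  if (!is.null(necro)) {
    run_stage("permanova_cge",
              permanova_pheno(necro, "one-way", trait = "necrosis_pct",
                              n_perm = n_perm, seed = child_seed(seed, 22)))
    run_stage("survival", survival_summary(necro))
  } else note("permanova_cge", "skipped: no necrosis input")

  ## --- P_ST-F_ST comparisons ---------------------------------------------
  fst_refs <- if (is.null(config$fst_refs)) c(F_STall = 0.1) else unlist(config$fst_refs)
  pst_inputs <- list()
  if (!is.null(pheno)) {
    ## within each treatment habitat, compare the origin samples
    for (tr in levels(droplevels(pheno$treatment_depth))) {
      d <- pheno[pheno$treatment_depth == tr & pheno$trait == "growth_mm", ]
      if (length(unique(d$sample)) >= 2L)
        pst_inputs[[paste0("growth_", tr)]] <- d
    }
  }
  if (!is.null(necro)) {
    d <- necro[necro$trait == "necrosis_pct", ]
    if ("time" %in% names(d)) d <- d[d$time == max(d$time), ]
    if (length(unique(d$sample)) >= 2L) pst_inputs[["necrosis_cge"]] <- d
  }
  if (length(pst_inputs)) {
    run_stage("pst_fst", {
      out <- list()
      for (nm in names(pst_inputs)) {
        d <- pst_inputs[[nm]]
        pst <- pst_bootstrap(d$value, d$sample, n_boot = max(n_boot, 200),
                             seed = child_seed(seed, 31 + length(out)))
        refs <- fst_refs
        samp <- unique(as.character(d$sample))
        hit <- integer(0)
        if (!is.null(theta_pairs) && length(samp) == 2L &&
            "ci_hi" %in% names(theta_pairs))
          hit <- which((theta_pairs$sample1 %in% samp) &
                         (theta_pairs$sample2 %in% samp))
        if (length(hit)) {
          refs <- c(theta_upper_CI = theta_pairs$ci_hi[hit[1]], refs)
        } else if (!is.null(theta_global) && !is.null(theta_global$ci95)) {
          ## no matching genotyped pair: fall back to the global theta CI
          refs <- c(theta_upper_CI = unname(theta_global$ci95[2]), refs)
        }
        out[[nm]] <- list(pst = pst, comparison = pst_fst_compare(pst, refs))
      }
      out
    })
  } else note("pst_fst", "skipped: no trait table with >= 2 samples")

  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("margadapt run report (seed", x$seed, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-28s %s\n", nm, x$stages[[nm]]$status))
  if (length(x$warnings)) {
    cat("notes:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' CSV tables per stage, the tree as newick, and a JSON summary of every
#' numeric result.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- report$stages
  put_csv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(st$diversity$result)) put_csv(st$diversity$result, "diversity")
  if (!is.null(st$ld_battery$result)) put_csv(st$ld_battery$result, "ld_battery")
  if (!is.null(st$theta_pairwise$result))
    put_csv(st$theta_pairwise$result, "theta_pairwise")
  if (!is.null(st$nj_tree$result))
    writeLines(st$nj_tree$result$newick, file.path(out_dir, "tree.nwk"))
  if (!is.null(st$permanova_rte$result))
    put_csv(st$permanova_rte$result$table, "permanova_rte")
  if (!is.null(st$permanova_cge$result))
    put_csv(st$permanova_cge$result$table, "permanova_cge")
  if (!is.null(st$pst_fst$result)) {
    for (nm in names(st$pst_fst$result)) {
      p <- st$pst_fst$result[[nm]]$pst
      put_csv(data.frame(r = p$r_grid, pst = p$pst, ci_lo = p$ci_lo,
                         ci_hi = p$ci_hi), paste0("pst_curve_", nm))
      put_csv(st$pst_fst$result[[nm]]$comparison, paste0("pst_fst_", nm))
    }
  }
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Flat numeric summary of a run report
#'
#' @param report a `run_report`.
#' @return a named list of scalar summaries (suitable for JSON output).
#' @export
report_summary <- function(report) {
  st <- report$stages
  out <- list(version = report$version, seed = report$seed)
  if (!is.null(st$theta_global$result)) {
    tg <- st$theta_global$result
    out$global_theta <- tg$theta
    out$global_theta_ci <- tg$ci95
  }
  if (!is.null(st$theta_pairwise$result)) {
    tp <- st$theta_pairwise$result
    out$pairwise_theta_min <- min(tp$theta)
    out$pairwise_theta_max <- max(tp$theta)
  }
  if (!is.null(st$diversity$result)) {
    dv <- st$diversity$result
    out$mean_Ho <- mean(dv$Ho_mean)
    out$mean_He <- mean(dv$He_mean)
    out$mean_Ar <- mean(dv$Ar_mean)
  }
  if (!is.null(st$ne$result))
    out$ne_estimates <- lapply(st$ne$result, function(e)
      list(ne = e$ne_hat, lo = e$ci95[1], hi = e$ci95[2]))
  if (!is.null(st$permanova_rte$result)) {
    tb <- st$permanova_rte$result$table
    out$rte_interaction_F <- tb$pseudo_F[3]
    out$rte_interaction_p <- tb$p[3]
  }
  if (!is.null(st$permanova_cge$result)) {
    tb <- st$permanova_cge$result$table
    out$cge_origin_F <- tb$pseudo_F[1]
    out$cge_origin_p <- tb$p[1]
  }
  if (!is.null(st$pst_fst$result)) {
    out$pst_fst <- lapply(st$pst_fst$result, function(x) {
      i1 <- which.min(abs(x$pst$r_grid - 1))
      list(pst_1 = x$pst$pst[i1], ci_lo = x$pst$ci_lo[i1],
           ci_hi = x$pst$ci_hi[i1],
           crit_r = stats::setNames(as.list(x$comparison$crit_r),
                                    x$comparison$ref))
    })
  }
  out$warnings <- report$warnings
  out
}
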
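#' Read a GENEPOP genotype file
#'
#' Parses the classical GENEPOP text format: a title line, one locus name per
#' line (or a single comma-separated line), then population blocks delimited
#' by lines reading `pop` (any capitalisation). Each record is
#' `id , g1 g2 ...` with each genotype a concatenation of two fixed-width
#' allele codes. `00`/`000` (or the whole-genotype zero) marks a missing
#' call. Parsing is insensitive to Windows line endings and trailing
#' whitespace.
#'
#' @param path path to a GENEPOP file.
#' @param allele_digits 2 or 3, or `NULL` (default) to auto-detect from the
#'   genotype field width of the first record.
#' @param pop_labels optional character vector of population labels, one per
#'   `pop` block; defaults to the id of the last individual of each block
#'   (the usual GENEPOP convention), de-duplicated if needed.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, allele_digits = NULL, pop_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- sub("[ \t]+$", "", lines)
  if (length(lines) < 3L) stop("empty or truncated GENEPOP file: ", path)

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'pop' separator found in ", path)
  if (first_pop < 3L) stop("zero loci declared before the first 'pop' line")

  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("zero loci declared in ", path)

  block_of <- cumsum(is_pop)
  body <- which(seq_along(lines) > first_pop & !is_pop & nzchar(trimws(lines)))
  if (length(body) == 0L) stop("zero individuals in ", path)

  ids <- character(length(body))
  pops <- integer(length(body))
  geno_tok <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    parts <- strsplit(lines[ln], ",")[[1]]
    if (length(parts) < 2L)
      stop("malformed record (no comma) at line ", ln, " of ", path)
    ids[k] <- trimws(parts[1])
    pops[k] <- block_of[ln]
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci))
      stop("expected ", length(loci), " genotypes but found ", length(toks),
           " at line ", ln, " of ", path)
    geno_tok[[k]] <- toks
  }

  widths <- unique(nchar(unlist(geno_tok)))
  if (is.null(allele_digits)) {
    if (all(widths == 4L)) allele_digits <- 2L
    else if (all(widths == 6L)) allele_digits <- 3L
    else stop("cannot auto-detect allele digits: genotype widths ",
              paste(widths, collapse = "/"), " in ", path)
  }
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  w <- 2L * allele_digits
  bad <- which(vapply(geno_tok, function(t) any(nchar(t) != w), logical(1)))
  if (length(bad))
    stop("malformed genotype width at line ", body[bad[1]], " of ", path)

  n <- length(body); L <- length(loci)
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (k in seq_len(n)) {
    toks <- geno_tok[[k]]
    a1 <- suppressWarnings(as.integer(substr(toks, 1L, allele_digits)))
    a2 <- suppressWarnings(as.integer(substr(toks, allele_digits + 1L, w)))
    if (anyNA(a1) || anyNA(a2))
      stop("non-numeric genotype at line ", body[k], " of ", path)
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    calls[k, , 1] <- a1; calls[k, , 2] <- a2
  }

  n_pop <- max(pops)
  if (is.null(pop_labels)) {
    pop_labels <- vapply(seq_len(n_pop),
                         function(b) ids[max(which(pops == b))], character(1))
    if (anyDuplicated(pop_labels))
      pop_labels <- paste0("pop", seq_len(n_pop))
  }
  if (length(pop_labels) != n_pop)
    stop("need ", n_pop, " population labels, got ", length(pop_labels))

  genotype_matrix(calls, pop = pop_labels[pops], individuals = ids, loci = loci)
}

#' Write a genotype matrix to GENEPOP format
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param allele_digits 2 or 3; must accommodate the largest allele code.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, allele_digits = NULL,
                          title = "margadapt export") {
  max_code <- suppressWarnings(max(x$calls, na.rm = TRUE))
  if (!is.finite(max_code)) max_code <- 1L
  if (is.null(allele_digits)) allele_digits <- if (max_code > 99L) 3L else 2L
  if (max_code >= 10^allele_digits)
    stop("allele code ", max_code, " does not fit in ", allele_digits, " digits")
  fmt <- paste0("%0", allele_digits, "d")
  out <- c(title, x$loci)
  for (p in levels(x$pop)) {
    out <- c(out, "pop")
    for (i in which(x$pop == p)) {
      a1 <- x$calls[i, , 1]; a2 <- x$calls[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      toks <- paste0(sprintf(fmt, a1), sprintf(fmt, a2))
      out <- c(out, paste0(x$individuals[i], " ,  ", paste(toks, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a delimited text file of per-colony trait records into a validated
#' `phenotype_table`. Required columns: `individual`, `sample`,
#' `origin_depth`, `treatment_depth`, `trait`, `value`. An optional `time`
#' column supports necrosis time series. Factor levels for the two depth
#' columns must come from `depth_levels`; trait names from `trait_levels`.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected from the
#'   header line).
#' @param depth_levels allowed levels for origin/treatment depth factors.
#' @param trait_levels allowed trait names.
#' @return a `phenotype_table` (a validated `data.frame`).
#' @export
read_phenotypes <- function(path,
                            depth_levels = c("shallow", "mesophotic"),
                            trait_levels = c("growth_mm", "necrosis_pct")) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  phenotype_table(df, depth_levels = depth_levels, trait_levels = trait_levels)
}

#' Construct and validate a phenotype table
#'
#' @param df a data.frame with columns `individual`, `sample`,
#'   `origin_depth`, `treatment_depth`, `trait`, `value` and optionally
#'   `time`.
#' @inheritParams read_phenotypes
#' @return `df` with factor columns typed, classed `phenotype_table`.
#' @export
phenotype_table <- function(df,
                            depth_levels = c("shallow", "mesophotic"),
                            trait_levels = c("growth_mm", "necrosis_pct")) {
  required <- c("individual", "sample", "origin_depth", "treatment_depth",
                "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$value)) {
    v <- suppressWarnings(as.numeric(df$value))
    if (anyNA(v) && !all(is.na(df$value[is.na(v)])))
      stop("non-numeric trait value in phenotype table")
    df$value <- v
  }
  if (any(!is.finite(df$value))) stop("trait values must be finite")
  bad_lvl <- setdiff(unique(c(df$origin_depth, df$treatment_depth)), depth_levels)
  if (length(bad_lvl))
    stop("unknown depth level(s): ", paste(bad_lvl, collapse = ", "))
  bad_tr <- setdiff(unique(df$trait), trait_levels)
  if (length(bad_tr))
    stop("unknown trait(s): ", paste(bad_tr, collapse = ", "))
  nec <- df$trait == "necrosis_pct"
  if (any(df$value[nec] < 0 | df$value[nec] > 100))
    stop("necrosis_pct must lie in [0, 100]")
  key <- if ("time" %in% names(df))
    paste(df$individual, df$trait, df$time) else paste(df$individual, df$trait)
  if (anyDuplicated(key))
    stop("duplicate record for (individual, trait, time): ",
         key[anyDuplicated(key)])
  df$origin_depth <- factor(df$origin_depth, levels = depth_levels)
  df$treatment_depth <- factor(df$treatment_depth, levels = depth_levels)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table to CSV
#'
#' @param pheno a `phenotype_table`.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
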
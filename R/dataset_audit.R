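# Dataset-level audit: per-allele composition, sPC90 across populations,
# income-level grouping, and distributional significance tests.

#' Read a pHLA dataset
#'
#' Delimited text with a header and columns `peptide` and `allele` (or
#' `alleles`); optional `assay` (`BA`/`MS`) and `label`.  Multi-allelic
#' records list their candidate alleles separated by `;`, `,` or `/` (at most
#' six candidates).  Candidate alleles are canonicalized on read.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame with (at least) `peptide` and `alleles` columns.
#' @export
read_phla_dataset <- function(path, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  if (!"peptide" %in% names(tab)) stop("dataset lacks a 'peptide' column")
  if ("alleles" %in% names(tab)) al <- tab$alleles
  else if ("allele" %in% names(tab)) al <- tab$allele
  else stop("dataset lacks an 'allele'/'alleles' column")
  cand <- split_candidates(al)
  if (any(lengths(cand) < 1L | lengths(cand) > 6L)) {
    stop("records must carry between 1 and 6 candidate alleles")
  }
  tab$alleles <- vapply(cand, function(a) paste(canonicalize_allele(a), collapse = ";"),
                        character(1))
  tab$allele <- NULL
  if (any(!grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = "")), tab$peptide))) {
    stop("peptides must use the 20-letter amino-acid alphabet")
  }
  tab
}

split_candidates <- function(x) strsplit(as.character(x), "[;,/]\\s*")

is_mono_allelic <- function(dataset) {
  al <- dataset$alleles %||% dataset$allele
  lengths(split_candidates(al)) == 1L
}

# Unique mono-allelic (peptide, allele) pairs of a dataset.
dataset_pairs <- function(dataset) {
  al <- dataset$alleles %||% dataset$allele
  if (!all(is_mono_allelic(dataset))) {
    stop("dataset contains multi-allelic records; deconvolute() it first")
  }
  unique(data.frame(peptide = dataset$peptide, allele = al,
                    stringsAsFactors = FALSE))
}

#' Per-allele data-point counts
#'
#' Exact count of data points per allele in a mono-allelic dataset, sorted by
#' descending count (the long-tail view of dataset composition).
#'
#' @param dataset mono-allelic dataset (data.frame with `peptide` and
#'   `allele`/`alleles`).
#' @return data.frame of class `allele_counts` with columns `allele`, `count`
#'   (descending) and attribute `total` (= sum of counts = number of records).
#' @export
per_allele_counts <- function(dataset) {
  al <- dataset$alleles %||% dataset$allele
  if (length(al) && !all(is_mono_allelic(dataset))) {
    stop("dataset contains multi-allelic records; deconvolute() it first")
  }
  tb <- sort(table(al), decreasing = TRUE)
  out <- data.frame(allele = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$count)
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' @export
print.allele_counts <- function(x, n = 10L, ...) {
  cat("Per-allele counts:", nrow(x), "alleles,", attr(x, "total"), "data points\n")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more alleles\n")
  invisible(x)
}

#' Coverage audit of a dataset across all populations
#'
#' Computes [population_coverage()] for every population in a prepared
#' frequency table, returning one row per population.
#'
#' @param dataset mono-allelic dataset.
#' @param freq_table prepared frequency table (see
#'   [prepare_frequency_table()]), optionally income-annotated.
#' @inheritParams population_coverage
#' @return data.frame with columns `population`, `country`, `income_level`,
#'   `coverage`, `pc90`, `spc90`, `n`.
#' @export
audit_coverage <- function(dataset, freq_table, loci = c("A", "B", "C"),
                           q = 0.9, interpolate = FALSE, sum_tolerance = 1e-6) {
  pairs <- dataset_pairs(dataset)
  pops <- unique(freq_table$population)
  rows <- lapply(pops, function(pp) {
    pr <- freq_table[freq_table$population == pp, , drop = FALSE]
    cv <- population_coverage(pairs, pr, loci = loci, q = q,
                              interpolate = interpolate,
                              sum_tolerance = sum_tolerance)
    data.frame(population = pp,
               country = pr$country[1] %||% NA_character_,
               income_level = pr$income_level[1] %||% NA_character_,
               coverage = cv$coverage, pc90 = cv$pc90, spc90 = cv$spc90,
               n = cv$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA across groups
#'
#' Standard between/within mean-square F ratio with its upper-tail p-value
#' (via [stats::oneway.test()] assuming equal variances).  The degenerate case
#' of zero between-group variance returns F = 0, p = 1.
#'
#' @param groups named list of numeric vectors; at least two groups, each with
#'   at least two values.
#' @return list with `statistic` (F), `p.value`, and `df` (numerator,
#'   denominator).
#' @export
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("every group needs at least two values")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  v <- unlist(groups, use.names = FALSE)
  means <- tapply(v, g, mean)
  ssb <- sum(lengths(groups) * (means - mean(v))^2)
  if (ssb < .Machine$double.eps * sum(v^2 + 1)) {
    return(list(statistic = 0, p.value = 1,
                df = c(length(groups) - 1L, length(v) - length(groups))))
  }
  ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the signed ECDF difference in the requested
#' direction; the p-value uses the one-sided asymptotic tail
#' `exp(-2 m n D^2 / (m + n))`.  With `alternative = "less"` the test asks
#' whether `a` is stochastically smaller than `b` (its ECDF lies above), the
#' direction used for the income comparisons.  Samples smaller than 10 are
#' flagged (`small_sample`), as the asymptotic p-value is then unreliable.
#'
#' @param a,b numeric samples (nonempty).
#' @param alternative `"less"` (`a` stochastically below `b`) or `"greater"`.
#' @return list with `statistic` (D), `p.value`, `alternative`, `m`, `n`,
#'   `small_sample`.
#' @export
ks_one_sided <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  z <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(z)
  fb <- stats::ecdf(b)(z)
  d <- if (alternative == "less") max(c(0, fa - fb)) else max(c(0, fb - fa))
  m <- length(a); n <- length(b)
  p <- min(1, exp(-2 * m * n * d^2 / (m + n)))
  list(statistic = d, p.value = p, alternative = alternative,
       m = m, n = n, small_sample = min(m, n) < 10L)
}

#' Income-stratified statistics of sPC90 values
#'
#' Groups per-population sPC90 values by income level, runs a one-way ANOVA
#' across the levels, and a one-sided KS test for every ordered pair of
#' levels asking whether the lower-income group's sPC90 distribution is
#' stochastically smaller than the higher-income group's.  Pairwise p-values
#' are reported raw and Holm-adjusted.
#'
#' @param coverage per-population coverage results ([audit_coverage()] output)
#'   or any data.frame with the two columns named below.
#' @param value_col column holding the audited statistic (default `spc90`).
#' @param group_col column holding the income level.
#' @return object of class `income_group_stats`: list with `groups` (named
#'   list, ordered low to high), `anova`, and `ks` (data.frame with columns
#'   `lower`, `higher`, `D`, `p`, `p_holm`, `small_sample`).
#' @export
income_group_stats <- function(coverage, value_col = "spc90",
                               group_col = "income_level") {
  lv <- coverage[[group_col]]
  keep <- lv %in% INCOME_LEVELS
  groups <- split(coverage[[value_col]][keep],
                  factor(lv[keep], levels = INCOME_LEVELS))
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L) stop("need sPC90 values for at least two income levels")
  av <- anova_one_way(groups)
  cmb <- utils::combn(names(groups), 2L)
  ks_rows <- apply(cmb, 2L, function(pr) {
    kt <- ks_one_sided(groups[[pr[1]]], groups[[pr[2]]], "less")
    data.frame(lower = pr[1], higher = pr[2], D = kt$statistic, p = kt$p.value,
               small_sample = kt$small_sample, stringsAsFactors = FALSE)
  })
  ks <- do.call(rbind, ks_rows)
  ks$p_holm <- stats::p.adjust(ks$p, method = "holm")
  ks <- ks[, c("lower", "higher", "D", "p", "p_holm", "small_sample")]
  structure(list(groups = groups, anova = av, ks = ks),
            class = "income_group_stats")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.income_group_stats <- function(x, ...) {
  cat("sPC90 by income level:\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %-13s n=%3d  mean=%.4f\n", g, length(x$groups[[g]]),
                mean(x$groups[[g]])))
  }
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.3g %s\n",
              x$anova$statistic, x$anova$p.value, p_stars(x$anova$p.value)))
  cat("One-sided KS (lower income stochastically below higher):\n")
  ks <- x$ks
  ks$sig <- p_stars(ks$p_holm)
  print.data.frame(ks, row.names = FALSE, digits = 4)
  invisible(x)
}
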
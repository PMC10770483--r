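# Ingestion, canonicalization and validation of population allele-frequency
# tables (AFND-style), plus World Bank income classification of the
# populations' countries.

#' Canonicalize HLA allele names to two-field nomenclature
#'
#' Reduces class I HLA allele names to the two-field form `locus*group:protein`
#' (e.g. `A*01:01`), keeping the gene, the allele group and the specific
#' protein and truncating higher-resolution fields (synonymous and noncoding
#' variants).  An optional `HLA-` prefix and a missing `*` separator are
#' tolerated; numeric fields are zero-padded to two digits.
#'
#' @param x character vector of allele names.
#' @param loci allowed loci; names whose locus is not among these are rejected.
#' @return character vector of canonical allele names, same length as `x`.
#'   The function is idempotent: applying it to its own output is a no-op.
#' @examples
#' canonicalize_allele(c("HLA-A*01:01:01:01", "b*07:02", "C*05:01"))
#' @export
canonicalize_allele <- function(x, loci = c("A", "B", "C")) {
  x0 <- trimws(as.character(x))
  y <- sub("^HLA-", "", toupper(x0))
  m <- regmatches(y, regexec("^([A-Z]+)\\*?([0-9]{1,3}):([0-9]{1,3})", y))
  ok <- lengths(m) == 4L
  locus <- rep(NA_character_, length(y))
  locus[ok] <- vapply(m[ok], `[`, character(1), 2L)
  ok <- ok & locus %in% loci
  if (any(!ok)) {
    stopf("cannot canonicalize allele name(s): %s",
          paste(unique(x0[!ok]), collapse = ", "))
  }
  grp <- vapply(m, `[`, character(1), 3L)
  prt <- vapply(m, `[`, character(1), 4L)
  pad <- function(v) formatC(as.integer(v), width = 2, flag = "0")
  sprintf("%s*%s:%s", locus, pad(grp), pad(prt))
}

allele_locus <- function(allele) sub("\\*.*$", "", allele)

#' Read a population allele-frequency table
#'
#' Expects delimited text (TSV, or CSV for a `.csv` extension) with a header
#' and columns `population`, `allele`, `frequency`, plus optional `country`,
#' `locus` and `sample_size`.  Allele names are canonicalized on read and the
#' `locus` column is derived from them.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame with columns `population`, `country` (if present),
#'   `locus`, `allele`, `frequency` and `sample_size` (if present).
#' @seealso [prepare_frequency_table()] for the full cleaning pipeline.
#' @export
read_frequency_table <- function(path, sep = NULL) {
  tab <- read_delim_auto(path, sep)
  need <- c("population", "allele", "frequency")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("frequency table lacks column(s): %s", paste(miss, collapse = ", "))
  tab$allele <- canonicalize_allele(tab$allele)
  tab$locus <- allele_locus(tab$allele)
  tab$frequency <- as.numeric(tab$frequency)
  if (any(!is.finite(tab$frequency) | tab$frequency < 0 | tab$frequency > 1)) {
    stop("frequencies must be numeric in [0, 1]")
  }
  tab
}

#' Remove duplicate (population, allele) entries
#'
#' At most one row per (population, allele) pair is kept.  When duplicates
#' conflict, the row with the larger reported `sample_size` wins (rule
#' `"sample_size"`, the default); rows without a sample size, or under rule
#' `"first"`, fall back to first-in-file order.  Removed rows are attached as
#' the `"dedupe_log"` attribute so every removal is auditable.  Re-running the
#' function on its own output is a no-op.
#'
#' @param tab frequency table (data.frame with `population` and `allele`).
#' @param rule conflict-resolution rule, `"sample_size"` or `"first"`.
#' @return the deduplicated table, with attribute `dedupe_log` (a data.frame
#'   of the removed rows).
#' @export
dedupe_entries <- function(tab, rule = c("sample_size", "first")) {
  rule <- match.arg(rule)
  n <- nrow(tab)
  key <- paste(tab$population, tab$allele, sep = "\r")
  idx <- seq_len(n)
  if (rule == "sample_size" && "sample_size" %in% names(tab)) {
    pref <- suppressWarnings(as.numeric(tab$sample_size))
    pref[is.na(pref)] <- -Inf
    o <- order(key, -pref, idx)
  } else {
    o <- order(key, idx)
  }
  kept <- sort(o[!duplicated(key[o])])
  removed <- tab[setdiff(idx, kept), , drop = FALSE]
  out <- tab[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dedupe_log") <- removed
  out
}

#' Validate and normalize per-population, per-locus frequency sums
#'
#' A sanity check that allele frequencies per population and locus add up
#' to 1.  Sums within `tolerance` of 1 are repaired: proportionally rescaled
#' when `renormalize = TRUE`, or (when disabled and the sum falls short) the
#' deficit is assigned to a synthetic residual allele `<locus>*OTHER` that can
#' never match a dataset entry, preserving probability mass for the coverage
#' computation.  Sums outside the tolerance flag the (population, locus) pair
#' and its rows are excluded.  Every sum is listed in the `validation_report`
#' attribute.
#'
#' @param tab deduplicated frequency table.
#' @param tolerance maximum allowed deviation of a per-locus sum from 1.
#' @param renormalize proportionally rescale in-tolerance sums (default) or
#'   use the residual-allele rule for deficits.
#' @return the normalized table; attribute `validation_report` is a data.frame
#'   with columns `population`, `locus`, `sum`, `status` (one of `pass`,
#'   `renormalized`, `residual_added`, `excluded`).
#' @export
validate_frequencies <- function(tab, tolerance = 0.05, renormalize = TRUE) {
  key <- paste(tab$population, tab$locus, sep = "\r")
  groups <- split(seq_len(nrow(tab)), key)
  report <- vector("list", length(groups))
  keep <- rep(TRUE, nrow(tab))
  extra <- list()
  for (k in seq_along(groups)) {
    rows <- groups[[k]]
    s <- sum(tab$frequency[rows])
    pop <- tab$population[rows[1]]
    loc <- tab$locus[rows[1]]
    if (abs(s - 1) <= 1e-9) {
      status <- "pass"
    } else if (abs(s - 1) <= tolerance) {
      if (renormalize || s > 1) {
        f <- tab$frequency[rows] / s
        # pin the sum to exactly 1 by absorbing rounding into the largest entry
        f[which.max(f)] <- f[which.max(f)] + (1 - sum(f))
        tab$frequency[rows] <- f
        status <- "renormalized"
      } else {
        res <- tab[rows[1], , drop = FALSE]
        res$allele <- paste0(loc, "*OTHER")
        res$frequency <- 1 - s
        if ("sample_size" %in% names(res)) res$sample_size <- NA
        extra[[length(extra) + 1L]] <- res
        status <- "residual_added"
      }
    } else {
      keep[rows] <- FALSE
      status <- "excluded"
    }
    report[[k]] <- data.frame(population = pop, locus = loc, sum = s,
                              status = status, stringsAsFactors = FALSE)
  }
  out <- tab[keep, , drop = FALSE]
  if (length(extra)) out <- rbind(out, do.call(rbind, extra))
  rownames(out) <- NULL
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  attr(out, "validation_report") <- rep_df
  out
}

#' Keep only populations with data for every required locus
#'
#' @param tab validated frequency table.
#' @param loci loci every retained population must cover.
#' @return the filtered table.
#' @export
filter_complete_loci <- function(tab, loci = c("A", "B", "C")) {
  has <- tapply(tab$locus, tab$population, function(l) all(loci %in% l))
  keep_pops <- names(has)[has]
  out <- tab[tab$population %in% keep_pops, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clean a raw frequency table end to end
#'
#' Convenience pipeline: canonicalize allele names, deduplicate
#' (population, allele) pairs, validate per-locus sums, and drop populations
#' missing any required locus.  The dedupe and validation logs of the
#' intermediate steps are carried through as attributes.
#'
#' @inheritParams dedupe_entries
#' @inheritParams validate_frequencies
#' @inheritParams filter_complete_loci
#' @return cleaned table with attributes `dedupe_log` and `validation_report`.
#' @export
prepare_frequency_table <- function(tab, loci = c("A", "B", "C"),
                                    tolerance = 0.05, renormalize = TRUE,
                                    rule = c("sample_size", "first")) {
  tab$allele <- canonicalize_allele(tab$allele, loci = loci)
  tab$locus <- allele_locus(tab$allele)
  tab <- dedupe_entries(tab, rule = match.arg(rule))
  dlog <- attr(tab, "dedupe_log")
  tab <- validate_frequencies(tab, tolerance = tolerance, renormalize = renormalize)
  vrep <- attr(tab, "validation_report")
  tab <- filter_complete_loci(tab, loci = loci)
  attr(tab, "dedupe_log") <- dlog
  attr(tab, "validation_report") <- vrep
  tab
}

# ---------------------------------------------------------------------------
# Income classification (World Bank country and lending groups style)

INCOME_LEVELS <- c("low", "lower-middle", "upper-middle", "high")

#' World Bank style income-band ceilings
#'
#' GNI-per-capita ceilings (current US$) of the low, lower-middle and
#' upper-middle bands; anything above the last ceiling is high income.
#' Defaults are the 2022-2023 bands: low \eqn{\le} 1,085; lower-middle
#' 1,086-4,255; upper-middle 4,256-13,205; high above 13,205.
#'
#' @param low,lower_middle,upper_middle band ceilings, strictly increasing.
#' @return named numeric vector of class `income_thresholds`.
#' @export
income_thresholds <- function(low = 1085, lower_middle = 4255, upper_middle = 13205) {
  thr <- c(low = low, lower_middle = lower_middle, upper_middle = upper_middle)
  if (any(diff(thr) <= 0)) stop("income ceilings must be strictly increasing")
  structure(thr, class = "income_thresholds")
}

#' Map GNI per capita to an income level
#'
#' @param gni numeric GNI per capita values.
#' @param thresholds band ceilings, see [income_thresholds()].
#' @return character vector over `"low"`, `"lower-middle"`, `"upper-middle"`,
#'   `"high"`.  Bands are closed at their printed ceilings: a GNI equal to a
#'   ceiling belongs to the band below it.
#' @export
gni_to_income <- function(gni, thresholds = income_thresholds()) {
  as.character(cut(as.numeric(gni),
                   breaks = c(-Inf, unclass(thresholds), Inf),
                   labels = INCOME_LEVELS, right = TRUE))
}

#' Classify countries by national income level
#'
#' Deterministic lookup of each country in a classification table holding
#' either a precomputed `income_level` column or a `gni_per_capita` column
#' (converted through the band ceilings).  Countries absent from the table are
#' reported as `"unclassified"`, never silently defaulted.
#'
#' @param country character vector of country names.
#' @param income_table data.frame with column `country` and one of
#'   `income_level` or `gni_per_capita`.
#' @param thresholds band ceilings, see [income_thresholds()].
#' @return character vector of income levels (or `"unclassified"`).
#' @export
classify_income <- function(country, income_table, thresholds = income_thresholds()) {
  if (!"country" %in% names(income_table)) stop("income table lacks a 'country' column")
  if ("income_level" %in% names(income_table)) {
    lv <- as.character(income_table$income_level)
    bad <- !lv %in% INCOME_LEVELS
    if (any(bad)) stopf("unknown income level(s) in table: %s",
                        paste(unique(lv[bad]), collapse = ", "))
  } else if ("gni_per_capita" %in% names(income_table)) {
    lv <- gni_to_income(income_table$gni_per_capita, thresholds)
  } else {
    stop("income table needs an 'income_level' or 'gni_per_capita' column")
  }
  i <- match(tolower(trimws(country)), tolower(trimws(income_table$country)))
  out <- rep("unclassified", length(country))
  out[!is.na(i)] <- lv[i[!is.na(i)]]
  out
}

#' Extract country names from population labels
#'
#' AFND-style population labels embed the country (e.g. "USA Hispanic",
#' "Thailand North East").  Each label is matched case-insensitively against
#' the classification table's country names and the longest matching name
#' wins; an explicit `overrides` map (label -> country) takes precedence for
#' ambiguous labels.
#'
#' @param labels population labels.
#' @param countries known country names.
#' @param overrides optional named character vector, `names()` are labels.
#' @return character vector of countries, `NA` where no country matched.
#' @export
extract_country <- function(labels, countries, overrides = NULL) {
  res <- rep(NA_character_, length(labels))
  if (!is.null(overrides)) {
    i <- match(labels, names(overrides))
    res[!is.na(i)] <- unname(overrides[i[!is.na(i)]])
  }
  lab_low <- tolower(labels)
  for (cn in countries[order(-nchar(countries))]) {
    hit <- is.na(res) & grepl(tolower(cn), lab_low, fixed = TRUE)
    res[hit] <- cn
  }
  res
}

#' Annotate a frequency table with country and income level
#'
#' Fills the `country` column (from population labels if needed, via
#' [extract_country()]) and adds an `income_level` column via
#' [classify_income()].
#'
#' @param tab frequency table.
#' @param income_table country classification table, see [classify_income()].
#' @param thresholds band ceilings.
#' @param overrides optional label -> country overrides.
#' @return the table with `country` and `income_level` columns.
#' @export
annotate_income <- function(tab, income_table, thresholds = income_thresholds(),
                            overrides = NULL) {
  if (is.null(tab$country) || anyNA(tab$country)) {
    guess <- extract_country(tab$population, income_table$country, overrides)
    if (is.null(tab$country)) tab$country <- guess
    else tab$country[is.na(tab$country)] <- guess[is.na(tab$country)]
  }
  tab$income_level <- classify_income(tab$country, income_table, thresholds)
  tab
}
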
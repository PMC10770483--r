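# The two audit entry points tying the stages together, with provenance,
# machine-readable reports and plotting.

#' Audit the population representativeness of a pHLA dataset
#'
#' End-to-end data-bias audit: deconvolutes multi-allelic records if a
#' predictor is supplied, deduplicates to unique (peptide, allele) pairs,
#' tabulates per-allele counts, computes coverage / PC90 / sPC90 for every
#' population in the frequency table, and — when income levels are annotated —
#' the income-stratified ANOVA and one-sided KS statistics.
#'
#' @param dataset pHLA dataset (data.frame, see [read_phla_dataset()]).
#' @param freq_table prepared frequency table, optionally income-annotated.
#' @param predictor a [phla_predictor()]; required when the dataset contains
#'   multi-allelic records.
#' @param rank_cutoff deconvolution exclusion threshold (see [deconvolute()]).
#' @inheritParams audit_coverage
#' @return object of class `audit_data`: list with `counts`, `coverage`,
#'   `group_stats` (or `NULL`), `provenance`.
#' @export
run_audit_data <- function(dataset, freq_table, predictor = NULL,
                           rank_cutoff = 0.5, loci = c("A", "B", "C"),
                           q = 0.9, interpolate = FALSE) {
  if (!nrow(dataset)) stop("empty dataset")
  n_input <- nrow(dataset)
  deconv <- NULL
  if (!all(is_mono_allelic(dataset))) {
    if (is.null(predictor)) stop("multi-allelic records present: a predictor is required")
    dataset <- deconvolute(dataset, predictor, rank_cutoff = rank_cutoff)
    deconv <- list(n_excluded = attr(dataset, "n_excluded"),
                   n_flagged = nrow(attr(dataset, "flagged")))
  }
  counts <- per_allele_counts(dataset)
  coverage <- audit_coverage(dataset, freq_table, loci = loci, q = q,
                             interpolate = interpolate)
  gs <- NULL
  if (sum(unique(coverage$income_level) %in% INCOME_LEVELS) >= 2L) {
    gs <- tryCatch(income_group_stats(coverage), error = function(e) NULL)
  }
  structure(list(counts = counts, coverage = coverage, group_stats = gs,
                 provenance = list(stage = "audit-data", n_input = n_input,
                                   deconvolution = deconv,
                                   predictor = if (!is.null(predictor)) predictor$name,
                                   rank_cutoff = rank_cutoff, loci = loci, q = q,
                                   interpolate = interpolate,
                                   n_pairs = nrow(dataset_pairs(dataset)),
                                   n_populations = nrow(coverage))),
            class = "audit_data")
}

#' @export
print.audit_data <- function(x, ...) {
  pv <- x$provenance
  cat("pHLA data-bias audit:", pv$n_pairs, "unique pairs,",
      nrow(x$counts), "alleles,", pv$n_populations, "populations\n")
  if (!is.null(pv$deconvolution)) {
    cat("  deconvolution: ", pv$deconvolution$n_excluded, " excluded (rank >= ",
        pv$rank_cutoff, "), ", pv$deconvolution$n_flagged, " flagged\n", sep = "")
  }
  cat(sprintf("  sPC90: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$coverage$spc90), min(x$coverage$spc90), max(x$coverage$spc90)))
  if (!is.null(x$group_stats)) print(x$group_stats)
  invisible(x)
}

#' @method summary audit_data
#' @export
summary.audit_data <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Boxplots of sPC90 by income level
#'
#' @param x an `audit_data` object.
#' @param ... passed to [graphics::boxplot()].
#' @method plot audit_data
#' @export
plot.audit_data <- function(x, ...) {
  cv <- x$coverage[x$coverage$income_level %in% INCOME_LEVELS, , drop = FALSE]
  if (!nrow(cv)) stop("no income-annotated populations to plot")
  grp <- factor(cv$income_level, levels = INCOME_LEVELS)
  graphics::boxplot(cv$spc90 ~ grp, xlab = "income level", ylab = "sPC90",
                    main = "Population coverage by income level", ...)
  invisible(x)
}

#' Audit the per-allele accuracy of a predictor
#'
#' End-to-end model-bias audit: deconvolutes multi-allelic records, samples
#' proteome decoys for every peptide length found in the dataset, computes
#' per-allele PPV and FOOP, and annotates each allele with the income levels
#' of the populations expressing it the most.
#'
#' @param dataset pHLA dataset of true binders.
#' @param predictor a [phla_predictor()].
#' @param proteome decoy source (see [sample_decoys()]).
#' @param freq_table optional income-annotated frequency table used for the
#'   allele income annotation.
#' @param n_decoys decoys per peptide length (reference value 500,000).
#' @param seed decoy-sampling seed.
#' @param foop_threshold FOOP percentile-rank threshold in percent.
#' @param rank_cutoff deconvolution exclusion threshold.
#' @param min_binders smallest per-allele binder count to evaluate.
#' @return object of class `audit_model`: list with `eval` (per-allele table,
#'   income columns appended when available) and `provenance`.
#' @export
run_audit_model <- function(dataset, predictor, proteome, freq_table = NULL,
                            n_decoys = 500000L, seed = NULL,
                            foop_threshold = 0.1, rank_cutoff = 0.5,
                            min_binders = 1L) {
  if (!nrow(dataset)) stop("empty dataset")
  n_input <- nrow(dataset)
  if (!all(is_mono_allelic(dataset))) {
    dataset <- deconvolute(dataset, predictor, rank_cutoff = rank_cutoff)
  }
  lens <- sort(unique(nchar(dataset_pairs(dataset)$peptide)))
  decoys <- lapply(seq_along(lens), function(i) {
    sample_decoys(proteome, lens[i], n = n_decoys,
                  seed = if (is.null(seed)) NULL else seed + i)
  })
  names(decoys) <- lens
  ev <- evaluate_predictor(dataset, predictor, decoys,
                           foop_threshold = foop_threshold,
                           min_binders = min_binders)
  if (!is.null(freq_table) && "income_level" %in% names(freq_table)) {
    ann <- allele_income_annotation(freq_table)
    ev <- merge(ev, ann, by = "allele", all.x = TRUE, sort = FALSE)
    class(ev) <- c("predictor_eval", "data.frame")
    attr(ev, "foop_threshold") <- foop_threshold
  }
  structure(list(eval = ev,
                 provenance = list(stage = "audit-model", n_input = n_input,
                                   predictor = predictor$name,
                                   n_decoys_per_length = n_decoys,
                                   lengths = lens, seed = seed,
                                   foop_threshold = foop_threshold,
                                   rank_cutoff = rank_cutoff)),
            class = "audit_model")
}

#' Income levels of the populations expressing each allele the most
#'
#' For every allele, finds the population with the highest frequency within
#' each income level, and the income level of the globally top-expressing
#' population.
#'
#' @param freq_table income-annotated frequency table.
#' @return data.frame with columns `allele`, `top_population`, `top_income`,
#'   and `max_freq_<level>` per income level.
#' @export
allele_income_annotation <- function(freq_table) {
  sp <- split(freq_table, freq_table$allele)
  rows <- lapply(sp, function(r) {
    top <- r[which.max(r$frequency), ]
    out <- data.frame(allele = top$allele, top_population = top$population,
                      top_income = top$income_level, stringsAsFactors = FALSE)
    for (lev in INCOME_LEVELS) {
      f <- r$frequency[r$income_level == lev]
      out[[paste0("max_freq_", gsub("-", "_", lev))]] <-
        if (length(f)) max(f) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.audit_model <- function(x, ...) {
  pv <- x$provenance
  cat("pHLA model-bias audit:", pv$predictor, "|", nrow(x$eval), "alleles |",
      pv$n_decoys_per_length, "decoys per length (",
      paste(pv$lengths, collapse = ","), ")\n")
  cat(sprintf("  PPV:  mean %.3f, range [%.3f, %.3f]\n",
              mean(x$eval$ppv), min(x$eval$ppv), max(x$eval$ppv)))
  cat(sprintf("  FOOP: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$eval$foop), min(x$eval$foop), max(x$eval$foop)))
  invisible(x)
}

#' @method summary audit_model
#' @export
summary.audit_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Per-allele PPV and FOOP profile plot
#'
#' @param x an `audit_model` object.
#' @param ... ignored.
#' @method plot audit_model
#' @export
plot.audit_model <- function(x, ...) {
  ev <- x$eval[order(x$eval$allele), ]
  old <- graphics::par(mfrow = c(2, 1), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  for (metric in c("ppv", "foop")) {
    graphics::plot(seq_len(nrow(ev)), ev[[metric]], xaxt = "n", xlab = "",
                   ylab = toupper(metric), ylim = c(0, 1), pch = 19)
    graphics::axis(1, at = seq_len(nrow(ev)), labels = ev$allele, las = 2,
                   cex.axis = 0.7)
  }
  invisible(x)
}

#' Write an audit report as JSON
#'
#' Machine-readable report containing the numeric sections and the
#' provenance needed to reproduce them.
#'
#' @param audit an `audit_data` or `audit_model` object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_audit_report <- function(audit, path) {
  to_plain <- function(x) {
    if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass)))
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  body <- if (inherits(audit, "audit_data")) {
    list(kind = "audit_data",
         counts = as.data.frame(audit$counts),
         coverage = audit$coverage,
         group_stats = if (!is.null(audit$group_stats)) {
           list(anova = audit$group_stats$anova, ks = audit$group_stats$ks)
         },
         provenance = audit$provenance)
  } else if (inherits(audit, "audit_model")) {
    list(kind = "audit_model", eval = as.data.frame(audit$eval),
         provenance = audit$provenance)
  } else stop("not an audit object")
  jsonlite::write_json(to_plain(body), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
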
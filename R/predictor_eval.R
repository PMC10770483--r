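# Per-allele evaluation of pHLA binding predictors: predictor adapter
# contract, multi-allelic deconvolution, proteome decoy sampling, and the
# PPV / FOOP accuracy metrics.

#' Wrap a scoring function as a predictor adapter
#'
#' The adapter contract: given equal-length vectors of peptides and alleles,
#' return a data.frame with numeric columns `strength` (higher = stronger
#' binding) and `percentile_rank` (lower = stronger, in percent, in
#' \eqn{[0, 100]}), deterministic for fixed inputs.  `NA` entries signal a
#' prediction failure for that pair and cause the affected records to be
#' flagged downstream rather than silently dropped.
#'
#' @param fun `function(peptide, allele)` returning the data.frame above.
#' @param name label used in printing and provenance.
#' @return object of class `phla_predictor`.
#' @seealso [predict_phla()], [table_predictor()], [mock_predictor()]
#' @export
phla_predictor <- function(fun, name = "predictor") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, name = name), class = "phla_predictor")
}

#' @export
print.phla_predictor <- function(x, ...) {
  cat("<phla_predictor:", x$name, ">\n")
  invisible(x)
}

#' Score peptide-allele pairs through a predictor adapter
#'
#' Calls the adapter and validates its output against the contract.
#'
#' @param predictor a [phla_predictor()].
#' @param peptide,allele equal-length character vectors.
#' @return data.frame with columns `peptide`, `allele`, `strength`,
#'   `percentile_rank`.
#' @export
predict_phla <- function(predictor, peptide, allele) {
  stopifnot(inherits(predictor, "phla_predictor"))
  if (length(peptide) != length(allele)) stop("peptide and allele lengths differ")
  out <- predictor$fun(as.character(peptide), as.character(allele))
  if (!is.data.frame(out) || !all(c("strength", "percentile_rank") %in% names(out))) {
    stopf("predictor '%s' violated the adapter contract (need columns strength, percentile_rank)",
          predictor$name)
  }
  if (nrow(out) != length(peptide)) {
    stopf("predictor '%s' returned %d rows for %d pairs", predictor$name,
          nrow(out), length(peptide))
  }
  rk <- out$percentile_rank
  if (any(rk < 0 | rk > 100, na.rm = TRUE)) {
    stopf("predictor '%s' returned percentile ranks outside [0, 100]", predictor$name)
  }
  data.frame(peptide = as.character(peptide), allele = as.character(allele),
             strength = as.numeric(out$strength),
             percentile_rank = as.numeric(rk), stringsAsFactors = FALSE)
}

#' Predictor adapter backed by a table of precomputed scores
#'
#' File/table contract for external tools: score (peptide, allele) pairs
#' offline, write them as delimited text with columns `peptide`, `allele`,
#' `strength`, `percentile_rank`, and plug the table in.  Pairs absent from
#' the table come back as `NA` (a flagged prediction failure).
#'
#' @param scores data.frame with the four columns above, or a path to a
#'   delimited text file holding them.
#' @param name adapter label.
#' @return a [phla_predictor()].
#' @export
table_predictor <- function(scores, name = "table") {
  if (is.character(scores)) scores <- read_delim_auto(scores)
  need <- c("peptide", "allele", "strength", "percentile_rank")
  if (!all(need %in% names(scores))) {
    stopf("score table lacks column(s): %s",
          paste(setdiff(need, names(scores)), collapse = ", "))
  }
  key <- paste(scores$peptide, scores$allele, sep = "\r")
  phla_predictor(function(peptide, allele) {
    i <- match(paste(peptide, allele, sep = "\r"), key)
    data.frame(strength = scores$strength[i],
               percentile_rank = scores$percentile_rank[i])
  }, name = name)
}

#' Deconvolute multi-allelic records to mono-allelic pairs
#'
#' Each record's peptide is assigned to the candidate allele with the
#' strongest predicted binding — operationalized as the lowest percentile
#' rank, ties broken by the higher strength.  Records whose best rank is
#' greater than or equal to `rank_cutoff` are excluded as likely
#' non-binders (the cutoff is inclusive).  Records for which the predictor
#' failed on any candidate are flagged and set aside, never silently dropped.
#'
#' @param dataset data.frame with `peptide` and `alleles` (candidates joined
#'   by `;`) or `allele`; other columns are carried through.
#' @param predictor a [phla_predictor()].
#' @param rank_cutoff percentile-rank exclusion threshold (default 0.5,
#'   i.e. %rank >= 0.5 excluded).
#' @return mono-allelic data.frame with columns `peptide`, `allele`,
#'   `percentile_rank`, `strength` plus carried-through columns.  Attributes:
#'   `n_input`, `n_excluded` (rank filter), `excluded` (their best-candidate
#'   rows), `flagged` (records with predictor failures).
#' @export
deconvolute <- function(dataset, predictor, rank_cutoff = 0.5) {
  al <- dataset$alleles %||% dataset$allele
  cand <- split_candidates(al)
  if (any(lengths(cand) < 1L)) stop("every record needs at least one candidate allele")
  rec <- rep(seq_len(nrow(dataset)), lengths(cand))
  sc <- predict_phla(predictor, dataset$peptide[rec], unlist(cand))
  failed <- !is.finite(sc$strength) | !is.finite(sc$percentile_rank)
  flagged_rec <- unique(rec[failed])
  ok <- !(rec %in% flagged_rec)
  o <- order(rec[ok], sc$percentile_rank[ok], -sc$strength[ok])
  best <- o[!duplicated(rec[ok][o])]
  best_rec <- rec[ok][best]
  best_sc <- sc[ok, , drop = FALSE][best, , drop = FALSE]
  keep_cols <- setdiff(names(dataset), c("alleles", "allele"))
  out <- cbind(best_sc[, c("peptide", "allele", "percentile_rank", "strength")],
               dataset[best_rec, keep_cols, drop = FALSE])
  pass <- out$percentile_rank < rank_cutoff
  res <- out[pass, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_input") <- nrow(dataset)
  attr(res, "n_excluded") <- sum(!pass)
  attr(res, "excluded") <- out[!pass, , drop = FALSE]
  attr(res, "flagged") <- dataset[flagged_rec, , drop = FALSE]
  res
}

#' Sample proteome decoys of one peptide length
#'
#' Draws `n` length-`length` substrings uniformly over all valid
#' (sequence, offset) positions of the proteome, with replacement.  Sequences
#' containing residues outside the 20-letter alphabet are skipped.
#'
#' @param proteome a `Biostrings::AAStringSet`, a named character vector of
#'   protein sequences, or a FASTA file path.
#' @param length peptide length (the audited datasets use 8-11).
#' @param n number of decoys (the reference evaluation uses 500,000 per
#'   length).
#' @param seed RNG seed for reproducibility.
#' @param exclude optional peptides (e.g. the binder set) that may not appear
#'   among the decoys; matching draws are resampled.  By default decoys are
#'   not filtered against the binders.
#' @return character vector of `n` decoy peptides, with attributes `length`
#'   and `seed`.
#' @export
sample_decoys <- function(proteome, length, n = 500000, seed = NULL,
                          exclude = NULL) {
  if (n < 1) stop("need at least one decoy")
  seqs <- as_protein_strings(proteome)
  std <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = "")), seqs)
  seqs <- seqs[std]
  w <- nchar(seqs) - length + 1L
  seqs <- seqs[w > 0L]
  w <- w[w > 0L]
  if (!length(seqs)) stopf("no proteome sequence of length >= %d", length)
  with_seed(seed, {
    draw <- function(k) {
      si <- sample.int(length(seqs), k, replace = TRUE, prob = w)
      off <- floor(stats::runif(k) * w[si]) + 1L
      substring(seqs[si], off, off + length - 1L)
    }
    out <- draw(n)
    if (!is.null(exclude)) {
      for (i in 1:100) {
        bad <- out %in% exclude
        if (!any(bad)) break
        out[bad] <- draw(sum(bad))
      }
      if (any(out %in% exclude)) stop("could not sample decoys outside the excluded set")
    }
    attr(out, "length") <- as.integer(length)
    attr(out, "seed") <- seed
    out
  })
}

as_protein_strings <- function(proteome) {
  if (inherits(proteome, "AAStringSet")) return(as.character(proteome))
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    return(as.character(Biostrings::readAAStringSet(proteome)))
  }
  as.character(proteome)
}

#' Write decoys to FASTA with their sampling seed recorded
#'
#' @param decoys output of [sample_decoys()].
#' @param path FASTA file path.
#' @export
write_decoys_fasta <- function(decoys, path) {
  x <- Biostrings::AAStringSet(as.character(decoys))
  names(x) <- sprintf("decoy_%d len=%s seed=%s", seq_along(x),
                      attr(decoys, "length") %||% nchar(decoys[1]),
                      attr(decoys, "seed") %||% "NA")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Percentile rank of strengths against a decoy score set
#'
#' Rank of a prediction among `d` decoy predictions, in percent:
#' `100 * (# decoys scoring >= strength) / d`.  Ties with decoys count
#' against the query (conservative).
#'
#' @param strength numeric strengths to rank.
#' @param decoy_strength numeric decoy strengths.
#' @return numeric percentile ranks in `[0, 100]`.
#' @export
percentile_rank <- function(strength, decoy_strength) {
  d <- sort(as.numeric(decoy_strength))
  n_less <- findInterval(as.numeric(strength), d, left.open = TRUE)
  100 * (length(d) - n_less) / length(d)
}

#' Positive predictive value for one allele
#'
#' Binder and decoy predictions are pooled and ranked from strong to weak
#' binding; PPV is the fraction of true binders among the top `n_a`
#' predictions, where `n_a` is the number of binders.  At tied scores decoys
#' are ranked ahead of binders, so ties can only lower PPV.
#'
#' @param binder_scores numeric strengths of the allele's true binders
#'   (`n_a >= 1`).
#' @param decoy_scores numeric strengths of the decoys (nonempty), scored by
#'   the same predictor against the same allele.
#' @return PPV in `[0, 1]`.
#' @export
ppv_per_allele <- function(binder_scores, decoy_scores) {
  nb <- length(binder_scores)
  if (nb < 1L) stop("need at least one binder")
  if (!length(decoy_scores)) stop("need at least one decoy")
  is_binder <- rep(c(TRUE, FALSE), c(nb, length(decoy_scores)))
  sc <- c(as.numeric(binder_scores), as.numeric(decoy_scores))
  o <- order(-sc, is_binder)  # decoys first on ties
  mean(is_binder[o][seq_len(nb)])
}

#' Fraction of observed peptides for one allele
#'
#' Fraction of the allele's true binders whose percentile rank against the
#' decoys is at or below `threshold` percent.  With the reference 500,000
#' decoys and the default 0.1% threshold, a binder is counted exactly when it
#' outranks all but at most 500 decoys.
#'
#' @inheritParams ppv_per_allele
#' @param threshold percentile-rank threshold in percent (default 0.1).
#' @return FOOP in `[0, 1]`.
#' @export
foop_per_allele <- function(binder_scores, decoy_scores, threshold = 0.1) {
  if (!length(binder_scores)) stop("need at least one binder")
  if (!length(decoy_scores)) stop("need at least one decoy")
  mean(percentile_rank(binder_scores, decoy_scores) <= threshold)
}

#' Per-allele PPV and FOOP of a predictor on a dataset
#'
#' For every allele with at least `min_binders` binders: scores the binders
#' and the decoys against the allele, then computes PPV (decoys pooled across
#' lengths) and FOOP (each binder ranked within the decoys of its own
#' length).
#'
#' @param dataset mono-allelic dataset of true binders (deconvoluted).
#' @param predictor a [phla_predictor()].
#' @param decoys named list of decoy peptide vectors, one per length
#'   (names are the lengths), e.g. from [sample_decoys()]; or a single
#'   character vector used for all lengths.
#' @param foop_threshold percentile-rank threshold for FOOP, in percent.
#' @param min_binders smallest per-allele binder count to evaluate.
#' @return data.frame of class `predictor_eval`: columns `allele`, `n`,
#'   `ppv`, `foop`, `n_decoys`; attribute `foop_threshold`.
#' @export
evaluate_predictor <- function(dataset, predictor, decoys, foop_threshold = 0.1,
                               min_binders = 1L) {
  pairs <- dataset_pairs(dataset)
  if (!is.list(decoys)) decoys <- stats::setNames(list(as.character(decoys)), "all")
  alleles <- names(sort(table(pairs$allele), decreasing = TRUE))
  rows <- list()
  for (a in alleles) {
    peps <- pairs$peptide[pairs$allele == a]
    if (length(peps) < min_binders) next
    bsc <- predict_phla(predictor, peps, rep(a, length(peps)))$strength
    dsc <- lapply(decoys, function(dp) {
      predict_phla(predictor, dp, rep(a, length(dp)))$strength
    })
    pooled <- unlist(dsc, use.names = FALSE)
    ppv <- ppv_per_allele(bsc, pooled)
    # FOOP: rank each binder within the decoys of its own length
    if (identical(names(decoys), "all")) {
      foop <- foop_per_allele(bsc, pooled, foop_threshold)
    } else {
      len <- as.character(nchar(peps))
      if (!all(len %in% names(decoys))) {
        stopf("no decoys for binder length(s) %s of allele %s",
              paste(setdiff(unique(len), names(decoys)), collapse = ", "), a)
      }
      counted <- vapply(seq_along(peps), function(i) {
        percentile_rank(bsc[i], dsc[[len[i]]]) <= foop_threshold
      }, logical(1))
      foop <- mean(counted)
    }
    rows[[a]] <- data.frame(allele = a, n = length(peps), ppv = ppv,
                            foop = foop, n_decoys = length(pooled),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no allele reached the minimum binder count")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "foop_threshold") <- foop_threshold
  class(out) <- c("predictor_eval", "data.frame")
  out
}

#' @export
print.predictor_eval <- function(x, ...) {
  cat("Per-allele predictor evaluation (", nrow(x), " alleles, FOOP threshold ",
      attr(x, "foop_threshold"), "%):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
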
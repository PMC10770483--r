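# Synthetic inputs for the audit pipeline: AFND-style frequency tables with a
# controllable income gradient, long-tailed pHLA datasets with controllable
# income-correlated allele bias, random proteomes, and a deterministic mock
# predictor with controllable per-allele accuracy.

#' Scenario specification for the synthetic generators
#'
#' One object holds every knob of the simulated study: population structure,
#' allele pool, dataset composition and the bias controls.
#'
#' @param populations_per_level populations simulated per income level.
#' @param alleles_per_locus alleles per locus (A, B, C).
#' @param loci loci simulated.
#' @param concentration symmetric-Dirichlet concentration of the allele
#'   frequency draws (smaller = more skewed, HLA-like frequency spectra).
#' @param within_concentration concentration of populations around their
#'   income level's frequency profile when `income_gradient > 0` (larger =
#'   tighter clustering).
#' @param income_gradient strength in `[0, 1]` of the frequency gradient
#'   across income levels; 0 draws every population i.i.d. from the symmetric
#'   Dirichlet (no income signal).
#' @param dataset_size number of pHLA records to generate.
#' @param bias overrepresentation exponent \eqn{\beta \ge 1}: dataset alleles
#'   are sampled with weight (mean frequency among high-income
#'   populations)^\eqn{\beta}; 1 = proportional, larger = stronger skew
#'   toward high-income-common alleles.
#' @param multi_allelic_fraction fraction of records carrying 2-6 candidate
#'   alleles.
#' @param ba_fraction fraction of mono-allelic records labelled as
#'   binding-affinity (`BA`) assays; the rest are `MS`.
#' @param peptide_lengths lengths of generated peptides.
#' @param seed master seed; all generators derive from it.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(populations_per_level = 8L, alleles_per_locus = 12L,
                          loci = c("A", "B", "C"), concentration = 0.5,
                          within_concentration = 50, income_gradient = 1,
                          dataset_size = 2000L, bias = 1,
                          multi_allelic_fraction = 0.3, ba_fraction = 0.3,
                          peptide_lengths = 8:11, seed = 1L) {
  stopifnot(populations_per_level >= 1, alleles_per_locus >= 1,
            concentration > 0, within_concentration > 0,
            income_gradient >= 0, income_gradient <= 1,
            dataset_size >= 1, bias >= 1,
            multi_allelic_fraction >= 0, multi_allelic_fraction <= 1,
            ba_fraction >= 0, ba_fraction <= 1)
  structure(list(populations_per_level = as.integer(populations_per_level),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 loci = loci, concentration = concentration,
                 within_concentration = within_concentration,
                 income_gradient = income_gradient,
                 dataset_size = as.integer(dataset_size), bias = bias,
                 multi_allelic_fraction = multi_allelic_fraction,
                 ba_fraction = ba_fraction,
                 peptide_lengths = as.integer(peptide_lengths),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Synthetic scenario:", 4 * x$populations_per_level, "populations,",
      length(x$loci) * x$alleles_per_locus, "alleles,",
      x$dataset_size, "records, bias beta =", x$bias,
      ", seed =", x$seed, "\n")
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Exact renormalization: absorb the floating-point residue into the largest
# entry, iterating until the sum is exactly 1 in double precision.
exact_simplex <- function(f) {
  f <- f / sum(f)
  for (i in 1:5) {
    r <- 1 - sum(f)
    if (r == 0) break
    f[which.max(f)] <- f[which.max(f)] + r
  }
  f
}

#' Generate an AFND-style allele-frequency table
#'
#' Each population gets a frequency vector per locus that sums exactly to 1,
#' with country and income annotations attached.  With `income_gradient = 0`
#' every population draws i.i.d. from a symmetric Dirichlet.  Otherwise two
#' archetype frequency profiles are drawn per locus and income levels
#' interpolate between them (high income sits on one archetype, low income
#' `income_gradient` of the way toward the other), with populations scattered
#' around their level's profile; this is what gives dataset bias toward
#' high-income-common alleles a graded footprint across income levels.
#'
#' @param spec a [scenario_spec()].
#' @return frequency table data.frame (`population`, `country`,
#'   `income_level`, `locus`, `allele`, `frequency`, `sample_size`),
#'   bit-reproducible under `spec$seed`.
#' @export
gen_frequency_table <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- spec$alleles_per_locus
  alleles <- lapply(spec$loci, function(l) sprintf("%s*%02d:01", l, seq_len(k)))
  names(alleles) <- spec$loci
  w_level <- stats::setNames(c(0, 1 / 3, 2 / 3, 1), INCOME_LEVELS)
  with_seed(spec$seed, {
    rows <- list()
    arch <- lapply(spec$loci, function(l) {
      list(high = rdirichlet1(rep(spec$concentration, k)),
           low = rdirichlet1(rep(spec$concentration, k)))
    })
    names(arch) <- spec$loci
    for (lev in INCOME_LEVELS) {
      for (i in seq_len(spec$populations_per_level)) {
        pretty <- c(low = "Low", `lower-middle` = "Lower Middle",
                    `upper-middle` = "Upper Middle", high = "High")[[lev]]
        country <- sprintf("%s Country %d", pretty, i)
        pop <- paste(country, "pop")
        for (l in spec$loci) {
          if (spec$income_gradient == 0) {
            f <- rdirichlet1(rep(spec$concentration, k))
          } else {
            mix <- spec$income_gradient * (1 - w_level[[lev]])
            base <- (1 - mix) * arch[[l]]$high + mix * arch[[l]]$low
            f <- rdirichlet1(spec$within_concentration * k * base)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            population = pop, country = country, income_level = lev,
            locus = l, allele = alleles[[l]], frequency = exact_simplex(f),
            sample_size = 100L, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

random_peptides <- function(n, lengths) {
  out <- character(n)
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    if (!length(idx)) next
    m <- matrix(sample(AA_ALPHABET20, length(idx) * L, replace = TRUE),
                nrow = length(idx))
    out[idx] <- apply(m, 1L, paste, collapse = "")
  }
  out
}

#' Generate a pHLA dataset with income-correlated allele bias
#'
#' Records sample their true allele with weight proportional to the allele's
#' mean frequency among high-income populations raised to the bias exponent
#' \eqn{\beta}.  At \eqn{\beta = 1} the composition follows the pooled
#' high-income frequencies; larger \eqn{\beta} concentrates data points on
#' the alleles most common in high-income populations, producing the
#' long-tailed per-allele count profile of real training sets.  The
#' configured fraction of records is multi-allelic, carrying the true allele
#' plus 1-5 distractor candidates.
#'
#' @param spec a [scenario_spec()].
#' @param freq_table output of [gen_frequency_table()].
#' @return data.frame with columns `peptide`, `alleles` (`;`-joined
#'   candidates), `assay`, `true_allele`; attribute `true_counts` holds the
#'   generator's own per-allele tally of true alleles (an oracle for
#'   downstream counting), and `weights` the sampling weights used.
#' @export
gen_phla_dataset <- function(spec, freq_table) {
  stopifnot(inherits(spec, "scenario_spec"))
  high <- freq_table[freq_table$income_level == "high", , drop = FALSE]
  ref <- if (nrow(high)) high else freq_table
  mf <- tapply(ref$frequency, ref$allele, mean)
  all_alleles <- sort(unique(freq_table$allele))
  m <- stats::setNames(rep(0, length(all_alleles)), all_alleles)
  m[names(mf)] <- mf
  w <- m^spec$bias
  w <- w / sum(w)
  n <- spec$dataset_size
  with_seed(spec$seed + 1L, {
    true_allele <- sample(all_alleles, n, replace = TRUE, prob = w)
    len <- sample(spec$peptide_lengths, n, replace = TRUE)
    peptide <- random_peptides(n, len)
    multi <- stats::runif(n) < spec$multi_allelic_fraction
    cands <- true_allele
    if (any(multi)) {
      cands[multi] <- vapply(which(multi), function(i) {
        extra <- sample(setdiff(all_alleles, true_allele[i]),
                        sample(1:5, 1L), replace = FALSE)
        paste(sample(c(true_allele[i], extra)), collapse = ";")
      }, character(1))
    }
    assay <- ifelse(multi, "MS",
                    ifelse(stats::runif(n) < spec$ba_fraction, "BA", "MS"))
    out <- data.frame(peptide = peptide, alleles = cands, assay = assay,
                      true_allele = true_allele, stringsAsFactors = FALSE)
    tc <- table(factor(true_allele, levels = all_alleles))
    attr(out, "true_counts") <- tc[tc > 0]
    attr(out, "weights") <- w
    out
  })
}

#' Generate a random proteome
#'
#' Random amino-acid sequences over the 20-letter alphabet, standing in for
#' the human proteome as the decoy source.  Composition is i.i.d. uniform —
#' no realistic residue usage is attempted.
#'
#' @param total_length total residues across all sequences (at least 11, so
#'   every audited peptide length has a window).
#' @param n_sequences number of protein sequences to split the residues into.
#' @param seed RNG seed.
#' @return a `Biostrings::AAStringSet`, reproducible under `seed`.
#' @export
gen_proteome <- function(total_length = 50000L, n_sequences = 25L, seed = NULL) {
  if (total_length < 11) stop("total_length must be at least 11")
  n_sequences <- max(1L, min(as.integer(n_sequences), total_length %/% 11L))
  base <- total_length %/% n_sequences
  lens <- rep(base, n_sequences)
  lens[n_sequences] <- lens[n_sequences] + total_length - sum(lens)
  with_seed(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
    }, character(1))
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- sprintf("synthetic_protein_%d", seq_along(x))
    x
  })
}

#' Deterministic mock predictor with controllable per-allele accuracy
#'
#' Scores are standard-normal deviates derived by hashing
#' (peptide, allele, seed), so every (peptide, allele) pair gets the same
#' score in any call order and batch composition.  A pair listed as a true
#' binder of allele `a` gets its score shifted by the separation `d_a`
#' (`separation[a]`, 0 for alleles without an entry), so `d_a = 0` makes
#' binders and decoys exchangeable and large `d_a` makes the allele perfectly
#' predicted.  Percentile ranks are computed against the frozen
#' standard-normal decoy reference: `rank = 100 * (1 - Phi(strength))`, which
#' keeps strength and rank strictly consistently ordered.
#'
#' @param separation named numeric vector of per-allele separations
#'   `d_a >= 0`.
#' @param binders data.frame with `peptide` and `allele`/`alleles`
#'   (mono-allelic) or `true_allele` listing the true binder pairs, or `NULL`
#'   for a pure-noise predictor.
#' @param seed integer folded into the hash; different seeds give independent
#'   score universes.
#' @return a [phla_predictor()].
#' @export
mock_predictor <- function(separation = numeric(0), binders = NULL, seed = 0L) {
  if (length(separation) && (is.null(names(separation)) || any(separation < 0))) {
    stop("separation must be a named vector with d_a >= 0")
  }
  bkeys <- character(0)
  if (!is.null(binders)) {
    ba <- binders$true_allele %||% binders$alleles %||% binders$allele
    if (any(grepl("[;,/]", ba))) stop("binder set must be mono-allelic")
    bkeys <- unique(paste(binders$peptide, ba, sep = "|"))
  }
  seed <- as.integer(seed)
  phla_predictor(function(peptide, allele) {
    u <- str_hash_uniform(paste(peptide, allele, seed, sep = "|"))
    z <- stats::qnorm(u)
    d <- unname(separation[allele])
    d[is.na(d)] <- 0
    strength <- z + d * (paste(peptide, allele, sep = "|") %in% bkeys)
    data.frame(strength = strength,
               percentile_rank = 100 * stats::pnorm(strength, lower.tail = FALSE))
  }, name = sprintf("mock(seed=%d)", seed))
}

#' Per-allele separations that grow with training-data abundance
#'
#' Convenience map for bias scenarios:
#' `d_a = d_min + (d_max - d_min) * sqrt(count_a / max count)`.  The floor
#' `d_min` reflects that real predictors separate true binders from decoys
#' reasonably well even for sparsely covered alleles (most eluted ligands
#' survive the deconvolution rank filter); the abundance-linked increment on
#' top of it emulates accuracy that tracks training data.
#'
#' @param counts named per-allele counts (e.g. `attr(dataset, "true_counts")`
#'   or a [per_allele_counts()] result).
#' @param d_max separation of the most abundant allele.
#' @param d_min baseline separation of a barely covered allele.
#' @return named numeric vector of separations.
#' @export
separation_from_counts <- function(counts, d_max = 6, d_min = 3) {
  if (inherits(counts, "allele_counts")) {
    counts <- stats::setNames(counts$count, counts$allele)
  }
  stopifnot(d_max >= d_min, d_min >= 0)
  cnt <- as.numeric(counts)
  stats::setNames(d_min + (d_max - d_min) * sqrt(cnt / max(cnt)), names(counts))
}

#' Generate every pipeline input for a scenario
#'
#' One call produces the four artifacts the audits need: frequency table,
#' pHLA dataset, proteome, and a mock predictor whose per-allele separation
#' grows with each allele's data abundance (the synthetic analogue of
#' training-data-driven accuracy).  Optionally writes them to a directory as
#' delimited text / FASTA / JSON.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional directory to write the artifacts into.
#' @param d_max,d_min separation of the best- and barely-covered alleles (see
#'   [separation_from_counts()]).
#' @param proteome_length total proteome residues.
#' @return list with `spec`, `freq_table`, `dataset`, `proteome`,
#'   `predictor`, `separation`.
#' @export
simulate_scenario <- function(spec = scenario_spec(), out_dir = NULL, d_max = 6,
                              d_min = 3, proteome_length = 50000L) {
  ft <- gen_frequency_table(spec)
  ds <- gen_phla_dataset(spec, ft)
  prot <- gen_proteome(proteome_length, seed = spec$seed + 2L)
  sep <- separation_from_counts(attr(ds, "true_counts"), d_max = d_max,
                                d_min = d_min)
  pred <- mock_predictor(sep, binders = ds, seed = spec$seed + 3L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_delim_auto(ft, file.path(out_dir, "frequency_table.tsv"))
    write_delim_auto(ds, file.path(out_dir, "phla_dataset.tsv"))
    Biostrings::writeXStringSet(prot, file.path(out_dir, "proteome.fasta"))
    jsonlite::write_json(list(spec = unclass(spec), separation = as.list(sep)),
                         file.path(out_dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(spec = spec, freq_table = ft, dataset = ds, proteome = prot,
       predictor = pred, separation = sep)
}
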
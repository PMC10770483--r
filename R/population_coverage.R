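# Population coverage of a pHLA dataset under Hardy-Weinberg genotype
# sampling (the Bui et al. IEDB population-coverage computation), and the
# derived PC90 / sPC90 statistics.
#
# For one locus with allele frequencies f_i, a diploid genotype (a_i, a_j)
# has HWE probability f_i^2 (i = j) or 2 f_i f_j (i != j).  A genotype "hits"
# the data points of the dataset whose allele is a_i or a_j; each data point
# counts at most once, so a homozygote (a, a) hits the points for a once.
# Loci are independent, so per-locus hit distributions convolve.

#' Hit-count distribution
#'
#' Probability mass function over the number of dataset data points an
#' individual's genotype hits.  Stored as a probability vector `p` for hit
#' counts `0, 1, ..., length(p) - 1`.
#'
#' @param p numeric vector of probabilities for hit counts starting at 0;
#'   must be nonnegative and sum to 1 within 1e-9.
#' @return object of class `hit_distribution` with elements `p` and `support`.
#' @export
hit_distribution <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty probability vector")
  if (any(p < -1e-12)) stop("negative probabilities")
  p[p < 0] <- 0
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1 (within 1e-9)")
  structure(list(p = p, support = seq_along(p) - 1L), class = "hit_distribution")
}

#' @export
print.hit_distribution <- function(x, ...) {
  nz <- x$p > 0
  cat("Hit-count distribution (", sum(nz), " support points, max ",
      max(x$support), " hits)\n", sep = "")
  print(stats::setNames(round(x$p[nz], 6), x$support[nz]))
  invisible(x)
}

mean_hits <- function(dist) sum(dist$support * dist$p)

#' Per-locus hit distribution under Hardy-Weinberg sampling
#'
#' Enumerates all unordered genotypes of one locus and returns the induced
#' distribution of dataset hit counts.  Dataset pairs whose allele is absent
#' from the frequency map have frequency 0 in this population and can never
#' be hit (they only cap the support).
#'
#' @param alleles character vector: the allele of every (peptide, allele)
#'   dataset pair at this locus (one element per pair).
#' @param freqs named numeric vector of allele frequencies for the locus,
#'   summing to 1 within `sum_tolerance` (a residual `*OTHER` allele counts
#'   toward the sum but hits nothing).
#' @param sum_tolerance rejection threshold for the frequency sum.
#' @return a [hit_distribution()].
#' @export
locus_hit_distribution <- function(alleles, freqs, sum_tolerance = 1e-6) {
  if (is.data.frame(alleles)) alleles <- alleles$allele
  s <- sum(freqs)
  if (abs(s - 1) > sum_tolerance) {
    stopf("locus frequencies sum to %.6f, not 1 (tolerance %g)", s, sum_tolerance)
  }
  f <- as.numeric(freqs) / s
  cnt <- as.integer(table(factor(alleles, levels = names(freqs))))
  H <- outer(cnt, cnt, "+")
  diag(H) <- cnt
  P <- outer(f, f)  # [i,j] + [j,i] = 2 f_i f_j; diagonal = f_i^2
  p <- numeric(max(H) + 1L)
  agg <- tapply(as.vector(P), as.vector(H), sum)
  p[as.integer(names(agg)) + 1L] <- agg
  # remove the summation round-off so degenerate cases stay exact
  hit_distribution(p / sum(p))
}

#' Combine per-locus hit distributions
#'
#' Loci are assumed independent (no linkage disequilibrium), so the total
#' hit count is the sum of per-locus hit counts and the pmfs convolve.
#'
#' @param dists list of [hit_distribution()] objects (or a single one).
#' @return a [hit_distribution()].
#' @export
combine_loci <- function(dists) {
  if (inherits(dists, "hit_distribution")) return(dists)
  if (!length(dists)) stop("need at least one per-locus distribution")
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      if (a[i] == 0) next
      idx <- i:(i + length(b) - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  hit_distribution(Reduce(conv, lapply(dists, `[[`, "p")))
}

#' Population coverage of a dataset
#'
#' Probability that a random individual's genotype hits at least one data
#' point: `1 - P(0 hits)`.
#'
#' @param dist a [hit_distribution()].
#' @return coverage in `[0, 1]`.
#' @export
hit_coverage <- function(dist) min(max(1 - dist$p[1], 0), 1)

#' PC90: hits guaranteed to 90% of a population
#'
#' The largest hit count `n` such that at least a fraction `q` of the
#' population hits `n` or more data points (the tail function of the hit
#' distribution evaluated at `n`).  With `interpolate = TRUE` the crossing
#' point of the tail function with `q` is interpolated linearly between the
#' bracketing integers.
#'
#' @param dist a [hit_distribution()].
#' @param q population fraction, in (0, 1); default 0.90.
#' @param interpolate return the interpolated crossing point instead of the
#'   integer value.
#' @return PC90 (nonnegative; integer unless `interpolate`).
#' @export
pc90 <- function(dist, q = 0.9, interpolate = FALSE) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be a single number in (0, 1)")
  }
  tail_p <- rev(cumsum(rev(dist$p)))  # tail_p[n + 1] = P(hits >= n)
  n <- max(which(tail_p >= q - 1e-12)) - 1L
  if (!interpolate || n == max(dist$support)) return(n)
  drop <- tail_p[n + 1L] - tail_p[n + 2L]
  n + (tail_p[n + 1L] - q) / drop
}

#' Scaled PC90
#'
#' PC90 divided by the dataset size, making differently sized datasets
#' comparable; lies in `[0, 1]`.
#'
#' @param pc90_value PC90 value.
#' @param n dataset size (unique peptide-allele pairs), at least 1.
#' @return sPC90 = `pc90_value / n`.
#' @export
scaled_pc90 <- function(pc90_value, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("dataset size n must be >= 1")
  pc90_value / n
}

# Split a population's frequency rows into named per-locus vectors.
freqs_by_locus <- function(pop_rows, loci) {
  out <- lapply(loci, function(l) {
    r <- pop_rows[pop_rows$locus == l, , drop = FALSE]
    if (!nrow(r)) stopf("population '%s' has no frequencies for locus %s",
                        pop_rows$population[1], l)
    stats::setNames(r$frequency, r$allele)
  })
  stats::setNames(out, loci)
}

#' Coverage, PC90 and sPC90 of a dataset for one population
#'
#' Builds the per-locus hit distributions from the population's allele
#' frequencies, convolves them across loci, and reads off coverage, PC90 and
#' sPC90.  The dataset size used for sPC90 is the number of unique
#' (peptide, allele) pairs supplied, across all loci.
#'
#' @param pairs data.frame with columns `peptide` and `allele` (mono-allelic,
#'   canonicalized); duplicated pairs are dropped.
#' @param pop_freqs frequency rows of a single population: data.frame with
#'   `locus`, `allele`, `frequency`.
#' @param loci loci entering the genotype model.
#' @param q population fraction for PC90.
#' @param interpolate see [pc90()].
#' @param sum_tolerance see [locus_hit_distribution()].
#' @return object of class `coverage_result`: list with `coverage`, `pc90`,
#'   `spc90`, `n` and the combined `dist`.
#' @export
population_coverage <- function(pairs, pop_freqs, loci = c("A", "B", "C"),
                                q = 0.9, interpolate = FALSE,
                                sum_tolerance = 1e-6) {
  pairs <- unique(pairs[, c("peptide", "allele")])
  n <- nrow(pairs)
  if (n < 1) stop("coverage needs at least one (peptide, allele) pair")
  fl <- freqs_by_locus(pop_freqs, loci)
  pair_locus <- allele_locus(pairs$allele)
  dists <- lapply(loci, function(l) {
    locus_hit_distribution(pairs$allele[pair_locus == l], fl[[l]],
                           sum_tolerance = sum_tolerance)
  })
  dist <- combine_loci(dists)
  pc <- pc90(dist, q = q, interpolate = interpolate)
  structure(list(coverage = hit_coverage(dist), pc90 = pc,
                 spc90 = scaled_pc90(pc, n), n = n, dist = dist),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Coverage %.4f | PC90 %.4g | sPC90 %.4f | N = %d\n",
              x$coverage, x$pc90, x$spc90, x$n))
  invisible(x)
}

#' Monte-Carlo hit distribution (validation oracle)
#'
#' Samples diploid genotypes per locus under Hardy-Weinberg equilibrium,
#' counts dataset hits, and returns the empirical distribution.  Exists as an
#' independent check of the exact enumeration; reproducible under `seed`.
#'
#' @inheritParams population_coverage
#' @param n_samples number of sampled individuals, at least 1.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @return a [hit_distribution()] (empirical).
#' @export
monte_carlo_hits <- function(pairs, pop_freqs, n_samples, seed = NULL,
                             loci = c("A", "B", "C")) {
  if (!is.numeric(n_samples) || n_samples < 1) stop("n_samples must be >= 1")
  n_samples <- as.integer(n_samples)
  pairs <- unique(pairs[, c("peptide", "allele")])
  fl <- freqs_by_locus(pop_freqs, loci)
  pair_locus <- allele_locus(pairs$allele)
  with_seed(seed, {
    tot <- integer(n_samples)
    for (l in loci) {
      f <- fl[[l]]
      cnt <- as.integer(table(factor(pairs$allele[pair_locus == l],
                                     levels = names(f))))
      k <- length(f)
      i1 <- sample.int(k, n_samples, replace = TRUE, prob = f)
      i2 <- sample.int(k, n_samples, replace = TRUE, prob = f)
      tot <- tot + cnt[i1] + ifelse(i1 == i2, 0L, cnt[i2])
    }
    hit_distribution(tabulate(tot + 1L, nbins = max(tot) + 1L) / n_samples)
  })
}
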
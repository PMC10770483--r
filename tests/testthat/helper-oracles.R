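# Independent oracles and small fixture builders used across test files.

# Brute-force hit pmf: enumerate every ordered genotype combination across
# loci directly (no convolution), multiply HWE probabilities, sum hit counts.
brute_force_hit_pmf <- function(pairs, pop_freqs, loci) {
  per_locus <- lapply(loci, function(l) {
    r <- pop_freqs[pop_freqs$locus == l, , drop = FALSE]
    f <- stats::setNames(r$frequency, r$allele)
    pl <- sub("\\*.*$", "", pairs$allele)
    cnt <- as.integer(table(factor(pairs$allele[pl == l], levels = names(f))))
    k <- length(f)
    gt <- expand.grid(i = seq_len(k), j = seq_len(k))
    list(prob = unname(f[gt$i] * f[gt$j]),
         hits = ifelse(gt$i == gt$j, cnt[gt$i], cnt[gt$i] + cnt[gt$j]))
  })
  acc <- list(prob = 1, hits = 0L)
  for (pl in per_locus) {
    acc <- list(prob = as.vector(outer(acc$prob, pl$prob)),
                hits = as.vector(outer(acc$hits, pl$hits, "+")))
  }
  agg <- tapply(acc$prob, acc$hits, sum)
  p <- numeric(max(as.integer(names(agg))) + 1L)
  p[as.integer(names(agg)) + 1L] <- agg
  p
}

# Random small coverage instance: <= `max_alleles` alleles per locus,
# `n_loci` loci, a few dataset pairs (some for alleles absent from the
# population).
random_coverage_instance <- function(n_loci = 2, max_alleles = 3, max_pairs = 4) {
  loci <- c("A", "B", "C")[seq_len(n_loci)]
  rows <- list()
  for (l in loci) {
    k <- sample(seq_len(max_alleles), 1)
    f <- as.numeric(stats::rgamma(k, 1))
    f <- f / sum(f)
    f[which.max(f)] <- f[which.max(f)] + (1 - sum(f))
    rows[[l]] <- data.frame(population = "P", locus = l,
                            allele = sprintf("%s*%02d:01", l, seq_len(k)),
                            frequency = f, stringsAsFactors = FALSE)
  }
  freqs <- do.call(rbind, rows)
  np <- sample(seq_len(max_pairs), 1)
  pool <- c(freqs$allele, sprintf("%s*99:01", loci))  # includes absent alleles
  data_pairs <- data.frame(peptide = replicate(np, paste(sample(LETTERS[1:20], 9, TRUE), collapse = "")),
                           allele = sample(pool, np, replace = TRUE),
                           stringsAsFactors = FALSE)
  list(pairs = unique(data_pairs), freqs = freqs, loci = loci)
}

# Tiny prepared two-population frequency table over loci A and B.
tiny_freq_table <- function() {
  data.frame(
    population = rep(c("Pop1", "Pop2"), each = 4),
    country = rep(c("Richland", "Poorland"), each = 4),
    income_level = rep(c("high", "low"), each = 4),
    locus = rep(c("A", "A", "B", "B"), 2),
    allele = rep(c("A*01:01", "A*02:01", "B*07:02", "B*08:01"), 2),
    frequency = c(0.7, 0.3, 0.6, 0.4,
                  0.2, 0.8, 0.1, 0.9),
    stringsAsFactors = FALSE
  )
}
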
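make_rank_predictor <- function(tab) {
  # deterministic adapter from an in-memory table; unknown pairs -> NA
  table_predictor(tab, name = "fixture")
}

test_that("the adapter contract is enforced", {
  bad <- phla_predictor(function(p, a) data.frame(strength = 1), name = "bad")
  expect_error(predict_phla(bad, "ACDEFGHIK", "A*01:01"), "contract")
  wrong_n <- phla_predictor(function(p, a) {
    data.frame(strength = c(1, 2), percentile_rank = c(1, 2))
  })
  expect_error(predict_phla(wrong_n, "ACDEFGHIK", "A*01:01"), "rows")
  out_of_range <- phla_predictor(function(p, a) {
    data.frame(strength = 1, percentile_rank = 150)
  })
  expect_error(predict_phla(out_of_range, "ACDEFGHIK", "A*01:01"), "\\[0, 100\\]")
  expect_error(predict_phla(bad, c("A", "B"), "A*01:01"), "lengths differ")
})

test_that("deconvolution picks the strongest candidate and applies the rank cutoff", {
  ds <- data.frame(
    peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"),
    alleles = c("A*01:01;B*07:02",   # ranks 0.1 / 0.3 -> A*01:01
                "A*01:01;B*07:02",   # best rank 0.7 -> excluded
                "A*01:01;B*07:02",   # best rank exactly 0.5 -> excluded
                "B*07:02"),          # mono-allelic, rank 0.2 -> kept
    stringsAsFactors = FALSE
  )
  sc <- data.frame(
    peptide = rep(ds$peptide, c(2, 2, 2, 1)),
    allele = c("A*01:01", "B*07:02", "A*01:01", "B*07:02",
               "A*01:01", "B*07:02", "B*07:02"),
    strength = c(5, 3, 1, 0.5, 2, 1, 4),
    percentile_rank = c(0.1, 0.3, 0.7, 0.9, 0.5, 0.6, 0.2),
    stringsAsFactors = FALSE
  )
  out <- deconvolute(ds, make_rank_predictor(sc))
  expect_equal(out$peptide, c("AAAAAAAAA", "EEEEEEEEE"))
  expect_equal(out$allele, c("A*01:01", "B*07:02"))
  expect_equal(attr(out, "n_excluded"), 2)
  expect_equal(nrow(attr(out, "flagged")), 0)
  # every output allele was among its record's candidates; size shrinks
  expect_lte(nrow(out), nrow(ds))
  # predictor failure flags the record instead of dropping it silently
  ds2 <- rbind(ds[1, ], data.frame(peptide = "GGGGGGGGG", alleles = "C*05:01"))
  out2 <- deconvolute(ds2, make_rank_predictor(sc))
  expect_equal(nrow(attr(out2, "flagged")), 1)
  expect_equal(attr(out2, "flagged")$peptide, "GGGGGGGGG")
  expect_equal(out2$peptide, "AAAAAAAAA")
})

test_that("deconvoluted assignments stay within each record's candidates", {
  spec <- scenario_spec(populations_per_level = 2, alleles_per_locus = 6,
                        dataset_size = 120, multi_allelic_fraction = 0.8,
                        seed = 37)
  ft <- gen_frequency_table(spec)
  ds <- gen_phla_dataset(spec, ft)
  pred <- mock_predictor(stats::setNames(rep(3, 18), sort(unique(ft$allele))),
                         binders = ds, seed = 5)
  out <- deconvolute(ds, pred)
  expect_lte(nrow(out), nrow(ds))
  cand <- strsplit(ds$alleles[match(out$peptide, ds$peptide)], ";")
  expect_true(all(mapply(function(a, cc) a %in% cc, out$allele, cand)))
  expect_true(all(out$percentile_rank < 0.5))
})

test_that("decoy sampling draws uniform substrings reproducibly", {
  prot <- c(p1 = "ACDEFGHIK")
  d <- sample_decoys(prot, 9, n = 5, seed = 1)
  expect_equal(as.character(d), rep("ACDEFGHIK", 5))
  expect_error(sample_decoys(prot, 10, n = 5), "length >= 10")
  expect_error(sample_decoys(prot, 9, n = 0), "at least one")
  # determinism
  big <- gen_proteome(5000, n_sequences = 4, seed = 3)
  d1 <- sample_decoys(big, 9, n = 200, seed = 7)
  d2 <- sample_decoys(big, 9, n = 200, seed = 7)
  expect_identical(as.character(d1), as.character(d2))
  expect_true(all(nchar(d1) == 9))
  # every decoy is a contiguous substring of the proteome
  seqs <- as.character(big)
  expect_true(all(vapply(unique(as.character(d1)),
                         function(x) any(grepl(x, seqs, fixed = TRUE)),
                         logical(1))))
  # sequences with nonstandard residues are skipped
  odd <- c(good = paste(rep("ACDEFGHIK", 3), collapse = ""), bad = "ACDEFGHIX")
  d3 <- sample_decoys(odd, 9, n = 50, seed = 2)
  expect_false(any(grepl("X", d3)))
  # optional binder exclusion resamples matching draws
  d4 <- sample_decoys(big, 9, n = 100, seed = 7, exclude = as.character(d1))
  expect_false(any(d4 %in% as.character(d1)))
})

test_that("PPV ranks strong-to-weak with decoys winning ties", {
  expect_equal(ppv_per_allele(1000 + 1:10, 1:990), 1)
  expect_equal(ppv_per_allele(1:10, 100 + 1:990), 0)
  # conservative tie rule: equal scores rank decoys first
  expect_equal(ppv_per_allele(rep(1, 5), rep(1, 5)), 0)
  expect_equal(ppv_per_allele(c(10, 1), c(5, 0.5)), 0.5)
  expect_error(ppv_per_allele(numeric(0), 1:5), "binder")
  expect_error(ppv_per_allele(1:5, numeric(0)), "decoy")
})

test_that("PPV and FOOP are invariant under monotone score transforms", {
  set.seed(91)
  b <- rnorm(20, 1); d <- rnorm(200)
  tf <- function(x) exp(3 * x) - 7
  expect_equal(ppv_per_allele(b, d), ppv_per_allele(tf(b), tf(d)))
  expect_equal(foop_per_allele(b, d, 5), foop_per_allele(tf(b), tf(d), 5))
})

test_that("random scores give PPV near the exchangeable expectation", {
  set.seed(101)
  reps <- 500
  ppvs <- replicate(reps, ppv_per_allele(runif(10), runif(990)))
  se <- sd(ppvs) / sqrt(reps)
  expect_lt(abs(mean(ppvs) - 0.01), 4 * se)
})

test_that("FOOP counts binders by decoy-rank position at the 0.1% threshold", {
  dec <- as.numeric(seq_len(500000))
  in_500 <- 500000 - 500 + 0.5     # exactly 500 decoys score above
  out_501 <- 500000 - 501 + 0.5    # 501 decoys above: rank 0.1002% > 0.1%
  expect_equal(percentile_rank(in_500, dec), 0.1)
  expect_equal(percentile_rank(out_501, dec), 0.1002)
  expect_equal(foop_per_allele(c(in_500, out_501), dec), 0.5)
  # binder above all decoys has rank 0 and is counted; all strong -> FOOP 1
  expect_equal(percentile_rank(500001, dec), 0)
  expect_equal(foop_per_allele(rep(500001, 3), dec), 1)
})

test_that("the mock predictor is deterministic with a frozen-null rank", {
  pred <- mock_predictor(c("A*01:01" = 2),
                         binders = data.frame(peptide = "AAAAAAAAA",
                                              allele = "A*01:01"),
                         seed = 13)
  s1 <- predict_phla(pred, c("AAAAAAAAA", "CCCCCCCCC"), rep("A*01:01", 2))
  s2 <- predict_phla(pred, c("CCCCCCCCC", "AAAAAAAAA"), rep("A*01:01", 2))
  expect_equal(s1$strength, rev(s2$strength))
  # rank is the frozen-null tail of the strength: consistent ordering
  expect_equal(s1$percentile_rank, 100 * pnorm(s1$strength, lower.tail = FALSE))
  # unknown allele behaves as separation 0
  s3 <- predict_phla(pred, "AAAAAAAAA", "B*99:99")
  expect_lt(abs(s3$strength), 6)
})

test_that("PPV and FOOP increase with the mock separation parameter", {
  set.seed(111)
  peps <- replicate(15, paste(sample(c("A", "C", "D", "E", "F"), 9, TRUE), collapse = ""))
  binders <- data.frame(peptide = peps, allele = "A*01:01", stringsAsFactors = FALSE)
  decoys <- replicate(400, paste(sample(c("G", "H", "I", "K", "L"), 9, TRUE), collapse = ""))
  res <- sapply(c(0, 1, 2, 4, 8), function(d) {
    pred <- mock_predictor(c("A*01:01" = d), binders = binders, seed = 3)
    b <- predict_phla(pred, binders$peptide, binders$allele)$strength
    dd <- predict_phla(pred, decoys, rep("A*01:01", length(decoys)))$strength
    c(ppv = ppv_per_allele(b, dd), foop = foop_per_allele(b, dd, threshold = 1))
  })
  expect_true(all(diff(res["ppv", ]) >= 0))
  expect_true(all(diff(res["foop", ]) >= 0))
  expect_equal(unname(res["ppv", 5]), 1)   # separation limit
  expect_equal(unname(res["foop", 5]), 1)
})

test_that("evaluate_predictor reports one row per allele with length-matched FOOP", {
  spec <- scenario_spec(populations_per_level = 2, alleles_per_locus = 3,
                        dataset_size = 60, multi_allelic_fraction = 0, seed = 47)
  ft <- gen_frequency_table(spec)
  ds <- gen_phla_dataset(spec, ft)
  ds$allele <- ds$true_allele
  pred <- mock_predictor(stats::setNames(rep(10, 9), sort(unique(ft$allele))),
                         binders = ds, seed = 2)
  prot <- gen_proteome(4000, seed = 5)
  decoys <- lapply(stats::setNames(8:11, 8:11), function(L) {
    sample_decoys(prot, L, n = 300, seed = L)
  })
  ev <- evaluate_predictor(ds, pred, decoys)
  expect_setequal(ev$allele, unique(ds$true_allele))
  expect_true(all(ev$ppv == 1))   # near-perfect separation
  expect_true(all(ev$foop == 1))
  expect_equal(sum(ev$n), length(unique(paste(ds$peptide, ds$allele))))
})
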
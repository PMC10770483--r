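test_that("allele names reduce to two-field nomenclature", {
  expect_identical(canonicalize_allele("HLA-A*01:01:01:01"), "A*01:01")
  expect_identical(canonicalize_allele("A*01:01"), "A*01:01")
  expect_identical(
    canonicalize_allele(c("b*07:02:01", "HLA-C*05:01", "A*101:03")),
    c("B*07:02", "C*05:01", "A*101:03")
  )
  expect_error(canonicalize_allele("XYZ-99"), "XYZ-99")
  expect_error(canonicalize_allele("DRB1*01:01"), "DRB1")
  expect_error(canonicalize_allele("A*01"), "A\\*01")
})

test_that("canonicalization is idempotent over generated names", {
  set.seed(11)
  raw <- sprintf("%sHLA-%s*%02d:%02d%s",
                 sample(c("", " "), 50, TRUE),
                 sample(c("A", "B", "C"), 50, TRUE),
                 sample(1:80, 50, TRUE), sample(1:99, 50, TRUE),
                 sample(c("", ":01", ":01:02N"), 50, TRUE))
  once <- canonicalize_allele(raw)
  expect_identical(canonicalize_allele(once), once)
})

test_that("duplicate (population, allele) entries resolve deterministically", {
  tab <- data.frame(
    population = c("PopX", "PopX", "PopX", "PopY"),
    locus = "A",
    allele = c("A*01:01", "A*01:01", "A*02:01", "A*01:01"),
    frequency = c(0.3, 0.4, 0.3, 0.5),
    sample_size = c(50, 200, 10, 30),
    stringsAsFactors = FALSE
  )
  out <- dedupe_entries(tab)
  expect_equal(nrow(out), 3)
  # larger sample size wins the conflict, and the loser is logged
  expect_equal(out$frequency[out$population == "PopX" & out$allele == "A*01:01"], 0.4)
  log <- attr(out, "dedupe_log")
  expect_equal(nrow(log), 1)
  expect_equal(log$frequency, 0.3)
  # identical duplicate rows collapse to one
  tab2 <- tab[c(1, 1, 3), ]
  expect_equal(nrow(dedupe_entries(tab2)), 2)
  # no duplicates -> unchanged; rerun is a no-op; never grows
  clean <- dedupe_entries(out)
  expect_equal(clean, out, ignore_attr = TRUE)
  expect_lte(nrow(out), nrow(tab))
  # without sample_size, first-in-file order wins
  tab$sample_size <- NULL
  out2 <- dedupe_entries(tab, rule = "first")
  expect_equal(out2$frequency[out2$population == "PopX" & out2$allele == "A*01:01"], 0.3)
})

test_that("frequency sums validate, renormalize, or exclude per tolerance", {
  tab <- data.frame(
    population = rep(c("Pass", "Renorm", "Bad"), each = 2),
    locus = "A",
    allele = rep(c("A*01:01", "A*02:01"), 3),
    frequency = c(0.5, 0.5, 0.58, 0.39, 0.6, 0.5),
    stringsAsFactors = FALSE
  )
  out <- validate_frequencies(tab, tolerance = 0.05)
  rep_df <- attr(out, "validation_report")
  expect_setequal(rep_df$status, c("pass", "renormalized", "excluded"))
  expect_equal(rep_df$sum[rep_df$population == "Bad"], 1.1)
  # renormalized locus sums to exactly 1; excluded population is gone
  expect_equal(sum(out$frequency[out$population == "Renorm"]), 1, tolerance = 1e-12)
  expect_equal(sum(out$frequency[out$population == "Pass"]), 1, tolerance = 1e-12)
  expect_false("Bad" %in% out$population)
})

test_that("disabled renormalization assigns the deficit to a residual allele", {
  tab <- data.frame(population = "P", locus = "A",
                    allele = c("A*01:01", "A*02:01"),
                    frequency = c(0.58, 0.39), stringsAsFactors = FALSE)
  out <- validate_frequencies(tab, tolerance = 0.05, renormalize = FALSE)
  expect_true("A*OTHER" %in% out$allele)
  expect_equal(out$frequency[out$allele == "A*OTHER"], 0.03)
  expect_equal(sum(out$frequency), 1, tolerance = 1e-12)
  # the original entries are untouched
  expect_equal(out$frequency[out$allele == "A*01:01"], 0.58)
})

test_that("populations missing a required locus are dropped", {
  tab <- data.frame(
    population = c("Full", "Full", "Full", "Partial", "Partial"),
    locus = c("A", "B", "C", "A", "B"),
    allele = c("A*01:01", "B*07:02", "C*05:01", "A*01:01", "B*07:02"),
    frequency = 1, stringsAsFactors = FALSE
  )
  out <- filter_complete_loci(tab, c("A", "B", "C"))
  expect_setequal(unique(out$population), "Full")
  out_a <- filter_complete_loci(tab, "A")
  expect_setequal(unique(out_a$population), c("Full", "Partial"))
})

test_that("the full cleaning pipeline leaves every locus summing to one", {
  set.seed(21)
  spec <- scenario_spec(populations_per_level = 2, alleles_per_locus = 5, seed = 3)
  tab <- gen_frequency_table(spec)
  # corrupt it: duplicates, a drifting sum, a population missing locus C
  noisy <- rbind(tab, tab[1:4, ])
  noisy$frequency[noisy$population == noisy$population[1] & noisy$locus == "A"] <-
    noisy$frequency[noisy$population == noisy$population[1] & noisy$locus == "A"] * 1.02
  noisy <- noisy[!(noisy$population == noisy$population[nrow(noisy)] & noisy$locus == "C"), ]
  out <- prepare_frequency_table(noisy)
  sums <- tapply(out$frequency, paste(out$population, out$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(table(paste(out$population, out$allele)) == 1))
  expect_true(all(c("A", "B", "C") %in% out$locus))
})

test_that("GNI maps onto the four World Bank bands with closed ceilings", {
  expect_identical(gni_to_income(900), "low")
  expect_identical(gni_to_income(1085), "low")
  expect_identical(gni_to_income(1086), "lower-middle")
  expect_identical(gni_to_income(4255), "lower-middle")
  expect_identical(gni_to_income(4256), "upper-middle")
  expect_identical(gni_to_income(13205), "upper-middle")
  expect_identical(gni_to_income(13206), "high")
  expect_identical(gni_to_income(50000), "high")
  # partition property: every value lands in exactly one band
  set.seed(5)
  g <- exp(runif(200, log(100), log(1e5)))
  lv <- gni_to_income(g)
  expect_true(all(lv %in% c("low", "lower-middle", "upper-middle", "high")))
})

test_that("countries classify by table lookup and unknowns stay explicit", {
  inc <- data.frame(country = c("Richland", "Poorland"),
                    gni_per_capita = c(50000, 900), stringsAsFactors = FALSE)
  expect_identical(classify_income(c("Richland", "poorland", "Atlantis"), inc),
                   c("high", "low", "unclassified"))
  inc2 <- data.frame(country = "Richland", income_level = "high",
                     stringsAsFactors = FALSE)
  expect_identical(classify_income("Richland", inc2), "high")
  expect_error(classify_income("Richland",
                               data.frame(country = "Richland", income_level = "rich")),
               "unknown income level")
})

test_that("country extraction takes the longest label match, overrides first", {
  countries <- c("Niger", "Nigeria", "United States")
  lab <- c("Nigeria Yoruba", "Niger Tuareg", "USA Hispanic")
  got <- extract_country(lab, countries, overrides = c("USA Hispanic" = "United States"))
  expect_identical(got, c("Nigeria", "Niger", "United States"))
  expect_true(is.na(extract_country("Atlantis deep", countries)))
})

test_that("income annotation joins countries to the frequency table", {
  ft <- tiny_freq_table()
  ft$income_level <- NULL
  inc <- data.frame(country = c("Richland", "Poorland"),
                    gni_per_capita = c(60000, 800), stringsAsFactors = FALSE)
  out <- annotate_income(ft, inc)
  expect_identical(unique(out$income_level[out$country == "Richland"]), "high")
  expect_identical(unique(out$income_level[out$country == "Poorland"]), "low")
})
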
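# hlabias

Population and income bias audits for peptide-HLA binding datasets and
predictors.

## The problem

Peptide-HLA (pHLA) binding predictors drive peptide-vaccine and
immunotherapy pipelines, and most advertise themselves as *pan-allele*. But
the public datasets they train on concentrate data points on a handful of
HLA class I alleles common in high-income countries, and that imbalance can
propagate into the models as unequal per-allele accuracy. `hlabias` is for
dataset curators and tool developers who want to measure both effects before
trusting (or publishing) a "pan-allele" claim:

* **Data bias.** For a dataset of (peptide, allele) pairs and a table of
  population allele frequencies, how much of the dataset does a random
  individual of each population actually carry? Under Hardy-Weinberg
  sampling of genotypes (frequencies `f_i`, genotype probabilities `f_i^2`
  and `2 f_i f_j`, loci A/B/C independent), the package computes the exact
  distribution of per-individual dataset hits and reads off:
  - coverage = `1 − P(0 hits)`,
  - `PC90` = largest `n` with `P(hits ≥ n) ≥ 0.9`,
  - `sPC90 = PC90 / N` (dataset-size-scaled, `N` = unique pairs).

  Populations are grouped by the World Bank income level of their country
  (low / lower-middle / upper-middle / high by GNI per capita), and the
  sPC90 distributions are compared across levels with one-way ANOVA and
  one-sided Kolmogorov-Smirnov tests (asymptotic
  `p = exp(−2mnD²/(m+n))`, Holm-adjusted pairwise).

* **Algorithmic bias.** For any predictor exposing binding strength and
  percentile rank per (peptide, allele) — via the file/table adapter
  contract, or the built-in deterministic mock — the package deconvolutes
  multi-allelic mass-spectrometry records (each peptide assigned to the
  candidate allele with the lowest predicted rank; best rank ≥ 0.5 excluded),
  samples length-matched decoys uniformly from a proteome, and computes per
  allele:
  - `PPV_a` = fraction of true binders among the top `n_a` of the pooled
    binder+decoy ranking (`n_a` = number of binders for allele `a`),
  - `FOOP_a` = fraction of binders whose percentile rank against the decoys
    is ≤ 0.1% (with the reference 500,000 decoys: outranked by ≤ 500 decoys).

A synthetic-scenario generator produces all four inputs — frequency tables
with a controllable income gradient, long-tailed datasets with a
controllable overrepresentation exponent β, random proteomes, and a mock
predictor with controllable per-allele accuracy — so the full pipeline runs
and is tested without any external downloads.

## Worked example

Simulate a biased study (24 populations across the four income levels, 30
alleles, 1,200 records with β = 3 overrepresentation of high-income-common
alleles, 30% multi-allelic) and audit it:

```r
library(hlabias)

spec <- scenario_spec(populations_per_level = 6, alleles_per_locus = 10,
                      dataset_size = 1200, bias = 3,
                      multi_allelic_fraction = 0.3, seed = 1)
art <- simulate_scenario(spec, proteome_length = 20000)

run_audit_data(art$dataset, art$freq_table, predictor = art$predictor)
#> pHLA data-bias audit: 1179 unique pairs, 11 alleles, 24 populations
#>   deconvolution: 21 excluded (rank >= 0.5), 0 flagged
#>   sPC90: mean 0.1747, range [0.0059, 0.6896]
#> sPC90 by income level:
#>   low           n=  6  mean=0.0059
#>   lower-middle  n=  6  mean=0.0219
#>   upper-middle  n=  6  mean=0.0476
#>   high          n=  6  mean=0.6233
#> One-way ANOVA: F = 86.36, p = 1.28e-11 ***
#> One-sided KS (lower income stochastically below higher):
#>         lower       higher D        p  p_holm small_sample sig
#>           low lower-middle 1 0.002479 0.01487         TRUE   *
#>           low upper-middle 1 0.002479 0.01487         TRUE   *
#>           low         high 1 0.002479 0.01487         TRUE   *
#>  lower-middle upper-middle 1 0.002479 0.01487         TRUE   *
#>  lower-middle         high 1 0.002479 0.01487         TRUE   *
#>  upper-middle         high 1 0.002479 0.01487         TRUE   *
```

90% of individuals in the simulated low-income populations are guaranteed
only ~0.6% of the dataset (sPC90 0.0059), against ~62% for high-income
populations — the planted bias, recovered with its significance stars.

```r
model <- run_audit_model(art$dataset, art$predictor, art$proteome,
                         freq_table = art$freq_table, n_decoys = 1000,
                         seed = 2, min_binders = 3)
head(as.data.frame(model$eval)[, c("allele", "n", "ppv", "foop", "top_income")], 4)
#>    allele   n       ppv      foop top_income
#> 1 A*05:01 802 0.9987531 1.0000000       high
#> 2 B*03:01 269 0.9702602 0.9628253       high
#> 3 C*06:01  47 0.8936170 0.8936170       high
#> 4 C*10:01  30 0.8666667 0.9666667        low
```

Per-allele PPV falls with training abundance (0.999 at 802 data points down
to 0.71 at 7), and each allele is annotated with the income level of the
population expressing it the most — the per-allele view of how data bias
becomes algorithmic bias.

Real inputs take the same path: `read_frequency_table()` +
`prepare_frequency_table()` + `annotate_income()` for AFND-style tables,
`read_phla_dataset()` for training/evaluation sets, a FASTA proteome, and
`table_predictor()` for scores exported from any external tool. A thin CLI
(`inst/scripts/hlabias.R`, subcommands `simulate` / `audit-data` /
`audit-model` over a YAML config) wraps the same functions.

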
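---
title: "Auditing population and income bias in peptide-HLA binding data and predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing population and income bias in peptide-HLA binding data and predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlabias)
```

## The problem

Peptide-HLA (pHLA) binding predictors are trained on public datasets whose
allele composition is far from uniform: a handful of class I alleles common
in wealthy countries account for most data points, while alleles frequent in
lower-income geographic populations are sparsely covered or absent.  This
package quantifies that imbalance at two levels:

* **Data bias** — how well does a dataset's allele content represent each
  geographic population, and does representativeness track the income level
  of the population's country?
* **Algorithmic bias** — does a predictor's per-allele accuracy track its
  per-allele training abundance, so that the data bias propagates into
  unequal predictions?

Every stage runs on synthetic inputs generated by the package itself, so the
whole pipeline is testable offline; the same functions accept real
allele-frequency tables, training sets, proteomes and predictor score tables
in plain delimited text.

## Population coverage under Hardy-Weinberg sampling

The central quantity is the distribution of *dataset hits* for a random
individual of a population.  An individual carries two alleles at each class
I locus (A, B, C).  Given per-locus allele frequencies $f_i$ (summing to 1),
Hardy-Weinberg equilibrium assigns genotype $(a_i, a_j)$ probability $f_i^2$
when $i = j$ and $2 f_i f_j$ otherwise.  A genotype *hits* the data points
whose allele is $a_i$ or $a_j$; a data point is either represented in the
genotype or not, so a homozygote counts each of its data points once.  Loci
are treated as independent (no linkage disequilibrium), so per-locus hit
distributions combine by discrete convolution.

From the combined distribution we read off

* **coverage** $= 1 - P(\text{0 hits})$, the probability that an individual
  is touched by the dataset at all;
* **PC90**, the largest $n$ with $P(\text{hits} \ge n) \ge 0.9$ — the number
  of data points guaranteed to 90% of the population;
* **sPC90** $=$ PC90 $/ N$, scaling by the dataset size $N$ so differently
  sized datasets compare.

```{r coverage-example}
freqs <- data.frame(population = "P", locus = "A",
                    allele = c("A*01:01", "A*OTHER"),
                    frequency = c(0.5, 0.5))
pairs <- data.frame(peptide = "ACDEFGHIK", allele = "A*01:01")
population_coverage(pairs, freqs, loci = "A")
```

Numerical choices worth knowing:

* **$N$ for sPC90** is the number of unique (peptide, allele) pairs after
  deconvolution and deduplication — the unit the coverage computation
  consumes.  Pairs whose allele a population lacks count toward $N$ but can
  never be hit there (their frequency is 0 for that population), which is
  the conservative reading.
* **PC90 is an integer by default** (the largest hit count whose tail
  probability still reaches 0.9).  `pc90(..., interpolate = TRUE)` instead
  interpolates the crossing point of the tail function linearly between the
  bracketing integers; both are exposed because published coverage tools do
  not document which convention they report.
* Loci are convolved in the fixed order A, B, C.  The result is
  order-invariant; the order is fixed only so logs are reproducible.
* An exact enumeration is used throughout; `monte_carlo_hits()` re-derives
  the same distribution by simulating genotypes and exists purely as an
  independent cross-check (the tests compare the two per bin).

## Cleaning allele-frequency tables

Frequency tables in the style of the Allele Frequency Net Database need four
repairs before they can serve as genotype models, each deterministic and
logged:

1. **Canonicalization** truncates allele names to two fields
   (`A*01:01`), keeping gene, allele group and protein; higher-resolution
   (synonymous/noncoding) fields are irrelevant at the resolution of
   frequency studies.
2. **Deduplication** keeps one row per (population, allele).  Conflicting
   duplicates resolve to the entry with the larger reported sample size,
   falling back to first-in-file order; every removal lands in the
   `dedupe_log` attribute so the resolution can be replayed.
3. **Sum validation**: per (population, locus) sums within 0.05 of 1 are
   proportionally renormalized to exactly 1 (or, if renormalization is
   disabled, a deficit is assigned to a synthetic `*OTHER` allele that can
   never match a data point — preserving probability mass without inventing
   hits).  Sums further from 1 exclude the (population, locus); 0.05 is a
   pragmatic default for tables that mix studies of different sizes.
4. **Complete-loci filtering** keeps only populations with data for every
   configured locus, since the cross-locus convolution needs all of them.

Income classification follows the World Bank's four levels by GNI per
capita, with the bands closed at their printed ceilings: low $\le 1{,}085$;
lower-middle $1{,}086$–$4{,}255$; upper-middle $4{,}256$–$13{,}205$; high
above $13{,}205$ (the printed tables overlap at the last ceiling; we resolve
the overlap downward).  Countries are extracted from population labels by
longest match against the classification table, with an explicit override
map for ambiguous labels, and unknown countries are reported as
`"unclassified"` rather than silently defaulted.

## Deconvolution of multi-allelic data

Mass-spectrometry datasets contain multi-allelic records: a peptide eluted
from a sample expressing up to six HLA alleles.  `deconvolute()` assigns
each peptide to the candidate with the strongest predicted binding.
"Strongest" is operationalized as the *lowest percentile rank*, because rank
is the quantity calibrated across alleles by the mainstream predictors;
strength breaks rank ties.  Records whose best rank is $\ge$ 0.5 are
excluded as peptides that likely bind none of the candidates.  The cutoff is
read on the percentile-rank scale (0.5%) — the scale on which the mainstream
tools report "%rank" — and is a configurable argument, so the alternative
reading (fraction 0.5) is selectable.  Records on which the predictor fails
are flagged and set aside, never silently dropped.

## Decoys and the per-allele accuracy metrics

Eluted-ligand data contain only binders, so negatives are sampled from the
proteome: for each peptide length present in the dataset (8–11 in the
audited sets), `sample_decoys()` draws substrings uniformly over all
(sequence, offset) windows, with replacement; sequences containing
non-standard residues are skipped.  The reference setting is 500,000 decoys
per length, shared across alleles.  Decoys are not filtered against the
binder set by default (collisions are astronomically rare at proteome
scale); an `exclude` argument removes exact matches for small fixtures.

For an allele $a$ with $n_a$ binders:

* **PPV** pools the binder and decoy predictions, ranks them from strong to
  weak, and reports the fraction of true binders among the top $n_a$.  At
  tied scores decoys are ranked ahead of binders, so ties can only lower
  PPV — a deliberately conservative convention.
* **FOOP** is the fraction of binders whose percentile rank against the
  decoys is $\le$ 0.1% — with 500,000 decoys, exactly those outranked by at
  most 500 decoys.  Each binder is ranked within the decoys of its own
  length, since percentile ranks are only comparable within a length class.

Both metrics depend on the predictor's scores only through their ordering,
and the tests verify invariance under monotone score transforms.

## Income-stratified significance

Per-population sPC90 values are grouped by income level and compared with a
one-way ANOVA (equal-variance F test) across the four levels, followed by a
one-sided two-sample Kolmogorov-Smirnov test for every ordered pair of
levels.  The KS direction asks whether the lower-income group's sPC90
distribution is stochastically smaller than the higher-income group's — the
direction of the bias claim.  The p-value uses the one-sided asymptotic tail
$\exp(-2 m n D^2 / (m+n))$; groups smaller than 10 are flagged because the
asymptotic formula is unreliable there.  Pairwise p-values are reported raw
and Holm-adjusted, since a star per pair without adjustment overstates joint
significance.

## The synthetic scenario generator

`scenario_spec()` fixes the study conditions; `simulate_scenario()` emits
all four artifacts (frequency table, dataset, proteome, predictor).  Design:

* **Frequency tables.**  Allele frequencies are Dirichlet draws; the default
  concentration 0.5 gives the skewed, few-dominant-alleles spectra typical
  of HLA loci.  With `income_gradient = 0` populations are i.i.d.
  (no income signal).  Otherwise two archetype profiles are drawn per locus
  and the four income levels interpolate between them — high income on one
  archetype, low income `income_gradient` of the way toward the other —
  with populations scattered around their level's profile
  (`within_concentration = 50` keeps within-level spread moderate).  This is
  the minimal structure that gives dataset bias a *graded* footprint across
  income levels rather than a high-vs-rest dichotomy.
* **Datasets.**  The true allele of each record is sampled with weight
  $(\bar f^{\text{high}}_a)^\beta$, the allele's mean frequency among
  high-income populations raised to the bias exponent.  $\beta = 1$
  reproduces pooled high-income composition; $\beta = 3$ (the bias-recovery
  scenario) produces the long-tailed counts and income skew seen in real
  training sets.  A configurable fraction of records carries 2–6 candidate
  alleles to exercise deconvolution.  The generator keeps its own tally of
  true alleles as an oracle for the counting code.
* **Peptides and proteome** are i.i.d. uniform over the 20-letter alphabet —
  the simplest null that exercises every code path.  No binding motifs, no
  realistic residue composition, no linkage disequilibrium: passing tests
  demonstrate the *machinery*, not that real data would show any particular
  effect size.
* **Mock predictor.**  Scores are standard-normal deviates derived by
  hashing (peptide, allele, seed), shifted by a per-allele separation $d_a$
  for true binder pairs; ranks come from the frozen standard-normal null.
  Determinism via hashing means the same pair scores identically in any
  batch, which makes caching and deconvolution testable without storing
  score files.  `separation_from_counts()` ties $d_a$ to training abundance,
  $d_a = d_{\min} + (d_{\max} - d_{\min})\sqrt{c_a / c_{\max}}$: the floor
  $d_{\min} = 3$ reflects that real predictors separate true ligands from
  decoys reasonably well even for sparsely covered alleles (so most records
  survive the deconvolution rank filter), while the abundance-linked
  increment up to $d_{\max} = 6$ emulates accuracy that tracks training
  data.

Every artifact is bit-reproducible under the scenario seed.

## Problem sizes in the test suite

The tests run the full pipeline at deliberately desk-sized conditions: the
bias-recovery scenario uses 24 populations (6 per income level), 30 alleles,
1,200 records with 30% multi-allelic, 1,000 decoys per length and
per-allele predictor separations between 3 and 6; oracle-equivalence checks
enumerate 100
random instances with at most 3 alleles per locus and 2 loci, and
Monte-Carlo cross-checks use 100,000 genotype draws.  The null calibration
of the tests uses 1,000 replicates with four groups of 15 (ANOVA) and two
groups of 40 (KS); the KS group size matters because the discrete null
distribution of $D$ makes the asymptotic test's exact level wobble around
the nominal 5% — 40 per group sits at 4.85%.

## Limitations

* Coverage assumes Hardy-Weinberg equilibrium and cross-locus independence;
  real populations deviate (admixture, LD between B and C).
* Two-field allele resolution merges variants that can differ in binding.
* The ethnic/ancestry dimension inside countries is out of scope: income is
  attached at country level, and within-country heterogeneity (which is
  substantial) is invisible to the audit.
* The asymptotic one-sided KS p-value is anti-conservative below ~10 values
  per group; the report flags, but does not replace, those cases.
* External predictors enter only through the file/table adapter contract;
  the package does not run or reimplement any neural network.
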
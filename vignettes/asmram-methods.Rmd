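---
title: "Methods: peak-RAM prediction, flavor allocation, and core-microbiome rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-RAM prediction, flavor allocation, and core-microbiome rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmram)
```

This vignette is the package's account of its own methods: the models and
rules it implements, the conventions it had to pin down where common usage
varies, and what its synthetic-data tests do and do not establish. It states
no empirical result that the test suite does not itself compute.

## 1. Spectrum features

All memory prediction rests on the k-mer spectrum of a read set: the mapping
from occurrence frequency $f \ge 1$ to $c_f$, the number of distinct
canonical k-mers observed exactly $f$ times. Canonical means the
lexicographically smaller of a k-mer and its reverse complement, so counting
is strand independent — the same convention as the widely used disk-based
k-mer counters. Windows containing a non-ACGT symbol are skipped; reads
shorter than $k$ contribute nothing. Counting is exact (hash map in C++);
probabilistic or streaming counting is out of scope at the dataset sizes
this package targets in-process. Defaults use $k \in \{13, 21, 71\}$: a
small $k$ that saturates quickly (its distinct count is bounded by
$4^{13}/2$), the classic mid-range $k$, and a long $k$ close to typical
assembler upper k-mer sizes.

From a spectrum, with $v_f = f\,c_f$ the total k-mer mass in bin $f$, the
package reports: total mass $\sum v_f$, distinct count $\sum c_f$, and the
mean, population SD and maximum of $v_f$ **over occupied bins**. The
averaging set for these three is genuinely underdetermined in common usage;
occupied histogram bins are the natural reading of a two-column histogram
file, and the convention is applied consistently in both the implementation
and the independent test oracle. Two tail statistics summarize the spectrum
shape: `q5_sum`, the mass of the largest low-frequency prefix of bins whose
cumulative mass stays within 5% of the total, and `q95_sum`, the analogous
high-frequency suffix. Defined this way (mass-weighted, capped), `q5_sum`
tracks the number of rare k-mers — sequencing errors plus low-abundance
community members — which is exactly the quantity relevant to de Bruijn
graph size. A bin-count-weighted alternative was rejected because a single
enormous $f{=}1$ bin would then saturate the statistic.

GC content is $(\#G + \#C)/(\#A+\#C+\#G+\#T)$ with ambiguous symbols
excluded from both numerator and denominator (they still count toward read
lengths). Gzip input is detected by magic bytes, not file extension. A
sequence-diversity index computed by an external redundancy tool may be
attached as an optional covariate; a missing value is recorded as missing
(`NA`), never as zero.

## 2. Regression pipeline

**Screening.** Features correlate with peak RAM or they are dropped:
Pearson $r > 0.6$ with two-sided $P < 0.05$ (t transform), signed by
default — every feature expected to matter correlates positively with RAM —
with an `absolute` switch for exploratory use. Constant features have
undefined $r$ and are dropped with a warning.

**Families.** Five regressor families are registered: ordinary linear
regression, a single greedy CART-style tree, a bootstrap random forest,
extremely randomized trees, and a voting average of linear + both forests.
The tree builders are the package's own C++: no tree-regression package is
assumed present, and the split rules are the methodologically relevant
difference between the families — the extremely randomized variant draws the
split threshold *uniformly at random* between the node minimum and maximum
of each candidate feature instead of optimizing it, decorrelating trees and
reducing ensemble variance. A support-vector family is not included: no SVR
implementation is available in the dependency set and re-implementing one is
out of proportion to its role as one baseline among several; the registry is
extensible. Tree defaults follow the common library defaults: 100 trees,
`min_samples_leaf = 1`, all features per split. Impurity importances are
variance reductions summed per feature and normalized.

**Comparison and tuning.** All families are evaluated by k-fold
cross-validation (default 10) on *one shared random fold partition*, so
per-family mean and SD of fold RMSEs are directly comparable; selection is
lowest mean, ties broken by lowest SD, then input order. Grid search is an
exhaustive Cartesian product evaluated by the same CV criterion with
duplicate grid points deduplicated. All stochastic steps take explicit
integer seeds and restore the caller's RNG state.

**Bias calibration.** The point prediction is inflated by a bias $b$ so
that requesting $\max(0,\hat y) + b$ rarely under-allocates. $b$ is the
upper endpoint of a seeded bootstrap (1000 resamples) 95% percentile CI of
an error statistic on a holdout split (default 10% of rows, at least 10)
disjoint from the training rows. Two statistics are offered:

* `error_quantile` (default): the 0.9 quantile of the signed error
  $y - \hat y$. This guards the per-dataset event "observed exceeds
  request" directly: before the CI safety margin, roughly 90% of datasets
  fall below prediction + bias.
* `mean_abs_error`: the mean absolute error. For symmetric residuals its CI
  upper endpoint sits near one SD of the error distribution, giving only
  ~84% per-dataset coverage ($\Phi(1.0)$); it is retained because a CI of
  the mean generalization error is what one naturally reports, but it was
  **not** made the default precisely because it cannot meet a 90%
  non-under-allocation goal. This is the one place the package deliberately
  departs from the most literal reading of its design brief; the arithmetic
  above is the reason.

**Persistence.** Bundles (family, hyperparameters, selected features, bias
and its CI, the full regressor state, training metadata) serialize to plain
JSON at 17 significant digits, which round-trips IEEE doubles exactly: a
loaded bundle reproduces the saved bundle's predictions identically. A
format-version field makes incompatible files fail loudly.

## 3. Flavor allocation

A flavor catalog is an ordered list of RAM tiers (default 14/29/58/113 GB —
user configuration in any real deployment). The request maps to the
smallest flavor with `ram_gb >= required_gb` (boundary inclusive); an
out-of-memory failure escalates to the next tier until success or
exhaustion. An attempt succeeds iff the flavor's RAM covers the dataset's
true peak, with no extra overhead margin — any reserve can be folded into
the catalog itself. Fleet accounting sums the RAM of *every* attempted
flavor for a dataset (failed attempts occupied a machine); totals cover
successful datasets only, with exhausted datasets counted and reported
separately rather than silently priced. Three policies are comparable:
fixed start (one flavor for everything), optimum (smallest sufficient
flavor, an oracle that needs the true peak), and predicted. Two structural
facts follow from the accounting and are asserted as properties: the
optimum policy's total is a lower bound for every policy, and a predicted
policy fed the true peaks with zero bias reproduces the optimum exactly.

## 4. Core-microbiome rules

Presence is abundance strictly greater than zero by default: the upstream
mapping stage that produces such tables already enforces genome-coverage
and identity thresholds, so a non-zero entry is a vetted detection; the
threshold is configurable for tables without that guarantee.

* **Depth filter:** samples below $Q_1 - 1.5\,\mathrm{IQR}$ of the
  genome-coverage percentage are removed (strictly below; quartiles by
  linear interpolation, R type 7 — the convention is not universal, and the
  worked example in the tests pins it: coverages
  `20 60 70 75 80 85 90 95` give cutoff 39.375). Fewer than four coverage
  values, or none at all, disables filtering with a warning.
* **Global core:** present in strictly more than 60% of all samples;
  presence in exactly 60% does not qualify.
* **Regional core (range-through):** stage 1 keeps, per country, species
  present in strictly more than 90% of that country's samples; stage 2
  declares a species a regional member when it passes stage 1 in at least
  80% of the region's countries — inclusive at the boundary, since a
  membership listed at exactly the 80% mark must qualify. Both thresholds
  are parameters. Countries contributing no samples are excluded from
  denominators with a warning.
* **Ubiquity–abundance curves:** ubiquity of species $s$ at threshold $t$
  is the percentage of samples with abundance $\ge t$; the default grid is
  50 log10-spaced steps across the observed positive range, and the plot
  shows species reaching 50% ubiquity, colouring those above 60%. Curves
  are non-increasing in $t$ by construction.
* **Top-abundance share:** the percentage of samples in which a species is
  the *unique* maximum; ties credit nobody and are warned about, so shares
  sum to at most 100%.

## 5. The synthetic world

The generators state one fixed world rather than tunable difficulty dials.

*Read sets:* i.i.d. genomes at a chosen GC; reads drawn proportionally to
explicit or lognormal ($\sigma = 1$) abundance weights, uniform start,
50/50 strand, substitution-only errors at 0.1% (Illumina-like; indels would
not change which statistics are exercised), constant quality string since
no feature reads qualities.

*Training tables (default n = 300, noise SD = 2 GB):* dataset size is
lognormal around 5 Gbp; a latent community k-mer richness (lognormal around
$2\times10^9$) saturates with depth to give the distinct 21-mer count, the
71-mer count sits 25–35% above it, and the remaining candidate features are
derived with realistic couplings plus independent nuisance columns. The
response is $4 + 12\cdot10^{-9} d_{21} + 9\cdot10^{-9} d_{71} +
\mathcal N(0, 2)$ GB, placing peaks in the 10–130 GB band a short-read
metagenome assembler occupies at these depths; the meta-sensitive mode
scales the coefficients by 1.4 (wider k-mer range costs more memory). A
`via_reads` mode measures features from actually simulated reads at toy
scale instead of sampling them.

*Abundance fixtures:* three regions with 3–5 countries and 10 samples per
country; planted global species in every sample; planted regional species
in all samples of 80% of their region's countries and at 20% presence
elsewhere (chosen so their expected global prevalence stays safely below
the 60% rule for any seed); 30 background species at 30% presence.
Abundances are lognormal, an order of magnitude higher for the global core.

What a green test establishes: exact agreement of the counting and rule
machinery with independent oracles, recovery of planted structure, and the
allocation invariants. What it does not establish: that real assembler
memory is linear in distinct k-mer counts (the generators assume the
relationship the model family can represent), that real abundance tables
separate core from background this cleanly, or anything about mapping,
binning or dereplication quality upstream of the abundance table.

## 6. Numerical and edge-case choices

* Population (not sample) SD for the per-bin spectrum statistic; sample SD
  for fold RMSEs (a dispersion estimate over folds).
* Tree node splits send `x < threshold` left, both in training and
  prediction; a node with no valid split (constant features, or leaf-size
  constraints unmeetable) becomes a leaf. Node purity is tested against an
  absolute $10^{-12} n$ floor on the node SSE.
* The C++ RNG is a fixed Mersenne Twister with hand-rolled uniform deviates,
  so forests are byte-identical across standard-library implementations;
  per-tree seeds derive from the user seed by a fixed multiplicative hash.
* Empty spectra (all reads shorter than k) are representable and error only
  when statistics are requested. Zero-count histogram lines are dropped on
  read; malformed lines fail with their line number.
* `select_flavor` errors when the requirement exceeds the largest flavor
  (an interactive user should see the problem); the fleet simulator instead
  starts such datasets on the largest flavor and reports them exhausted,
  because a replay over hundreds of datasets must not abort on one outlier.
* All-zero abundance columns tie every species at 0 and credit no one in
  top-share computations.

## 7. Known limitations

Exact counting keeps every distinct k-mer in memory, which bounds in-process
read-set size; histogram files from an external counter are accepted for
real datasets. The model transfers across assembler parameter settings only
by retraining (one table, one mode). The voting family averages its members
without weighting. Regional rules treat countries as equal-weight units
regardless of sample count, which is the intent of the range-through
approach but worth remembering when country sampling is very uneven.
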
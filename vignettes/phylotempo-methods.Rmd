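---
title: "Models and methods behind phylotempo"
author: "phylotempo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylotempo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotempo)
```

# Scope

phylotempo implements an evolutionary-transcriptomics workflow for
replicated developmental time courses of a single focal species: gene-age
(phylostratum) assignment by Dollo parsimony, low-expression filtering and
consensus co-expression clustering with an unassigned remainder,
transcriptome age index (TAI) profiles with a permutation-based reductive
hourglass test, per-stratum expression variability and level summaries,
and Fisher-exact enrichment of phylostrata within clusters. A pair of
simulators generates phyletic patterns and expression matrices with known
ground truth so that every stage can be validated end to end.

# Gene ages by Dollo parsimony

The species tree must arrive rooted, with one designated focal leaf;
rooting is never guessed. The chain of ancestors on the root-to-focal path
plus the focal leaf itself defines the phylostrata, ranked 1 (root,
pan-eukaryotic origin) to S (focal-species-specific). Throughout the
package stratum 1 is the *oldest* class; the writer can emit the reversed
numbering for interoperability with tables that count the other way.

Under Dollo parsimony a gene family is gained exactly once and may be lost
arbitrarily often. For a presence/absence pattern that includes the focal
species, the unique most-parsimonious gain node is then the last common
ancestor (LCA) of all carrier species: placing the gain at any strict
ancestor of the LCA forces at least one additional loss. Because the focal
species is always a carrier (orthogroups are derived from its proteome),
the gain node lies on the root-to-focal chain and maps directly to a
stratum rank. Genes with no orthogroup at all are classified
focal-specific (stratum S). The test suite checks this LCA shortcut
against an exhaustive enumeration of all single-gain reconstructions on
small trees.

A consequence worth keeping in mind when interpreting results: stochastic
losses can only *shrink* the observed carrier set, so inferred ages are
never older than the truth — the error is one-signed toward the focal
species, and it grows with the loss rate. The package's Dollo simulator
makes this bias measurable.

# The synthetic data generators

`simulateSpeciesTree()` builds a ladderized tree in which each of the
S − 1 internal chain nodes sprouts a clade of outgroup species; the
default spreads 30 outgroups over a 10-stratum chain, the shape typical of
phylostratigraphic designs that compare one proteome against a ladder of
increasingly distant outgroups.

`simulateDolloMatrix()` draws each orthogroup's gain stratum from a
weight vector (uniform by default), then loses the family independently
on every branch strictly below the gain node with a constant per-branch
probability, losses being inherited by whole subtrees; the gain-to-focal
path is protected so the focal species always carries the family. A
constant per-branch Bernoulli loss model was chosen over a
rate-times-branch-length model because the trees used in this setting
carry no meaningful branch lengths.

`simulateExpression()` emulates the features of a coenocytic-growth /
cellularization style time course that matter for the downstream methods:

* **design** — 10 timepoints at 6-hour intervals (12 h to 66 h), 2
  replicates; both are adjustable;
* **low expression** — a fraction (default 0.58, matching the roughly
  58% of genes below the 0.5-tpm filter in data of this kind) receives
  baselines with expected mean well under 0.5 tpm;
* **temporal programs** — a configurable set of sharply activated
  unit-scale profiles (default five Gaussian-bump activation waves spread
  across the course), each populated by a planted member list; remaining
  genes are flat;
* **noise** — multiplicative log-normal measurement noise (default
  sigma 0.25 on the log scale), the standard non-negativity-preserving
  choice for expression magnitudes;
* **age-by-phase interaction** — for gene *i* at timepoint *t* the mean is
  `base_i * profile(t) * (1 + delta * w(age_i) * m(t))` with `m(t)` the
  mid-phase indicator and `w` mapping the oldest stratum to +1 and the
  youngest to −1 linearly. A positive `delta` boosts old genes and damps
  young genes mid-course, producing an hourglass-shaped TAI profile; a
  negative `delta` plants the inverse; 0 is an exact null. Means driven
  negative by extreme deltas are clipped at zero with a warning;
* **replicate shift** — the replicate-2 program can lag by a whole number
  of timepoint slots, emulating a culture that runs behind its sibling;
* **age-biased clusters** — optionally the latest-activated cluster is
  drawn preferentially from the youngest strata and the mid-course
  cluster from the oldest, planting the young-late / old-mid enrichment
  pattern consistent with the hourglass.

The generator is a stand-in: real expression data have gene-length and
library-composition artefacts, count noise at low abundance, and
correlated gene modules beyond the planted clusters. Passing tests on
simulated data therefore demonstrate the correctness and calibration of
the algorithms under the stated model, not the biological validity of any
particular dataset.

All draws in both simulators are governed by a single integer seed and are
fully deterministic given it.

# Expression processing

**Filtering.** Genes whose arithmetic mean tpm over *all* samples of both
replicates is strictly below the threshold (default 0.5 tpm) are removed;
a gene at exactly the threshold is retained. Filtering never alters
retained values.

**Replicate alignment.** When one replicate's developmental program lags,
its timepoint labels can be shifted by a whole number of sampling
intervals; samples falling outside the common window are dropped and
logged. The shift is a user decision made after inspecting the sample
dendrogram, as is conventional.

**Sample dendrogram.** Samples are compared by Spearman correlation over
genes; the distance between two samples is the Euclidean distance between
their rows of the correlation matrix, clustered with average linkage.
Correlations against a constant (zero-variance) sample are undefined and
are set to 0 with a warning. Average linkage was fixed as the default
since the choice is not critical for the phase-separation use of the tree.

**Normalization.** Co-expression clustering operates on per-gene
standardized profiles: `log2(tpm + 1)` followed by centring and scaling
to unit standard deviation. This scale-free transform is the common
choice for time-course profile clustering; zero-variance genes cannot be
standardized and are excluded (and recorded) rather than imputed.

# Consensus co-expression clustering

The defining behaviour required here is *tight clusters plus an
unassigned remainder*: most genes should end up in no cluster. The
package implements a transparent consensus scheme:

1. k-means base learners (k-means++ seeding, recorded seeds) are run over
   a grid of k values (default 5–15) with several random restarts each
   (default 20), on the normalized profiles with replicates concatenated
   as additional dimensions;
2. a gene-by-gene co-assignment frequency matrix is accumulated;
3. clusters are extracted greedily: seed at the remaining pair with the
   highest frequency, grow by admitting the gene with the highest mean
   frequency to the current members while that mean stays at or above the
   consensus threshold tau (default 0.7), and discard extracted groups
   smaller than the minimum size (default 10).

The greedy quality-threshold extraction was chosen over cutting a
dendrogram of the consensus matrix and over connected components of the
thresholded co-assignment graph: components chain unstructured genes
through incidental intermediates into spurious clusters, whereas the
mean-frequency admission rule keeps clusters internally tight and leaves
non-conforming genes unassigned. Raising tau makes admission strictly
harder, so the number of assigned genes does not grow with tau; this
monotonicity is exercised in the tests at tau in {0.5, 0.7, 0.9}.

Replicate robustness is quantified by re-clustering replicate 1 alone,
replicate 2 alone, and the per-timepoint average, and reporting pairwise
adjusted Rand indices over genes assigned in both runs of a pair. Note
that the averaged run shares data with each replicate; only the
replicate-1-versus-replicate-2 comparison is between independent
measurements.

# TAI and the reductive hourglass test

For each sample the transcriptome age index is the expression-weighted
mean phylostratum,

$$\mathrm{TAI} = \frac{\sum_i ps_i \, e_i}{\sum_i e_i},$$

with $ps_i$ the integer stratum of gene $i$ (1 = oldest) and $e_i$ its
expression in tpm. Higher TAI means a transcriptionally younger state.
TAI is computed on the tpm values of the filtered ("expressed") gene
set — the formula's $e_i$ is an expression level, not a normalized
profile — and separately per replicate, so each replicate yields its own
profile and test. The index is exactly invariant to rescaling a sample's
column and is bounded by the stratum range; both identities are tested.

The reductive hourglass test partitions the ordered timepoints of a
replicate into early, mid and late phases (default: timepoints 1–2, 3–6
and 7–10) and uses the one-sided statistic

$$D = \min\big(\overline{\mathrm{TAI}}_{early} - \overline{\mathrm{TAI}}_{mid},\;
\overline{\mathrm{TAI}}_{late} - \overline{\mathrm{TAI}}_{mid}\big),$$

positive exactly for a high–low–high profile. The null distribution is
obtained by permuting the gene-to-stratum labels while keeping the
expression matrix fixed, which preserves the expression covariance
structure under the null of no age–expression association. Two p-values
are always reported: the upper tail of a Gaussian fitted to the permuted
statistics (the convention of this test family) and the empirical
$p = (1 + \#\{D_{perm} \ge D_{obs}\})/(B + 1)$. The empirical p-value is
the authoritative one in all package tests; the Gaussian value is a
smooth summary that agrees with it in rank.

Numerical choices: comparisons of permuted against observed statistics
use an absolute tolerance of 1e-10 (TAI lives on the order-1..S stratum
scale), which also defines the degenerate-null guard — when the permuted
statistics have essentially zero spread (for example when all genes share
one stratum), the Gaussian p is undefined and only the empirical p is
reported, with a flag.

Calibration and power are part of the test suite and the acceptance
script: under 500 null simulations the rejection rate at the 0.05 level
must fall inside the exact binomial 95% interval [0.033, 0.071], and a
planted effect of delta = 0.5 at noise 0.1 must reach empirical p < 0.01
in at least 95 of 100 simulations. The suite uses 200 permutations per
null simulation and 1000 elsewhere; these sizes were chosen as the
smallest that leave the binomial check meaningful at the 0.05 level.

# Variability and enrichment summaries

Per-gene variability is the coefficient of variation across timepoints
(sample standard deviation over mean, n − 1 denominator), computed on tpm
averaged across replicates per timepoint and binned by stratum;
zero-mean genes have no defined CV and are excluded with a count. Mean
expression by stratum is summarized the same way.

Enrichment uses Fisher's exact test. One-sided p-values are the
enrichment-direction tail P(X ≥ a); two-sided p-values sum all table
probabilities not exceeding the observed one; the reported odds ratio is
the sample odds ratio ad/bc (infinite when bc = 0 with a, d positive).
For the stratum-by-cluster family the gene universe is *all* filtered
genes, assigned or not, and one-sided p-values are Benjamini–Hochberg
adjusted across the whole family by default (raw values are always kept;
the adjustment can be disabled). Sidedness and correction are deliberate
package defaults rather than universal conventions, and both raw and
adjusted values appear in every output table.

# Problem sizes and determinism

The simulation-based checks run at desk scale by design: 2,000 genes for
age-recovery and hourglass studies, 1,000 genes with five planted
100-gene clusters for clustering recovery, 500 null datasets for
calibration, 1,200 genes for the end-to-end study. These sizes keep every
stage's sampling error well below the decision margins used in the tests
while remaining quick on a single CPU. Every stochastic step — both
simulators, k-means restarts, permutation tests — flows from explicit
integer seeds, and identical seeds reproduce results bit for bit.

# Known limitations

* The Dollo model ignores branch lengths and rate variation; it cannot
  express lineage-specific loss rates.
* The consensus scheme does not estimate the number of clusters; it
  reports whatever tight groups survive the threshold, which is the
  intended behaviour but means cluster counts are not comparable across
  datasets with different noise levels.
* TAI weights by relative expression, so a handful of highly expressed
  genes can dominate a sample's index; the permutation null accounts for
  this, but point estimates of TAI should be read with that weighting in
  mind.
* The expression generator does not simulate counts, gene lengths,
  library-size artefacts, alternative splicing or non-coding RNA biology.
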
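---
title: "Methylation landscapes, relatedness networks and cell-type decomposition: models and design choices"
author: "MethylScape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation landscapes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylScape)
```

# Scope

MethylScape implements the analysis chain used to place tumor entities in a
DNA methylation "landscape" from Illumina EPIC-style beta-value matrices:
detection-p sample QC, probe filtering, top-variance CpG selection, t-SNE
embedding, hierarchical and agglomerative consensus clustering with a
consensus-degree group comparison, a moderated-t differential methylation
statistic, all-pairs DMP counting, a DMP-count-binned relatedness network
over diagnosis groups, TSS-based pathway direction calls, and reference-based
cell-type fraction estimation. A synthetic cohort generator with planted
ground truth ties the stages together so every claim the package makes about
itself is testable.

This vignette explains the models, the defaults and why they were chosen,
the numerical corner cases, and what validation on synthetic data does and
does not establish.

# The data model

A cohort is a `MethylExperiment` (extending `SummarizedExperiment`): a
probe × sample matrix of beta values (methylated fraction, in $[0,1]$) in
assay `beta`, an optional matrix of detection p-values in assay `detP`,
probe annotation (chromosome, position, gene symbol, TSS flag) in `rowData`
and the sample sheet (group label, material, grade, mutation status) in
`colData`. Validity enforces unique identifiers and value ranges; readers
reject malformed input with the offending probe/sample named rather than
silently coercing. Matrix orientation is fixed to probes-in-rows, the
array-export convention. Genome coordinates are 1-based.

# Sample QC and feature selection

A sample fails QC when the fraction of probes with detection $p >$
`pThreshold` (default 0.01) exceeds `maxFailFraction`. The default cap is
0.10: a conventional array-QC cutoff that, for instance, excludes a sample
failing at 14% of CpG sites. Exclusion is monotone in the cap — lowering it
never readmits a sample.

The landscape feature space is the $k$ probes with the largest
across-sample standard deviation of beta values (default $k = 10{,}000$).
The SD is computed on the beta scale, the convention of methylation
classifier landscapes; the statistical testing scale is configurable
separately. Ties are broken lexicographically by probe id so the selection
is deterministic, and the selection is idempotent.

M-values are provided via `betaToM()` ($m = \log_2 \beta/(1-\beta)$ with
clipping at `epsilon` so the transform is finite); testing on M-values is
available through `scale = "m"` in `pairwiseDMPCounts()`.

# The moderated differential methylation statistic

For each probe $g$ the two-group comparison uses the pooled within-group
variance $s_g^2$ on $d = n_A + n_B - 2$ degrees of freedom, shrunk towards
a common prior by empirical Bayes:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
\qquad t_g = \frac{\bar x_{B,g} - \bar x_{A,g}}
{\tilde s_g \sqrt{1/n_A + 1/n_B}},$$

with $t_g$ referred to a t distribution on $d_0 + d$ degrees of freedom.
The prior $(d_0, s_0^2)$ is fitted by method of moments on the log
variances: under the scaled-F model, $\log s_g^2$ has known digamma/trigamma
mean and variance, and matching the empirical moments requires inverting
the trigamma function, done by Newton iteration. When the excess variance
of the log variances is non-positive the prior degrees of freedom are
infinite (all probes share one variance). Setting `priorDf = 0` disables
shrinkage and recovers the ordinary pooled t exactly — this limit, and
agreement of the fitted prior with an established reference implementation,
are both asserted in the test suite.

Degenerate inputs: if *every* probe has zero within-group variance the
statistic is undefined; the function then falls back to exact-equality
calls ($p = 0$ where group means differ, $p = 1$ otherwise) with a warning.
Fewer than 50 positive-variance probes disables shrinkage with a warning,
since a two-parameter moment fit on so few variances is unreliable.

A probe is a DMP when its Benjamini–Hochberg adjusted p-value is below
0.01 **and** its absolute group difference exceeds 0.3 (strict
inequalities). On the beta scale the effect reads directly as a
30-percentage-point methylation difference, which is how the "logFC"
convention of array pipelines behaves for beta input. BH adjustment is the
classic step-up with cumulative-minimum enforcement, applied per pairwise
comparison (the per-contrast convention), not jointly across all pairs. The
step-up itself is implemented in the package and cross-checked against both
a brute-force oracle and `p.adjust` in the tests.

`pairwiseDMPCounts()` applies the statistic to every unordered pair of
groups — 23 groups evaluate $\binom{23}{2} = 253$ pairs — skipping groups
with fewer than two samples (with a warning) rather than merging them.

# Landscape construction

*t-SNE.* `tsneEmbed()` uses perplexity 30, 1,000 iterations and PCA
initialisation to 50 components, with a mandatory seed recorded alongside
the coordinates. Whether groups "separate" is quantified, not eyeballed:
`knnPurity()` reports the mean fraction of a sample's k nearest embedded
neighbours sharing its label.

*Hierarchical clustering.* Distance is $1 -$ Pearson correlation between
samples, linkage average — the standard choice in methylation-classifier
work. Correlation distance makes the tree invariant to per-sample affine
rescaling, which the tests assert on random instances.

*Consensus clustering.* `consensusCluster()` repeats the base clusterer on
B random subsamples (without replacement) of a fraction of the samples
(defaults $B = 500$, 80%), cuts each tree at $k$ clusters (default: the
number of sample-sheet groups) and records, per sample pair, co-clustering
occurrences divided by co-draw occurrences. Pairs never co-drawn are NA,
not 0 — absence of evidence is flagged as missing.

*Consensus-degree comparison.* For a reference group R,
`consensusDegreeTest()` compares the within-R consensus values (upper
triangle only, to avoid duplicating symmetric entries) against the R-to-g
values for every other group g with the two-sided Mann–Whitney test
(the conventional nonparametric two-sample choice), BH-adjusted across
groups. A non-significant result means g's samples co-cluster with R as
strongly as R does with itself — the signature of a sibling entity. When
every consensus value is tied (e.g. an all-ones matrix) the normal
approximation degenerates; the distributions are then identical and p is
reported as 1.

# The relatedness network

Edges between groups are drawn from the pairwise DMP counts using five
count bins — $\{0\}$, $[1, 999]$, $[1000, 4999]$, $[5000, 9999]$,
$[10000, 14999]$ — where fewer DMPs mean stronger similarity (a 0-count
edge is the strongest possible tie). Counts of 15,000 or more draw no
edge; this no-edge rule is inferred from the bin list ending at 14,999
together with the notion of groups "remaining disconnected". A single graph
carries bin labels on its edges, which reproduces both the
one-network-per-threshold and the single-multilevel-network reading of the
construction. Groups left without any edge are annotated with their
closest connection: the minimum-count partner and the exact count, keeping
*all* tied partners rather than picking one arbitrarily. Layout is left to
consumers (GraphML / edge-list export); the package emits structure only.

# TSS pathway direction calls

DMPs between a lesion and its normal tissue are restricted to probes with
the manifest TSS flag (modelled on the TSS200/TSS1500 categories of array
manifests), mapped to genes, and labelled: hypermethylated TSS probes →
gene *inhibited*, hypomethylated → *activated*. The contrast orientation
is never guessed: callers state which group is the lesion (the `flip`
argument / pipeline config). Genes with TSS probes of conflicting sign are
assigned by the sign of the mean delta and reported as conflicting.
Enrichment against a GMT collection is one-sided hypergeometric
over-representation ($P(X \ge k)$, including the observed overlap) with BH
across sets; the universe is the genes with at least one TSS probe
surviving probe filters, not the whole genome, and sets are intersected
with the universe before testing — the universe defines the margins of the
test.

# Cell-type decomposition

Gene activity is derived from methylation as $1 -$ mean TSS beta per gene
— the simplest monotone promoter-methylation-to-expression surrogate,
exposed as a pluggable transform. Fractions solve

$$\min_f \|S f - a\|^2 \quad \text{s.t. } f \ge 0,\ \textstyle\sum_i f_i = 1$$

per sample. The production solver augments the system with a heavily
weighted sum-to-one row, solves by nonnegative least squares and
renormalises; an exact equality-constrained active-set solver is kept as
an internal cross-check, and the two agree to $10^{-6}$ in the test suite,
as does a 0.01-step grid search on two-type problems. The sum-to-one
constraint makes fractions invariant to a common positive rescaling of
activity and signature. Group comparisons of fractions follow the
normality-gated rule: Shapiro–Wilk per group at $\alpha = 0.05$; both
normal → unpaired pooled-variance t-test, otherwise Mann–Whitney; p-values
map to the conventional star categories (\*, \*\*, \*\*\*, \*\*\*\* at
0.05, 0.01, 0.001, 0.0001). Constant-valued groups, where Shapiro–Wilk is
undefined, fall to Mann–Whitney.

# The synthetic cohort generator

`generateCohort()` emulates what the downstream stages need from an
EPIC-style cohort, with ground truth:

- **Baseline:** each probe's mean is drawn from a 50/50 mixture of
  Beta(2,18) (unmethylated mode) and Beta(18,2) (methylated mode), clipped
  to $[0.01, 0.99]$ — the bimodal marginal shape of real array betas.
- **Planting:** an entry shifts one group's mean by `delta` beta units on
  n fresh probes, in the direction that keeps the mean inside
  $[0.01, 0.99]$; shifts are additive across entries, and an entry may
  clone another's probes and shifts (`sameAs`), which creates exact
  distributional siblings with zero true DMPs between them. Ground truth
  lists, per group pair, the probes whose true means differ.
- **Noise:** per-sample Gaussian noise with sd `noiseSd` (default 0.1) on
  the logit scale, mapped back through the logistic — values stay in
  $(0,1)$ and the beta-scale distortion of planted differences is second
  order at this noise level.
- **Detection p:** passing samples draw $p < 0.01$ everywhere; designated
  bad samples exceed 0.01 at exactly the configured fraction of probes
  (rounded to $1/n_{\text{probes}}$).

The default configuration (`defaultSyntheticConfig()`) is 20,000 probes ×
150 samples in six groups modelled on a pancreato-ovarian landscape, with
one pair of exact siblings (MCN_P / MCN_L), planted deltas of 0.35, and
one QC-failing sample at a 14% failure fraction. The scale is large enough
that top-10,000 selection is a real subset and small enough for
minutes-scale validation; planted counts scale proportionally if
`nProbes` is overridden.

**What the generator does not emulate:** Infinium I/II probe-type
chemistry bias, raw IDAT intensities, FFPE-vs-frozen batch effects (no
batch term is included, since the emulated study describes no batch
correction), spatial correlation along the genome, and realistic
biological within-entity heterogeneity beyond i.i.d. logit-normal noise.
Passing the synthetic validation therefore establishes the correctness of
the algorithms under the planted model — not that real cohorts will
separate as cleanly, nor that the QC or thresholds are optimal for any
particular dataset.

**Evaluating structure recovery with sibling groups.** Two groups planted
with identical shift sets share a distribution; no clustering or embedding
method can split them, and any split would be noise. Structure-recovery
checks therefore score against sibling-merged labels and cut dendrograms
at the number of *distinct planted distributions* (five for the default
cohort), which is the mathematically correct ground truth for that
configuration. The consensus-degree test, by design, is the component that
detects the siblings as such.

# Numerical choices and degenerate inputs

- Trigamma inversion: Newton iteration with the asymptotic guards
  $1/\sqrt x$ for tiny and $1/x$ for large targets; convergence tolerance
  $10^{-8}$ on the relative step.
- Top-SD ties: lexicographic by probe id. Bin boundaries: half-open
  integer intervals exactly as printed; 15,000 is the first unbinned count.
- `betaToM` clips at `epsilon` (default $10^{-3}$); the round trip
  m→beta→m is identity to $10^{-12}$ away from clipping.
- NNLS augmentation weight: $10^4 \times \max|S|$, making the sum-to-one
  violation before renormalisation $O(10^{-8})$.
- Probes with > 10% missing values are dropped at load (missingness is
  undocumented in the emulated study; the cap is configurable).
- Consensus pairs never co-drawn: NA, and the degree test drops them.

# Problem sizes used in validation

The shipped validation runs on cohorts of 20,000 probes × 150 samples for
the landscape checks (consensus B = 200–500), 23 groups × 4 samples ×
1,500 probes for the all-pairs count, 20,000 probes for null calibration,
5,000 probes for power, and 200 simulated mixtures for deconvolution —
sizes chosen so each property is measured meaningfully at minutes-scale
total runtime.

# Known limitations

- The package consumes deposited beta matrices; raw IDAT preprocessing,
  normalisation and probe-type correction are upstream and out of scope.
- The moderated statistic covers two-group contrasts only; no covariates,
  no region-level (DMR) aggregation.
- The activity transform ($1 -$ mean TSS beta) is a deliberate simple
  surrogate; the decomposition is a constrained-least-squares formulation,
  stated as such rather than as a reproduction of any specific published
  solver.
- Enrichment requires the caller's GMT; no pathway database is bundled.
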
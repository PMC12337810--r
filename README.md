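# MethylScape

Placing tumor entities in a DNA methylation landscape.

Rare lesions are often classified by where their genome-wide DNA
methylation profile falls relative to better-known entities. MethylScape
implements that analysis chain for Illumina EPIC-style beta-value
matrices, for epigenomics researchers who have deposited-level data
(beta values + detection p-values + sample sheet + manifest annotation)
and want a tested, scriptable pipeline rather than a one-off notebook:

- **QC & features** — sample exclusion on detection-p failure fractions,
  probe filtering, selection of the top-k CpGs by standard deviation.
- **Landscape** — t-SNE embedding (with a quantitative kNN label-purity
  readout), hierarchical clustering (1 − Pearson, average linkage), and
  agglomerative consensus clustering with a consensus-degree test that
  identifies "sibling" entities statistically.
- **Differential methylation** — an internally implemented moderated t
  statistic with empirical-Bayes variance shrinkage. Per probe g:

      s̃²_g = (d₀·s₀² + d·s²_g) / (d₀ + d)
      t_g  = (x̄_B − x̄_A) / (s̃_g · √(1/n_A + 1/n_B))   ~  t(d₀ + d)

  with the prior (d₀, s₀²) fitted by method of moments on log variances.
  A probe is a DMP at BH-adjusted p < 0.01 and |Δβ| > 0.3.
- **Relatedness network** — all-pairs DMP counts binned into edges
  ({0}, 1–999, 1,000–4,999, 5,000–9,999, 10,000–14,999; ≥ 15,000 = no
  edge), with exact-count closest-connection annotation for groups left
  disconnected. Fewer DMPs = stronger similarity.
- **TSS pathways** — hypermethylated TSS probes → gene inhibited,
  hypomethylated → activated; hypergeometric over-representation against
  any GMT collection.
- **Deconvolution** — promoter-methylation-derived gene activity
  (1 − mean TSS beta) decomposed on a cell-type signature by sum-to-one
  constrained nonnegative least squares, with normality-gated group
  comparisons (Shapiro–Wilk → t-test or Mann–Whitney).
- **Synthetic cohorts** — an EPIC-like generator with planted group
  structure, planted per-pair DMP sets, designated QC-failing samples and
  known cell-type mixtures, so every stage is validated against ground
  truth.

See the vignette (`vignettes/methylation-landscapes.Rmd`) for the models,
defaults, and the reasoning behind every tunable.

## Worked example

Generate a small cohort with a planted sibling pair (MCN_P and MCN_L carry
identical methylation shifts, so zero probes truly differ between them),
run QC, count DMPs across all pairs, and build the relatedness network:

```r
library(MethylScape)

cfg <- syntheticConfig(
  nProbes = 4000,
  groups  = c(MCN_P = 10, MCN_L = 8, mBOT = 10, NormPancreas = 12),
  plantedDMPs = list(
    list(pair = c("NormPancreas", "mBOT"),  n = 500, delta = 0.35),
    list(pair = c("NormPancreas", "MCN_P"), n = 450, delta = 0.35),
    list(pair = c("NormPancreas", "MCN_L"), sameAs = 2)),   # clone: siblings
  noiseSd = 0.1, badSamples = c(MCN_P_01 = 0.14), seed = 7)

cohort <- generateCohort(cfg)
me <- cohort$experiment

qc <- sampleQC(me)                      # detection p > 0.01, cap 10%
print(qc)
#> Sample QC: detection p > 0.01 in more than 10% of probes
#>   40 samples, 1 excluded: MCN_P_01

me <- me[, setdiff(colnames(me), qc$excluded)]
pd <- pairwiseDMPCounts(me)             # adj p < 0.01, |delta| > 0.3
dmpCounts(pd)
#>              MCN_P MCN_L mBOT NormPancreas
#> MCN_P            0     0  950          450
#> MCN_L            0     0  950          450
#> mBOT           950   950    0          500
#> NormPancreas   450   450  500            0

net <- annotateClosest(buildNetwork(pd), pd)
net
#> RelatednessGraph: 4 groups, 6 binned edges, 0 closest-connection annotations
#>   bin 0 : 1 edges
#>   bin 1-999 : 5 edges

nearestEntity(pd, "MCN_P")
#> $group
#> [1] "MCN_L"
#> $count
#> [1] 0
```

Reading the output: the designated bad sample (14% of probes failing
detection p) is excluded; the sibling pair shows exactly 0 DMPs and is
joined by the strongest possible edge (the "0" bin); each lesion group
shows its planted 450/500-probe difference from normal tissue, and the
MCN_P↔mBOT count (950) is the sum of their disjoint planted sets. The
count matrix is what the landscape figures of a cohort study summarise:
fewer DMPs, closer entities.

For the full chain on one object — including t-SNE, consensus clustering,
pathway calls and deconvolution — see `runPipeline()`:

```r
res <- runPipeline(me, "run1",
                   pipelineConfig(referenceGroups = "MCN_P",
                                  lesionGroup = "MCN_P",
                                  normalGroup = "NormPancreas",
                                  seed = 1))
```

which writes per-stage artifacts (embedding CSV, consensus matrix,
dendrogram Newick, DMP tables, network GraphML/edge list, gene lists,
fractions) plus a reproducibility manifest into `run1/`.

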
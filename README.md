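# braindev

Temporal-regulation analysis of lifespan brain transcriptomes.

Bulk expression atlases of the developing brain sample many regions across
ordinal developmental stages (prenatal through late adulthood). A recurring
finding in such data is that stage-to-stage transcriptional change is not
uniform: differential expression between adjacent stages is concentrated in
two bursts — one perinatal, one around childhood ("twin peaks") — while
all-pairs stage divergence is dominated by fetal comparisons and collapses
after birth (the "waterfall"). `braindev` packages the full analysis chain
needed to characterise these patterns, together with a seeded synthetic data
generator with planted ground truth so every stage of the chain is testable
without access to post-mortem atlas data.

## What the package computes

For a log2 expression matrix (genes × samples) with per-sample region,
stage, and technical covariates (post-mortem interval PMI, RNA integrity
number RIN):

- **Temporal DEGs** — per region, a linear model of expression on stage
  (categorical) plus covariates; the partial *F* test for stage, BH-adjusted
  per region, calls a gene a temporal DEG when *Q* < 0.01 and its stage-mean
  range is at least 1 on the log2 scale (≥ 2-fold).
- **Tukey HSD stage comparison** — all stage pairs per gene, studentized-range
  adjusted *p* with Tukey–Kramer pooling for unbalanced groups; the count of
  significant temporal-DEG comparisons per stage pair is the waterfall
  surface.
- **Developmental DEGs and twin peaks** — temporal DEGs whose adjacent-stage
  mean difference satisfies |Δ| ≥ 1; per-region counts over transitions form
  the regulation profile, with prominence-filtered local-maximum peak
  detection.
- **Cross-region sharing** — shared proportions between regions, and a
  permutation test of the size of the DEG intersection across regions against
  size-matched random gene sets (add-one permutation *p*).
- **Gene-set enrichment** — one-sided Fisher's exact tests (hypergeometric
  tail) of functional/disease/marker sets against every region × transition
  DEG set, BH per set; majority-of-regions High/Medium/Low calls; paired
  Wilcoxon comparison of two marker sets across regions.
- **Signed co-expression networks** — adjacency
  *a_ij* = ((1 + cor_ij)/2)^18, topological overlap matrix, hybrid dynamic
  tree cut (minimum module size 50, deepSplit 4), eigengene merging at
  dissimilarity 0.15, intramodular connectivity and top-linked genes,
  module–DEG enrichment.
- **Dynamic network biomarker (DNB)** — per stage, Welch *t* candidates
  against the first stage (BH), correlation clustering capped at 40
  clusters, and the composite index CI = SD · PCC_in / PCC_out per cluster;
  the tipping stage is the largest CI jump of a cluster tracked across
  stages.

## Worked example

```r
library(braindev)

cfg <- sim_config(n_genes = 1000, n_regions = 3, seed = 1)
sim <- simulate_lifespan(cfg)
sim$data
#> expression_dataset: 1000 genes x 195 samples
#>   regions: R01, R02, R03
#>   stages: 3 4 5 6 7 8 9 10 11 12 13 14 15

prof <- developmental_profile(sim$data)
prof$profile[, c("6-7", "7-8", "8-9", "9-10", "10-11", "11-12")]
#>     6-7 7-8 8-9 9-10 10-11 11-12
#> R01   0 203   2    0   161     2
#> R02   2 210   0    0   170     0
#> R03   1 197   1    2   172     1
prof$peaks$R01
#> [1] "7-8"   "10-11"
```

The generator planted expression steps at transitions 7→8 and 10→11; the
adjacent-stage DEG profile recovers both bursts in every region, and
`detect_peaks` returns them in descending count order.

```r
ov <- overlap_permutation_test(prof$devdegs, "7-8",
                               universe = rownames(sim$data$expr),
                               n_permutations = 1000, seed = 2)
ov
#> overlap_test at transition 7-8
#>   observed shared genes: 152 (>= 3 regions)
#>   null: mean 8.40, sd 2.77 (1000 permutations)
#>   p = 0.000999
```

152 first-peak DEGs are shared by all three regions; size-matched random
sets share 8.4 on average, so the sharing is extreme under the resampling
null (*p* = 1/1001, the smallest value the add-one estimator can report).

```r
net <- build_coexpression_network(sim$data$expr)
net
#> coexpression_network: 1000 genes, 6 modules (209 unassigned); power 18, scale-free R2 0.35

sel <- select_dnb(dnb_trace(sim$data))
sel$stage
#> [1] 12
round(sel$ci_trajectory, 2)
#>    8    9   10   11   12   13   14   15
#> 0.79 1.41 0.98 0.86 3.24 0.87 0.90 0.83
```

The network step recovers the four planted co-expression modules (plus
burst-gene groupings), and the DNB composite index of the selected cluster
spikes exactly at the planted tipping stage (12), where the generator
inflates the cluster's variance threefold and raises its internal
correlation to 0.9.

The whole chain — simulation, DEG calling, profiling, permutation,
enrichment, networks, DNB — runs end to end via `run_pipeline()` (or the
thin CLI wrapper `inst/scripts/run_pipeline.R`), writing TSV/GMT/JSON
artifacts plus a machine-readable `summary.json` that is byte-identical
across reruns with the same seed.

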
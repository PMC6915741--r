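---
title: "Models and design choices in braindev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in braindev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`braindev` analyses stage-structured bulk expression data of the developing
brain: many regions, an ordinal stage per sample (the analysis spans stages
3–15 by default), and log2-scale intensities. This vignette explains the
statistical models behind each step, the parameters that matter, the
numerical conventions, and the design decisions taken where the problem was
genuinely open.

## Temporal DEG model

For one region, each gene is fit with the linear model

    expression ~ covariates + stage

where stage is categorical and covariates default to none (post-mortem
interval and RNA integrity number are the intended nuisance terms for
post-mortem data; they enter the mean model only). The stage effect is
tested with the partial *F* statistic — the comparison of this model with
the covariates-only model — which reduces to one-way ANOVA without
covariates. A sequential *F* would be identical here because stage is the
last (and only other) term; the partial form is what generalises.

P-values are Benjamini–Hochberg adjusted *within region across genes*: the
analysis reports per-region DEG counts, so the region is the natural family.
A gene is a temporal DEG when *Q* < 0.01 (exclusive) and the range of its
covariate-free stage means is at least 1 in log2 units (inclusive, i.e. at
least 2-fold between its most extreme stages). The fold-change filter is
deliberately computed on raw stage means, not model-adjusted means, so that
the filter and the adjacent-stage criterion below live on the same scale.

Degenerate genes (zero variance in the region) receive *F* = 0, *p* = 1 and
a flag; genes with zero residual variance but real stage differences would
have an unbounded *F*, which is guarded at 1e12. Both conventions are
conservative and keep `NaN`s out of downstream multiplicity adjustment.

## Tukey HSD and developmental DEGs

All stage pairs are compared with Tukey's honestly-significant-difference
test: the difference of stage means divided by the Tukey–Kramer standard
error `sqrt(MSE/2 * (1/n_a + 1/n_b))`, referred to the studentized-range
distribution with the one-way pooled degrees of freedom. The pooled MSE is
covariate-free: the stage groups are compared as observed. Differences are
reported as later stage minus earlier stage, so a positive value means
up-regulation with age; reversing the declared stage order negates the
differences and leaves the p-values unchanged (a property the test suite
checks). Zero pooled variance is flagged degenerate; the adjusted *p* is 0
when the means differ and 1 otherwise.

The count of temporal DEGs with Tukey-adjusted *p* < 0.05 per stage pair and
region is the inter-stage "combination count" surface (the waterfall). A
**developmental DEG** at transition (s, s+1) is a temporal DEG whose
adjacent-stage |difference| is at least 1 (log2). The defining criterion is
the magnitude rule alone; an optional flag additionally requires Tukey
significance at the transition. Both behaviours are exposed because the
magnitude rule is the stated definition while the significance gate is a
natural strengthening; the default follows the stated rule.

Evaluating the studentized-range distribution is by far the most expensive
primitive (about 0.2 ms per value), so `tukey_hsd()` accepts a gene subset
and a `compute_p` switch; the pipeline computes adjusted p-values only for
temporal DEGs, which are the only genes whose Tukey significance is ever
used.

## Profiles, peaks, and cross-region sharing

The per-region vector of developmental DEG counts over transitions is the
regulation profile. A transition is a **peak** when its count exceeds the
previous transition's, is at least the next one's (boundary transitions
compare to their single neighbour), and reaches at least 20% of the
profile's maximum. The prominence floor (`min_prominence_fraction = 0.2`)
exists because count profiles of null data wiggle by a few genes; without a
floor those wiggles would be reported as peaks. Peaks are returned in
descending count order, so the first element is the dominant burst.

Sharing between regions is quantified two ways. `shared_proportion()` is
the directed fraction |A∩B|/|A|. `overlap_permutation_test()` takes the
number of genes present in the developmental DEG sets of all regions at a
transition (optionally: at least *k* regions) and compares it with the same
statistic after redrawing every region's set uniformly at random — same
sizes, same universe — 10,000 times by default. The p-value is the add-one
estimator (1 + #{null ≥ observed})/(1 + B), which can never be zero and is
exactly valid at finite B. The universe is the set of genes in the matrix
under analysis, not the genome: proportions in this literature are quoted
against expressed genes.

`subsample_robustness()` redraws a fixed number of samples per region ×
stage cell without replacement and reruns the whole DEG chain, measuring
whether peak positions survive reduced sampling depth.

## Enrichment

`fisher_enrichment()` is the one-sided (over-representation)
hypergeometric tail; two-sided alternatives are not offered because every
question asked of it is an enrichment question. The odds ratio is the
sample odds ratio, with a 0.5 Haldane correction applied — and flagged —
only when a table cell is zero. Within `enrichment_matrix()` BH is applied
per gene set across all region × transition cells; the matrix of one set's
q-values is the unit a reader inspects, so it is the family. BH never
reorders p-values within a family, so the choice of family affects
thresholds, not rankings.

The majority-of-regions call summarises a marker set at a transition:
**High** if enriched at *p* < 0.001 in a strict majority of regions, else
**Medium** at *p* < 0.01, else **Low** at *p* < 0.05, else not enriched.
The Medium cutoff is set to 0.01: the three levels must be nested, and
0.01 is the midpoint of the ladder (a Medium threshold equal to High's
would make the level unreachable). The comparison of two marker sets (for
example excitatory-neuron vs interneuron markers) is a paired two-sided
Wilcoxon signed-rank test across regions on −log10(p) enrichment scores;
the score choice makes "more enriched" monotone and bounded, and the paired
test respects that regions are the repeated unit. All-zero differences
return *p* = 1 by convention. Fewer than 5 regions is an error — the
signed-rank null has no useful resolution below that.

## Signed co-expression networks

The adjacency is `((1 + cor)/2)^power` with Pearson correlation and
`power = 18`: a signed network, so anti-correlated genes are *not*
connected (adjacency 0 at correlation −1, `0.5^18 ≈ 3.8e-6` at 0). The
topological overlap matrix is

    TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

with connectivity excluding the diagonal. `scale_free_fit()` reports the
R² of log10(frequency) against log10(mean connectivity) over equal-width
connectivity bins, sign-flipped when the slope is positive; it is advisory
(the power is fixed at 18 by design, not refit per dataset). Equal-width
binning is used because equal-occupancy binning makes the per-bin frequency
constant by construction and the fit degenerate.

Module detection is a hybrid dynamic cut of the average-linkage tree on
1 − TOM, in two phases. A static phase removes every merge at or above
`cut_factor` (0.98) times the mean off-diagonal dissimilarity — merges at
background dissimilarity are noise joins, whatever the dataset's absolute
scale. A dynamic phase then splits a branch wherever its merge height sits
clearly above its children's internal merges: the relative height gap must
reach 0.5, 0.4, 0.3, 0.2 or 0.1 for `deep_split` 0–4, so larger values
split more aggressively but a homogeneous block — whose internal merges
climb smoothly to the top — is never split at any setting. Clusters smaller
than `min_module_size` (50) dissolve to label 0, as do clusters whose mean
within-cluster TOM fails to exceed `cohesion_factor` (2) times the
background mean TOM; the cohesion bar prevents a chained blob of noise
genes from surviving as a "module". Finally, unassigned genes whose mean
TOM to some module passes the same bar are adopted by their nearest module.
The procedure is deterministic and permutation-equivariant. It is a
variant, not a re-implementation, of the reference hybrid tree-cut
heuristics: correctness is assessed by planted-module recovery (adjusted
Rand index), not by label-for-label agreement with any particular
implementation.

Module eigengenes are the first principal component of the standardized
module submatrix, unit-variance, oriented to correlate positively with the
module's mean profile (so sign is reproducible). Modules whose eigengene
dissimilarity 1 − cor falls below `merge_height` (0.15) are merged
iteratively, closest pair first, recomputing eigengenes after each merge;
the procedure is idempotent. Intramodular connectivity (adjacency summed to
same-module genes; whole-network connectivity for unassigned genes) ranks
the "top linked" genes, ties broken by identifier.

For the end-to-end pipeline, networks are built per peak period by pooling
the samples of the two stages flanking each of the two dominant peak
transitions, across regions. The pooling window is configurable; two
stages per peak keeps the per-network sample count in the range typical of
atlas-scale peak periods.

## Dynamic network biomarker

At every stage after the first, candidates are genes whose Welch *t*-test
against the first stage survives BH at *q* < 0.05. Candidates are clustered
by average linkage on 1 − Pearson correlation over the stage's samples and
the tree is cut into at most 40 clusters. For each cluster the trace
records the average member SD, the mean absolute within-cluster pairwise
correlation (PCC_in, 1 by convention for singletons, flagged), the mean
absolute correlation between members and all other genes in the matrix
(PCC_out, floored at 1e-6, flagged when the floor binds), and the composite
index CI = SD · PCC_in / PCC_out. Absolute correlations are used because
the biomarker criterion concerns coupling strength, not direction. The
complement is the whole rest of the matrix rather than the other
candidates: the index contrasts a cluster against the transcriptome, and
the convention also keeps the complement non-empty whenever the cluster is
a proper subset of the genes.

Two refinements matter in practice. First, when samples are pooled across
regions, per-region means are removed within each stage before any SD or
correlation is computed: a gene expressed differently in different regions
otherwise acquires region-driven "correlation" and variance that mimics a
critical transition. (With a single region the centring is a no-op.)
Second, `select_dnb()` considers only clusters of at least `min_size = 5`
members: with a handful of samples per stage, the CI of singleton and pair
clusters is dominated by the PCC_in convention and by correlation sampling
noise rather than by coordinated fluctuation.

Clusters are tracked across consecutive evaluated stages by maximal Jaccard
membership overlap; the selected biomarker is the cluster with the largest
CI increase over its matched predecessor, ties broken by the larger CI. If
no cluster persists across any stage pair the global CI maximum is returned
with a fallback flag. The CI trajectory reported for the selection follows
the best-matching cluster at every stage.

## The synthetic generator

`simulate_lifespan()` emulates the structure of a multi-region lifespan
atlas: baseline log2 means per gene from Normal(8, 2) (the typical log
intensity range), independent Gaussian noise with SD 0.5 by default, 11
regions × stages 3–15 × 5 samples per cell, PMI ~ Uniform(5, 30) hours and
RIN ~ Uniform(6, 10) entering (centred) with coefficients that default to
zero so nuisance structure is opt-in. Planted structure:

- **Bursts**: step effects (1.5 log2 by default) at and after a transition's
  later stage. A step, rather than a pulse, changes adjacent-stage means at
  exactly one transition, so the transition a recovered gene is attributed
  to is unambiguous. A configurable fraction (default 0.7) of each burst's
  genes is affected in all regions; the rest in random proper subsets,
  emulating partly-regional regulation. Default bursts sit at 7→8 and
  10→11 with 250 and 150 genes — perinatal larger than childhood.
- **Modules**: each module's genes share a per-sample latent factor with
  loading λ (default 0.76); the in-module correlation is
  λ²/(λ² + σ²) ≈ 0.7 at the default noise. Module genes have no stage
  effect, so modules and bursts probe different machinery.
- **Tipping cluster**: members get a 1.5 log2 step starting one stage
  *before* the tipping stage (default stage 12, after the childhood peak) —
  so stage-wise screens against the first stage can see them on both sides
  of the transition — and, at the tipping stage only, noise inflated 3×
  with pairwise correlation 0.9. This is the canonical early-warning
  signature: variance and internal coupling spike at the critical stage.

Sample counts per cell are not dictated by any atlas; 5 per region × stage
was chosen for adequate ANOVA replication at desk scale, and an optional
jitter produces unbalanced designs. All randomness flows from the single
config seed; identical configs are bit-identical.

What the generator does **not** emulate: probe-level effects,
normalisation artifacts, batch structure, age-to-stage binning ambiguity,
missing cells, heavy-tailed noise, and correlated nuisance covariates.
Passing the planted-recovery tests therefore demonstrates that the
machinery is correct and calibrated under clean Gaussian conditions, not
that real atlas data would yield the same sensitivity.

## Problem sizes and numerical conventions

The test suite exercises the chain at 2,000 genes × 11 regions × 13 stages
× 5 samples for DEG/profile properties (20 seeded replicates), 500 genes ×
130 samples for module recovery (10 seeds), and 1,000 genes × 11 regions
for DNB recovery (20 seeds); the DNB design uses all 11 regions because the
trace pools samples within stage and correlation estimates need the ~55
samples per stage that layout provides. Permutation tests default to
10,000 draws in the API and use 1,000 in the routine suite.

Numerical conventions collected in one place: BH rejects `NA` input rather
than propagating it; zero-variance genes are flagged and never significant;
the permutation p-value is add-one; odds ratios use Haldane only at zero
cells; eigengene sign follows the module mean; connectivity ties in
`top_linked_genes()` break by gene identifier; `detect_modules()` and all
clustering are deterministic given their input, so every pipeline artifact
is byte-stable under a fixed seed.

## Known limitations

- The tree-cut variant is tuned for block-structured planted modules; on
  real data with nested or overlapping modules its labels will differ from
  reference hybrid tree-cut implementations (recovery, not label equality,
  is the contract).
- The DNB trace assumes the first stage is a valid reference; if the
  reference stage itself sits near a transition, candidate screens are
  misaligned.
- `compare_marker_regulation()` treats regions as exchangeable pairs;
  spatially correlated regions make its p-values liberal.
- Fold-change and |Δ| ≥ 1 thresholds presume log2 input; data on other
  scales must be transformed first.
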
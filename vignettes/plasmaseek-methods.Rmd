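---
title: "plasmaseek: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmaseek: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plasmaseek` screens plasma-detectable genes for tumor-vs-normal
deregulation, classifies stage-wise expression patterns, contrasts gene
importance between tumor- and normal-group co-expression networks, and
evaluates candidate biomarker panels with a cross-validated linear SVM.
This vignette records the statistical model behind each stage, the
parameters that matter, the choices made where the design was genuinely
open, and what the package's synthetic validation does and does not show
about real data.

## Input model

The unit of analysis is an *expression cohort*: a genes × samples matrix
of nonnegative normalized RNA-seq abundances (RSEM-style normalized
estimates; unitless, fractional values allowed) with per-sample
annotations `group ∈ {tumor, normal}` and `stage ∈ {I, II, III, IV,
unknown}`. Staging applies to tumors only; normals always carry
`unknown`. Values are used exactly as provided: the screening tests are
rank-based, so a monotone transform such as log2 changes nothing, and the
networks deliberately use the same scale the screen saw. Gene symbols are
matched case-sensitively after whitespace trimming with no alias
resolution; sub-stage labels (`IIa`, `IIIB`) collapse to their Roman
prefix. Restricting the cohort to a plasma-proteome panel is a plain set
intersection, with unmapped panel symbols reported and excluded.

## Screening

Every panel gene is tested with the two-sided Mann–Whitney U test, all
tumors against all normals. The reported U is the tumor-group statistic
under midrank tie handling. The p-value is exact when the smaller group
has ≤ 8 observations and the pooled values are tie-free; otherwise the
normal approximation with tie and continuity corrections is used. A
fully tied gene (zero pooled variance) gets the central U and p = 1
rather than an error. The screening threshold is a raw two-sided
p < 0.05 — by design no multiplicity correction drives the labels, since
the screen is an intentionally permissive first filter; a
Benjamini–Hochberg q column is emitted alongside for diagnostic use.

Direction (`up`/`down`) is assigned to significant genes by comparing
group medians, falling back on U against its central value n1·n2/2 when
the medians tie exactly.

**Leading genes** are the `top_k` (default 5) smallest-p significant
genes per direction.

**Stage-specific genes**: gene flagged for stage s when tumors of stage s
differ from tumors of all other known stages (Mann–Whitney p < α, focal
median higher for the up variant, lower for down). Unknown-stage tumors
are excluded from both sides. The comparison is focal-vs-other-stages
rather than focal-vs-normal: it asks where in the disease course a gene
is distinctive, and significance against normals is available separately
in the per-stage columns of the screen table (stage-s tumors vs all
normals). Stages with fewer than two tumors on either side are skipped
with a warning.

**Progressive genes** formalize "expression intensifying with stage" as
the conjunction of three conditions: (a) overall significance with the
matching direction; (b) stage medians nondecreasing (up) or nonincreasing
(down) from I to IV over stages with ≥ 2 tumors; and (c) a one-sided
ordered trend test at α. The trend statistic is the Jonckheere-style sum
of pairwise Mann–Whitney U counts over ordered stage pairs (ties counted
1/2), compared to its null mean (N² − Σn_s²)/4 and variance
(N²(2N+3) − Σn_s²(2n_s+3))/72 by normal approximation with continuity
correction. Tie correction of the variance is omitted: on continuous
expression values exact ties have probability zero, and on real data they
are vanishingly rare after normalization. The median-monotonicity
condition makes the call strict — a single out-of-order stage median
vetoes the gene — which trades a little sensitivity for pattern purity.

Every gene receives exactly one pattern label. Precedence (highest wins):
leading > progressive > stage-specific > not significant. The order
matters for genes qualifying for several patterns: a progressive gene
usually also passes the stage-IV-specific test (its stage-IV shift is its
largest), so progressive outranks stage-specific; and the leading label
is reserved for the very top of the significance ranking regardless of
shape, matching how candidate panels are assembled downstream. Genes that
are significant but match no pattern keep the fallback label; their
p-value and direction columns carry the significance.

## Dual co-expression networks

For one sample group (≥ 3 samples), pairwise Pearson correlations r_ij
feed two edge-weight transforms:

* similarity: ((1 + r)/2)^β — large for strongly positively co-expressed
  pairs;
* dissimilarity: ((1 − r)/2)^β — large for strongly anti-correlated
  pairs, interpretable as a distance.

At β = 1 the two transforms sum to 1; raising β shrinks weak
correlations. Self-loops are removed (zero diagonal) and edges with
weight strictly below the hard threshold 0.01 are deleted, in that order.
Zero-variance genes get r = 0 off-diagonal and survive as isolated nodes
rather than being dropped, keeping the gene set identical across all four
networks — a prerequisite for the paired RCC contrast.

The soft power β is selected by the scale-free topology criterion: for
each candidate power, node connectivities k_i = Σ_j w_ij (pre-threshold)
are binned into 10 equal-width bins, and log10 of the per-bin node
proportion is regressed on log10 of the per-bin mean connectivity over
non-empty bins; the fit index is R² signed by the negated slope, so +R²
rewards the decreasing relationship a scale-free degree distribution
implies. The smallest power in the grid (1..20) reaching signed R² ≥ 0.85
wins — the conventional threshold in weighted co-expression analysis —
else the argmax is taken with a warning.

Two selection refinements apply when networks are built *for the RCC
contrast* (`rcc_pipeline()`, `run_pipeline()`):

1. **One joint β for both groups.** Contrasting log2(RCC) between groups
   requires the same transform on both sides: with group-wise powers, any
   difference in chosen β shifts log2(RCC) for every gene and the paired
   test measures the power difference instead of network rewiring (on
   tumor==normal null cohorts this produced p ≈ 10⁻³ routinely). The
   joint selector takes the smallest power at which both groups pass the
   threshold, else the argmax of the per-power minimum.
2. **Admissibility.** Powers under which the hard threshold empties a
   network layer cannot support a closeness-ratio analysis: closeness
   degenerates to zero and RCC becomes undefined for most genes. A power
   is admissible when all four layers keep at least half their nodes
   non-isolated — checkable from per-node extreme correlations without
   powering any matrix, since a node keeps a similarity edge iff
   ((1+max_j r_ij)/2)^β ≥ 0.01 (mirrored for dissimilarity). Selection
   runs within the admissible range. This matters for any data set
   without strong negative correlations — including all cohorts this
   generator produces — whose dissimilarity layer cannot survive large β.

The standalone `build_dual_network()`/`select_soft_power()` keep the
plain per-group contract for users who want a single group's network.

## Closeness and RCC

Closeness uses edge traversal lengths 1/weight (heavier edges are
shorter) and Dijkstra shortest paths. For node v reaching m − 1 other
nodes in an n-node network, the score is the Wasserman–Faust
component-scaled closeness ((m−1)/Σd) · ((m−1)/(n−1)): within a
component it is the inverse average shortest-path distance, and the
scaling penalizes small components so that disconnection is handled
rather than errored. Isolated nodes score 0. On a complete graph with
constant weight w every node scores exactly w.

The dissimilarity layer is nominally a distance matrix, so a
configuration switch `distance_mode` chooses between the uniform
`"inverse"` contract (default; keeps the RCC ratio on one scale in both
layers) and `"direct"`, which uses dissimilarity weights themselves as
lengths.

RCC_N = CN_sim/CN_dis and RCC_P = CT_sim/CT_dis per gene; a zero
denominator marks the gene undefined — never imputed — and undefined
genes are excluded (and counted) in the paired test. The contrast is the
two-sided Wilcoxon signed-rank test on log2(RCC_N) − log2(RCC_P) over
the candidate biomarker genes: zero differences dropped per the standard
convention, exact p for ≤ 25 tie-free differences, normal approximation
with corrections otherwise; fewer than 3 usable pairs is reported as
untestable.

## Panel evaluation

A candidate panel is evaluated as features of a linear-kernel SVM
(cost 1, no class weighting — imbalance is handled by stratification
only) under `cv_repeats` (default 50) repetitions of stratified
`cv_folds` (default 5)-fold cross-validation. Repeat r reseeds the fold
split with `master_seed + r`. Within each fold, features are z-scored
using training-fold statistics only, and held-out samples are scored
with signed decision values oriented so that larger means tumor.
Held-out scores are pooled across the folds of one repetition into a
single ROC curve (pooling, rather than averaging per-fold AUCs, uses
every sample exactly once per curve); the trapezoid AUC of that curve
equals the midrank Mann–Whitney AUC identically, which the test suite
cross-checks against an independent rank-formula oracle. The summary
reports mean and SD over the repeat AUCs plus the mean ROC by vertical
averaging on a fixed 101-point FPR grid. The random baseline draws
`random_gene_count` (default 5, matching the candidate panel size) genes
uniformly without replacement from the cohort, seeded by a fixed offset
from the master seed.

## Synthetic cohorts

The generator is the package's validation instrument, so its model is
deliberately the simplest one with the right structure. For gene g and
sample s, the log2 signal is μ_g + λ f_{m(g),s} + √(1−λ²) ε, with noise
ε ~ N(0, σ_g), module factor f ~ N(0, σ_g) shared by all genes of a
module within a sample (within-module pairwise correlation exactly λ²),
μ_g ~ U(3, 9) and σ_g ~ U(0.5, 2) per gene; genes without a module keep
full-SD noise. Tumor samples add effect_size·σ_g by class: all tumors
(global), the focal stage only (stage-specific), or effect_size·σ_g·
(stage index)/4 with I = 1..IV = 4 (progressive). Tumors with unrecorded
stage draw a latent stage that drives effect generation and is then
masked — mirroring real cohorts, where stage is unrecorded rather than
absent. Expressed values are 2^(log2 signal), clipped at zero and not
rounded (RSEM-style normalized estimates are fractional). Expressing
effects in units of each gene's own SD makes rank-test power predictable
independently of baseline abundance.

Presets mirror two gastro-esophageal cohort layouts: `stomach_like`
(415/35, stage mix 13.7/29.6/40.7/9.9% + 6% unknown) and
`esophagus_like` (185/11, 9.7/42.2/30.3/4.9% + 13% unknown); printed
stage percentages are rescaled to sum exactly to one. Both plant five
genes per effect class at 1.5 SD and four 20-gene modules at λ = 0.6
among 500 genes — λ² = 0.36 within-module correlation, a mid-range value
for co-expression modules; 1.5 SD gives near-certain detection at the
stomach group sizes while staying within the range of plausible single-
gene effects. An optional `rewire_tumor` flag redraws the module
membership for tumor samples only, planting exactly the kind of
co-expression reorganization the RCC statistic is meant to detect.

What the generator does *not* emulate — library-size and batch effects,
count noise, heavy-tailed abundance distributions, negative
co-expression, overlapping modules — bounds what green tests mean:
passing shows the statistics are implemented correctly and calibrated
under clean assumptions, not that the pipeline is robust to real-world
artifacts.

## Validation design and problem sizes

The test suite checks each statistic against an independent oracle:
exhaustive enumeration of all rank assignments (Mann–Whitney, group
sizes to 6+6) and sign assignments (signed-rank, n ≤ 10), a
Floyd–Warshall all-pairs closeness oracle on random graphs of ≤ 15
nodes, and the rank-formula AUC identity. Calibration and power checks
run on simulated cohorts sized to keep the full suite within a few
minutes on one CPU: 50 all-null 200-gene screens for type-I, 50
equal-size (35/35) null cohorts for the RCC null rejection rate, 20
seeds of the 500-gene stomach-like design at effect 2 SD for recovery
and panel power, and 20 rewired-module cohorts (λ = 0.8, 150/150) for
RCC detection power.

Two validation-design points deserve emphasis. The RCC null calibration
generates the tumor group identically to the normal group — equal sizes —
because the statistic is *not* calibrated across unequal groups (below).
And the leading-gene recovery check plants only the ten global genes
against a null background: in a cohort that also plants progressive
effects, those genes are truly deregulated and legitimately compete for
the leading slots, so exact top-5 set recovery is the wrong yardstick
there.

## Known limitations

* **RCC across unequal sample sizes.** Sample correlation noise scales
  with 1/√n, and the dissimilarity network is anti-transitive (strong
  mutual negative correlation cannot be transitive), so the asymmetry
  between a gene's similarity- and dissimilarity-closeness depends
  systematically on group size. Contrasting a 415-sample tumor network
  against a 35-sample normal network therefore shifts log2(RCC) for
  every gene, and the paired Wilcoxon rejects a true null essentially
  always. The contrast is meaningful only between groups of comparable
  size; with heavily unbalanced cohorts, subsampling the larger group is
  advisable.
* **Dependence across genes.** The paired Wilcoxon treats genes as
  independent pairs, but all log2(RCC) values share one pair of
  estimated networks; a common network-noise shift is detected as signal
  with probability above α even at equal sizes (measured ≈ 0.11 at
  35/35 over 100 seeds against a nominal 0.05). p-values from the RCC
  contrast should be read as descriptive strength-of-evidence, not
  calibrated error rates.
* **Sparse dissimilarity layers.** Data without strong negative
  correlations populate the dissimilarity network only at small soft
  powers; the admissibility rule keeps the analysis defined but cannot
  conjure structure that is not there, and RCC may still be undefined
  for individual genes (reported in `n_dropped`).
* **Raw-p screening.** At α = 0.05 with ~1200-gene panels, dozens of
  false positives are expected by design; the q column, and the leading
  gene ranking, are the instruments for prioritization.
* **Pattern definitions are conventions.** Median monotonicity plus an
  ordered trend test, and focal-vs-other-stages testing, are explicit
  formalizations of informally described practices; other reasonable
  operationalizations (e.g. isotonic regression fits, focal-vs-normal
  testing) would flag overlapping but not identical gene sets.
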
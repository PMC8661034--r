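---
title: "Measuring transcriptomic derivedness: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptomic derivedness: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derivtree)
```

## The problem and the model

Conservation-based comparisons of embryonic transcriptomes score how similar
the expression of strictly shared (1:1 orthologous) genes has remained. When
many distantly related species are compared, the 1:1 set shrinks to a few
hundred genes — around one percent of a vertebrate genome — and changes
carried by duplicated or lost genes are invisible by construction.
`derivtree` measures the complementary quantity, *derivedness*: how much
transcriptomic change each embryo has accumulated since a common ancestor,
using (nearly) all genes.

The measurement has four stages:

1. **Ortholog-group table.** Genes of all species are grouped into
   ortholog-groups. Within a group and species, paralog TPMs are aggregated
   (mean by default; sum gives equivalent downstream behavior up to a
   per-group scale and is available). A group with no gene in a species is
   assigned expression exactly 0 in all of that species' samples: gene loss
   is treated as signal, not missing data. Species-specific genes (absent
   from the group map) are dropped by default — with them the inferred
   topology tends to contradict the reference phylogeny — but can be kept as
   singleton groups for sensitivity analyses.

2. **Normalization and distance.** Expression columns (one per embryo or per
   replicate-averaged stage) are normalized by one of nine chains — log2/log10
   of TPM+1, quantile, ascending/descending rank, z-score, and
   log2-anchored compositions — and compared by one of seven distances
   (1−Pearson, 1−Spearman, Euclidean, Manhattan, cosine, Canberra with 0/0
   defined as 0, and the Jensen–Shannon distance, the square root of the
   base-2 divergence). Spearman distance on raw TPM equals Spearman distance
   on any monotonically transformed table; this invariance is one of the
   package's standing tests.

3. **Tree and index.** A distance tree is inferred by neighbor joining or
   BIONJ, rooted on the edge separating an outgroup, and the *derivedness
   index* of an embryo is the sum of branch lengths from the ancestral node
   (the ingroup-side endpoint of the rooting edge, or a clade-specific
   ancestor) down to its leaf.

4. **Selection criteria.** A (normalization, distance, tree) combination is
   considered usable when (1) every species' samples form a clade, (2) the
   species-collapsed topology has Robinson–Foulds distance 0 to the
   reference phylogeny, and (3) within-species distance images are smooth
   along developmental order, scored by gray-level co-occurrence (GLCM)
   texture descriptors.

### Assumptions worth stating

* Between-species differences dominate within-species stage differences for
  the species compared — this is what makes criterion 1 plausible at all; it
  is an empirical property of distantly related taxa, not a theorem.
* The transcriptome tree is expected to recapitulate the sequence-based
  phylogeny (criterion 2). Where evolution of expression and of sequence
  genuinely decouple, this criterion would reject a truthful tree; it is a
  method-selection filter, not a validity proof.
* Branch lengths of a distance tree are only meaningful if the distance is
  approximately additive along the true tree; NJ/BIONJ estimate, not
  guarantee, this.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `aggregator` | `build_og_table()` | `"mean"` | paralog aggregation; `"sum"` rescales groups by paralog count |
| `min_species` | `build_og_table()` | 2 | drop groups present in fewer species (1 keeps species-specific groups) |
| normalization chain | `pipeline_config()` | `rank_ascending` | scan winner together with Spearman distance |
| `distance` | `pipeline_config()` | `"spearman"` | the only distance meeting all three criteria in our scans |
| `tree_method` | `pipeline_config()` | `"bionj"` | variance-weighted joins; equals NJ on additive input |
| `levels` | `smoothness_scan()` | 8 | GLCM gray levels per species block |
| `n_draws` | `bri_trees()` | 100 | replicate-resampled trees for supports and stage distributions |
| `threshold` | `temporal_pleiotropy()` | TPM 1 | a stage counts as "expressed" at or above this raw-scale value |

Rank, z-score and quantile steps are applied **per sample column**: the unit
of comparison is the embryo, and cross-species comparability requires
scaling within each embryo's profile. A per-gene variant (`margin = 1`)
exists for exploratory use.

## Numerical choices

* **Ties** in ranks use mid-ranks (required for Spearman consistency);
  ties in best-method selection during the smoothness scan split the win
  fractionally among the tied methods.
* **Quantile normalization** assigns sorted-position means, so every output
  column carries the identical multiset of values and the operation is
  idempotent; tied inputs receive adjacent means in input order,
  deterministically.
* **z-score of a constant column** returns zeros with a warning rather than
  an error: rows constant across a species (lost groups) are routine, whole
  constant samples are not.
* **Negative branch estimates** from NJ/BIONJ are clamped to 0 on the
  returned tree — indices are path sums and must stay non-negative to be
  interpretable — while the raw estimates are kept as an edge attribute for
  inspection. NJ and BIONJ are implemented in the package in double
  precision; they reconstruct random additive matrices to better than 1e-9
  in branch length (a standing acceptance check), and agree with the ape
  implementations in topology.
* **Rooting** places the root at the midpoint of the outgroup edge. The
  split is arbitrary, but the ancestral node is the ingroup-side endpoint of
  that edge, so ingroup indices never depend on it.
* **Canberra 0/0 terms are 0** (not dropped-and-rescaled): rows lost in two
  species at once would otherwise inflate the distance between those
  species' samples.
* **GLCM**: species blocks are min–max quantized to 8 gray levels, each 3x3
  sliding window contributes one symmetric co-occurrence matrix pooled over
  the distance-1 horizontal and vertical offsets, and descriptors are
  averaged over windows. The correlation descriptor is defined as 1 at zero
  marginal variance so that constant (perfectly smooth) blocks rank best
  under all five descriptors. Eight levels is a deliberate ceiling: a 3x3
  window has only 12 co-occurrences, so finer quantization only thins the
  matrix.
* **Degenerate Friedman blocks** (all stages tied in every draw) are
  reported as statistic 0, p 1; the textbook statistic is 0 there but the
  tie-corrected implementation in `stats` degenerates to 0/0.
* **DCO conventions**: "negative correlation" means strictly `rho < 0`; `NA`
  correlations (constant expression, or species with fewer than 3 stages)
  count as non-negative and are excluded from the per-group mean, with the
  count of contributing species reported. Indices for the correlation come
  from the mean-value tree, not per-BRI-draw trees. Temporal pleiotropy is
  computed on the raw-TPM stage table because "TPM >= 1" is a raw-scale
  threshold; the 10% bins use `floor(mean/10)` with exactly-100% in its own
  top bin, matching the convention that the "90% bin" means 90–99%.

## The synthetic-data generator

`simulate_transcriptomes()` emulates, with known ground truth, the structure
the method assumes: species-tree-shaped divergence of stage profiles, gene
duplication and loss, replicate noise, and optionally planted
derivedness-correlative groups. On the log2 scale:

* each group has a base level `N(3, 2)` (TPM spanning roughly 1–500);
* the ancestral stage profile adds a **stationary AR(1)** trajectory over
  stages (sd 0.5, lag-1 correlation 0.8): development changes expression
  gradually, without unbounded drift;
* expression evolves along the species tree as Brownian motion per group
  with step `branch_rate * sqrt(branch length)` (default rate 1.5);
* each species adds its own stationary AR(1) stage trajectory (sd 0.35);
* duplication (p = 0.1 per group and species) emits two paralogs with
  log-normal scale perturbations (sd 0.25); loss (p = 0.05) removes the
  group's genes for that species;
* replicates carry log-normal noise (sd 0.1) and every sample column is
  rescaled to TPM (sum 1e6).

Two modeling choices deserve emphasis. First, the stage processes are
**mean-reverting**, not random walks. A walk makes divergence from the
ancestor grow monotonically with stage in every species, which aligns the
per-stage derivedness orderings of all species with each other and with any
shared expression trend — in our measurements roughly 18% of unplanted
groups then show negative correlations in *all* species simultaneously,
i.e. the generator itself would mass-produce spurious DCOs. The stationary
process removes that artifact and is the more defensible model of
developmental expression. Second, the per-stage "distance from ancestor"
that planted DCO profiles decay against is computed from the orthogonal
decomposition (species-wide Brownian shift plus stage-specific component)
rather than from the raw realized deviation: the raw form's finite-size
cross term is constant in expectation across stages and, at realistic
branch rates, drowns the genuine stage signal, making the planted
gradient's orientation relative to the inferred ancestor an uninformative
coin flip.

The default condition — 8 ingroup species and one outgroup on a fixed
balanced tree, 10 stages, 3 replicates, 2,000 groups (3,000 in the
recovery checks) — is a deliberately strong-divergence regime: species
separation (pairwise tree distance >= 0.6 at rate 1.5, per-group shift sd
>= 1.16) clearly exceeds within-species stage spread (stationary sd 0.35).
That is the regime the method itself presumes (criterion 1), scaled to run
in seconds. Problem sizes in the standing checks (100 simulations for the
recovery and monotonicity rates, one 3,000-group simulation for planted-DCO
recovery) were chosen as the smallest sizes at which the binomial noise of
the reported rates is negligible.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: protocol batch effects (a Quartz-Seq-style
amplification bias is handled in real analyses by the `exclude_protocol()`
metadata filter, not modeled), read-depth differences between samples (only
the subsampling-target arithmetic is implemented), annotation-quality
differences between genomes, correlated gene modules (groups evolve
independently), developmental hourglass structure (no stage is privileged),
and any form of sequence evolution. Recovery rates on simulated data
validate the *machinery*, not the biological conclusions one would draw
from real datasets.

## Open design points, resolved

* **"tEuclidean"/"tManhattan"**: treated as plain Euclidean/Manhattan on
  whatever normalized table the chain produced; any transform is the
  chain's job.
* **Per-sample vs per-gene scaling** for rank/z-score: per-sample is the
  default (embryos are the objects being compared); per-gene is behind
  `margin`.
* **Window semantics of the smoothness score**: descriptors are computed per
  3x3 window and averaged over windows (not one co-occurrence matrix per
  block), so a single rough seam cannot be hidden by a large smooth
  remainder; no forced aggregate across the five descriptors is reported,
  wins are per descriptor.
* **Clamped vs raw branch lengths for indices**: clamped, for
  interpretability; raw values are retained as annotations.
* **Friedman blocking**: draws are the blocks, stages the treatments,
  per species.
* **Subsampling order**: read-depth subsampling (external) precedes table
  building; the package only computes the target read counts.

## Known limitations

* Criterion 2 inherits every caveat of the reference phylogeny; a wrong
  reference silently redefines "consistent".
* The derivedness index is a *tree* quantity: embryos of a species share
  the path from the ancestral node to their species clade, so between-species
  index differences are driven largely by that shared path, and within-species
  differences by the clade's internal structure. Interpreting small
  within-species differences requires the BRI distributions, not the
  point estimates.
* Zero-filled lost genes make distances between gene-poor species and
  everything else systematically smaller; this is a property of the method
  being studied, and the package reproduces it faithfully rather than
  correcting it.
* With a single distance method supplied, the smoothness scan degenerates
  (that method wins 100% by construction); the scan is informative only
  across methods.
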
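---
title: "Models and methods in caretile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in caretile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`caretile` implements the analysis chain behind dense tiling CRISPR
activation (CRISPRa) screens of non-coding regulatory DNA and their
single-cell follow-up:

1. **screen** — score tiling-screen guides against a non-targeting control
   null and call *CRISPRa-responsive elements* (CaREs) with a
   sliding-window linear mixed model;
2. **tesla** — identify element-to-gene regulatory links from targeted
   single-cell perturbation data with a covariate-adjusted hurdle test
   against a distal-guide background;
3. **features** — model CaREs from chromatin features with cross-validated
   logistic regression and classify strong vs weak pairs with a random
   forest;
4. **integrate** — attach 3D-interaction and enhancer-catalog evidence to
   element–gene pairs;
5. **simdata** — generate all of the above inputs with planted ground truth.

Every analysis stage is exercised against the synthetic world, so a green
test establishes that the *procedure* recovers what was planted under the
stated noise model — not that any particular biological dataset will behave
the same way.

## The screen model

Counts are normalized to counts per million (CPM) per sample, replicates
are averaged per timepoint, and the response is
$y = \log_{10}(\mathrm{CPM} + c)$ with pseudocount $c = 0.5$ (base 10 to
match the reporting convention of scores as $-\log_{10}$ adjusted $p$).

**Guide level.** The log2 fold change between first and last timepoint is
compared against a normal null fitted to the non-targeting control guides;
two-sided normal-tail $p$-values are Benjamini–Hochberg (BH) adjusted.

**Bin level.** For every 100 bp bin, the guides of the bin and its
`window_bins` neighbours on each side (default 1) enter a random-intercept
linear mixed model

$$ y_{gj} = \beta_0 + \beta_1\,\mathrm{day}_j + b_g + \varepsilon_{gj},
   \qquad b_g \sim N(0, \sigma_b^2),\;
   \varepsilon \sim N(0, \sigma^2), $$

fitted by maximum likelihood (not REML) and compared against the reduced
model without the day term by a likelihood-ratio test on 1 df. The window
default of ±1 bin (±100 bp) reflects that the neighbourhood is described
but not quantified in the underlying design; it is exposed in the
configuration.

*Numerical route.* After timepoint averaging the design is balanced (every
guide observed at every day), where the ML solution is closed form: GLS
equals OLS under compound symmetry with an intercept, and the profile
likelihood splits the residual sum of squares into within-guide and
between-guide parts. Unbalanced designs fall back to one-dimensional
profiled ML over the variance ratio. Both routes compute the exact optimum,
so the LRT is non-negative by nesting; the test suite checks agreement with
a direct numerical maximization of the multivariate-normal likelihood and
with `lme4::lmer(REML = FALSE)` to $10^{-4}$. When the random-intercept
variance collapses to zero the fit degenerates to OLS and is flagged
`singular`; the same LRT applies (this *is* the boundary ML solution).

**Merging and scoring.** Bins significant at BH-adjusted $p < 0.05$ merge
into CaREs when separated by at most 500 bp (end-to-start); bins of
opposite effect direction never merge, since neighbouring guides must act
in the same direction to describe one element. Each CaRE is re-fitted on
all member guides; the score is $-\log_{10}$ of the BH-adjusted $p$
re-adjusted across CaREs (both the CaRE-level $p$ and its adjustment are
recorded, since the adjustment scope at this level is a design choice).
BH adjustment at the bin level spans *tested* bins only — bins with fewer
than two guides in the window are skipped and reported.

## The single-cell model

**Guide thresholding.** Raw guide counts are bimodal: true integrations
produce tens of molecules, ambient contamination mostly one. A
two-component Gaussian mixture on $\log_{10}$ of the nonzero counts is fit
by EM; entries with posterior probability > 0.5 in the lower component are
zeroed. Counts are discrete, so a mixture component can collapse onto a
single value; component standard deviations are floored at 0.1 log10 units
(half the spacing between counts 1 and 2) to keep posteriors meaningful.
If the mixture is degenerate the fixed rule of keeping at least 2
molecules per cell applies and is flagged.

**Filtering.** All-zero guides and genes are dropped; cells need total
guide signal ≥ 2 and ≥ 1 detected gene; the filter iterates to a fixed
point and is idempotent.

**Normalization.** The default (`pearson_nb`) computes clipped Pearson
residuals of a regularized negative-binomial model with a sequencing-depth
offset: per-gene dispersions are estimated by moments and smoothed against
mean expression by kernel regression, and residuals are clipped at
$\pm\sqrt{n_\mathrm{cells}}$. This follows the regularized-NB approach of
modern single-cell normalizers without their empirical-Bayes machinery —
adequate here because calibration is verified by simulation, not assumed.
`log_normalize` (depth-scaled log1p) is available as the simpler
alternative. Batch (run) effects are removed per gene by regression on the
run label (closed form for a factor: subtract run means, restore the gene
grand mean).

**Background and test.** For each perturbation, background cells carry at
least one retained guide, all of whose targets are non-targeting controls
or lie at least 400 kb away (the distal radius stated in the methods of
the underlying design; a 4 kb figure appears once in its narrative — the
methods value is the default and `min_background_distance` is exposed).
Control-carrying cells are always eligible. Expression differences are
tested with a two-part hurdle in the style of MAST's covariate model:
logistic detection ~ group + detected-genes covariate, Gaussian expression
on detected cells ~ group + covariate, component LRTs summed and referred
to $\chi^2_2$. The log2 fold change is computed from pseudocounted
(+0.1) depth-normalized means, matching the fold-change reporting
convention rather than a model coefficient. BH adjustment spans all
(perturbation × gene) tests jointly — the conservative scope. At the CaRE
level, carriers are cells holding any retained guide targeting inside the
element.

## Feature models

Coverage tracks are summarized per region as reads per kilobase: track
scores are binned read counts, a region receives the width-prorated sum of
overlapping bins divided by region width in kb. Histone-mark summaries of
elements use regions resized to ≥ 1 kb centred on the element (flanking
nucleosomes carry the signal); the 100 bp bin feature matrix uses the raw
grid. Features are z-scored with the population (divide-by-$n$) standard
deviation — immaterial after standardization, fixed for reproducibility.
Missing coverage is imputed as zero before z-scoring.

The unified CaRE model is an ML logistic regression of bin membership on
the z-scored features, with Wald 95% intervals, Z-statistic $p$-values and
BH FDR across coefficients. Cross-validated performance uses 10
repetitions of stratified 5-fold CV (50 held-out AUCs) with a
shuffled-label baseline re-permuted per repetition. On (quasi-)separation
the fit falls back to a lightly L2-penalized IRLS (penalty $10^{-4}$) and
is flagged. Per-TF models regress membership on one TF track controlled
for the general features (H3K27ac, H3K4me1, H3K4me3, ATAC), FDR across TFs.

The top/bottom pair classifier is a random forest (bagged CART, Gini
impurity, $\sqrt{p}$ features per split) written in-package because no
forest library is available in the target environment; it reports both
out-of-bag and stratified-CV accuracy (which of the two the original
analysis used is unstated) plus OOB permutation importances and an
average-linkage dendrogram on $1 - |\mathrm{cor}|$ between features.

## Pair integration

Interaction scores attach to (element midpoint, gene TSS) anchor pairs via
2D squares: a score record matches when each of its two intervals,
expanded by the half-width on both sides, contains the corresponding
anchor, order-insensitively. Half-widths are 12.5 kb for Capture-C/Hi-C
(25 kb squares) and 2.5 kb for catalog links and ABC. Expanded intervals
are half-open: an anchor exactly at the expanded end is outside (the
brute-force oracle in the tests uses the same rule). Chicago interactions
require score > 3 (strict); Shaman ≥ 25 (inclusive); ABC records
additionally match by gene identity with the maximum across tissues.

Evidence classes partition elements by precedence nb > other > noEF using
closest-element distance with a 250 bp threshold; distance is edge-to-edge
(0 when overlapping), the standard closest-interval semantics, since the
underlying rule does not state a midpoint convention. Catalog dyad labels
map to promoter, DHS to accessible. Pair geometry: linear distance is
|element midpoint − TSS|; jumped genes counts annotated TSSs strictly
between, excluding the target; strand is ignored; trans pairs are retained
with null geometry and flagged.

## The synthetic world

The generator mirrors the study design at configurable scale: a tiled
region in 100 bp bins with 2–3 guides per bin and 100 non-targeting
controls; counts at days 5/20/29/33 in 2 replicates, negative binomial
(variance $\mu + \mu^2/\theta$, screen $\theta = 50$) around
$10^{\mathrm{base} + \mathrm{slope}\cdot\mathrm{day}}$ scaled to depth;
planted elements carry log10-scale slopes so they are directly comparable
to fitted slopes. All randomness flows from one master seed through named
substreams.

Two generator choices deserve justification:

* **Asymmetric enrichment.** Planted enriched elements default to 0.4× the
  depletion slope magnitude. Equal magnitudes are unrealistic — a
  +0.05 log10/day element grows 44-fold by day 33, dominates the library,
  and drags every null guide's CPM down (compositional drift of about
  −0.002 log10/day), which a well-calibrated scan then "detects"
  everywhere. Depletion can approach completeness while enrichment is
  bounded by the achievable growth advantage; tiling viability screens
  skew strongly towards depleted hits for the same reason.
* **Single-molecule ambient guides.** Ambient guide counts default to a
  Poisson mean of 0.15 (mostly single molecules, rare doubles) with a
  0.006 per-guide leak rate. A heavier ambient mode (mean 0.5) places
  ~4% of its nonzero mass at ≥ 3 molecules, which *no* classifier on
  counts can separate from real integrations — incompatible with the
  intended clearly-bimodal, log10-separable pattern.

Single-cell gene counts are NB ($\theta = 2$ per gene) around lognormal
baseline means, shifted by $2^{\mathrm{log2FC}}$ in carrier cells, and
multiplied by centred per-cell depth, per-run depth and per-run per-gene
batch factors (batch effects are contrasts; the absolute scale belongs to
the baseline). Cells receive Poisson(`moi` = 1) true guides, making the
median unique-guide count 1. Tracks are lognormal binned counts with a
+3-SD lift at a recorded subset of elements; interaction tables plant
scores straddling the integration thresholds.

What the simulator does **not** emulate: guide efficacy variation,
position-dependent CRISPRa effect decay, sequence-driven accessibility,
doublets, or correlated gene programs. Green recovery tests therefore
establish correctness of the statistics, not robustness to these
real-data features.

## Numerical and policy choices

* BH with a stable (p, id) tie order; adjusted values equal the textbook
  step-up procedure.
* LRT statistics are clipped at 0 (exact ML makes negatives impossible up
  to rounding).
* Variance floors: $10^{-12}$ in the mixed model, 0.1 log10 units for
  mixture component SDs.
* Guide-level direction calls use the control-null mean as the reference
  point; two-sided $p$-values (both depleted and enriched hits are
  reported).
* Logistic ridge fallback strength $10^{-4}$; CV fold assignment is
  stratified and reseeded per repetition.
* The hurdle test keeps 2 df even when one component is uninformative
  (constant detection) — conservative for genes detected everywhere.
* Coordinates are 0-based half-open internally, BED on disk; merge gaps
  are end-to-start.

## Known limitations

* **Far-tail calibration of the window LRT.** With ~7 guides and 4
  timepoint means per window, the $\chi^2_1$ reference for the mixed-model
  LRT is mildly anti-conservative in the extreme tail (the fraction of
  null window $p$-values below $2.5\times10^{-5}$ runs about 1.4× nominal
  in null simulations). After BH adjustment across 2000 bins this is
  exactly the tail that matters, so the realized fraction of null screens
  producing at least one discovery is nearer 7% than 5%. A
  Satterthwaite-type F reference would calibrate it, but the $\chi^2$ LRT
  is the procedure this package implements; the test suite documents the
  measured behaviour rather than hiding it.

* The hurdle test omits MAST's empirical-Bayes variance shrinkage; with
  tens of carrier cells and thousands of background cells the shrinkage is
  immaterial, and calibration is verified by simulation.
* The per-window LMM treats timepoint means as observations (replicates
  collapsed first, as the procedure specifies); replicate-level modelling
  is available through the unbalanced path but not the default.
* The random forest is a minimal implementation sized for hundreds of
  pairs; it is not a general-purpose learner.
* Chromosome-size validation of coordinates is limited to what the input
  tables themselves declare.
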
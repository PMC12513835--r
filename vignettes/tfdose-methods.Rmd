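---
title: "Dose-resolved analysis of single-cell TF overexpression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-resolved analysis of single-cell TF overexpression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdose)
```

## The measurement problem

Barcoded transcription-factor (TF) overexpression screens read out two
libraries per cell: a gene expression library (gene x cell UMI counts) and a
TF-barcode enrichment library (TF-ID x cell UMI counts). Because lentiviral
integration and doxycycline induction produce a wide, cell-to-cell spread of
exogenous TF levels, every screen is implicitly a dose-response experiment:
each cell reports the transcriptome obtained at its own TF dose, defined as

$$d = \ln(1 + \mathrm{UMI}_{\text{TF-ID}}).$$

`tfdose` turns this into a quantitative pipeline: assign cells to TFs,
measure how far each cell's transcriptome has moved from matched controls,
fit per-TF logistic dose-response models, and analyse the heterogeneity,
cell-cycle interplay and pairwise TF interactions that the dose axis
reveals.

## Overall transcriptomic change

Control cells (an inert fluorophore construct such as mCherry, overexpressed
under identical induction) define the unperturbed state. The pipeline:

1. log-normalizes counts to a fixed per-cell total (10,000) —
   `normalize_log1p()`;
2. regresses out control heterogeneity per batch by projecting every cell
   onto a PCA subspace fitted on control cells alone (`k_ctrl = 20`
   components by default) and subtracting that reconstruction —
   `regress_control_heterogeneity()`;
3. centres genes per batch and computes one joint PCA (200 components by
   default) — `integrate_batches()`;
4. defines per-cell change as the negative Pearson correlation with the
   control centroid in that space, shifted so control cells average exactly
   zero — `transcriptomic_change()`.

The change statistic is a bounded, correlation-based distance: it ranks
effect sizes monotonically (the package's tests require Spearman > 0.9
against planted effects) but it is not linear in expression fold change, so
absolute plateau values from the full count-level chain are
simulation-calibrated rather than identities. Change computations are meant
to run on G1-phase cells (by adjusted phase) so that cell-cycle programs do
not masquerade as reprogramming.

A change above 0.23 marks a cell as functional; the smallest dose at which
an isotonic (monotone) smoother of change versus dose crosses 0.23 is the
TF's minimal functional dose (`minimal_functional_dose()`). Isotonic
regression was chosen over a parametric inversion because it is
assumption-free, deterministic, and exactly monotone in the threshold; when
a fitted logistic model is available its closed-form inversion
$d = d_{50} - \ln(K/0.23 - 1)/s$ agrees with the isotonic crossing on
noiseless curves (this identity is frozen in the tests).

## Logistic dose-response and TF classes

For each TF with enough cells (>= 20, spanning >= 2 ln-UMI units), change is
modelled as

$$y(d) = a + \frac{K}{1 + e^{-s (d - d_{50})}}$$

with bounded least squares (`a` in [-0.2, 0.2], `K` in [0, 3], `s` in
[0.1, 20], `d50` in [0, max dose + 1]) and a multi-start over dose-quantile
`d50` and `{0.5, 2, 8}` slope initial values (`fit_logistic()`, backed by
Levenberg-Marquardt). The plateau `a + K` is the TF's reprogramming
capacity, and `d50` its dose sensitivity:

* **high capacity**: plateau above 0.23 *and* supported by the data
  (`d50 < max dose`) — an asymptote extrapolated beyond the observed dose
  range is not trusted;
* **high vs low sensitivity** (high-capacity TFs only): midpoint at or
  below a threshold, by default the cohort median `d50` of high-capacity
  TFs (an absolute threshold can be supplied instead).

Because a TF can be called low capacity simply because its doses never
reached the response region, `power_analysis()` truncates each
high-capacity TF's cells at a descending grid of dose thresholds (step
0.25, down to dose 2), refits, and records whether the high-capacity call
survives. A binomial-logit regression of correctness on maximum observed
dose converts these outcomes into, for every low-capacity TF, the
probability that its call is a truncation artefact (`p_false_low`).

## Heterogeneity: dose-driven versus stochastic states

Functional TF cells in G1 are pooled with controls, embedded, and
partitioned on a shared-nearest-neighbour graph (Jaccard weights over
20-NN, pruned at 1/15) with Louvain modularity at resolution 1.2
(`cluster_cells()`). Clusters with fewer than 60% focal-TF cells are
control clusters (strict rule: exactly 60% counts as functional). A TF is a
heterogeneity candidate when at least two functional clusters each hold
between 5% and 95% of its cells, and TFs with fewer than 30 cells are
excluded (`find_heterogeneous_tfs()`). Candidates are reclustered together
with their batch-paired controls (`recluster_tf_with_controls()`).

One behaviour worth knowing: SNN-graph communities are scale-invariant, so
at resolution 1.2 a homogeneous group much larger than the neighbourhood
size can subdivide into dose strata. For candidate detection this is
conservative in the direction that matters — low-capacity TFs cannot become
candidates because their cells are non-functional and never enter the
clustering.

Differential expression between cell groups uses per-gene negative-binomial
GLMs with a batch covariate, tagwise dispersion and likelihood-ratio tests
(delegated to edgeR, with Benjamini-Hochberg FDR); module-score trends over
dose use a local-linear LOESS with a bootstrap band
(`dose_module_curves()`; degree 1 keeps monotone inputs monotone at the
boundaries).

## Cell cycle

S and G2/M program scores are expression-bin-matched module scores
(`module_score()`: 24 bins over average expression, 100 seeded control
genes per set gene, drawn without replacement). The raw phase call is G1
when both scores are non-positive, otherwise the larger score wins.
Because TF overexpression shifts score distributions globally, phases are
re-thresholded against the control population: a cell below the control
95th percentile of both scores is called G1 (`adjust_phase()`). The
thresholds are clamped at zero so adjustment can only move cells toward G1,
which keeps the raw call a lower bound on cycling. Phase-composition shifts
per TF are tested with Fisher's exact test on the 2 x 3 (group x phase)
table — full enumeration for totals up to 300, seeded Monte-Carlo beyond —
and summaries over dose use phase x dose-bin means with bins under three
cells masked.

## TF pairs: dominance, unique states, synergy

For a pair experiment, cells are grouped by a strict rule on the two TF-ID
UMI counts (> 4 UMIs for both = dual; for only one = that TF; otherwise
control). Each dual cell's five nearest neighbours in 20-PC space (self
excluded, distance ties broken by cell index) are tabulated by group
(`knn_group_fractions()`). Dominance is then decided on the fractions
renormalized over the two single-TF groups: dual-TF cells are interleaved
with their own (typically largest) group, so the raw dual-group share
carries no information about which constituent wins; the renormalized
fraction must exceed 0.5 to draw a dominance edge (`dominance_network()`).

Unique combinatorial states are dual cells whose neighbourhoods are at
least half dual cells; their nearest matches within the single-TF groups
form the comparator for differential expression, and genes at FDR < 0.05
with |fold change| > 1.5 define the unique signature
(`unique_state_genes()`). Dose-binned synergy calls (`gene_synergy()`)
compare the dual-cell mean of a gene or module score against single-TF
cells in the matched marginal dose bins, with a 1,000-resample bootstrap
CI; bins are four uniform intervals over (0, max dose] plus a dedicated
zero bin (`dose_bin()`).

## The synthetic-data generator

`simulate_ground_truth()` / `simulate_experiment()` generate screens with
full per-cell truth so that every stage above is testable without a
sequenced dataset. The generative model:

* **Dose**: a point mass at zero (probability 0.1; uninfected or silenced
  cells) plus a log-normal UMI count (meanlog 3.2, sdlog 1.4), giving the
  long-tailed 0-8 ln-UMI spread characteristic of induced screens and
  >= 3 ln-UMI units of spread per TF.
* **Classes**: high-sensitive (K in [0.5, 1], d50 in [0.8, 1.8]),
  high-insensitive (d50 in [3.2, 4.2]) and low-capacity (K in [0, 0.08])
  TFs, in configurable proportions; midpoint ranges are configurable
  (`d50_ranges`) because combination designs need midpoints between the
  pair-grouping threshold (ln 5 ~ 1.6) and typical doses.
* **Counts**: negative binomial with log-normal gene baselines (meanlog
  log 5 — about 8,000 UMI per cell over ~2,000 genes, 10x-like depth) and
  log-normal dispersions around 0.1. Module genes (60 per TF by default, a
  realistic regulon size) are multiplied by
  `exp(effect_scale * K * f(d))` with `effect_scale = 2`, i.e. up to
  ~e^2-fold activation at plateau for a strong TF. These three defaults
  set the signal-to-noise of the whole benchmark and were fixed once while
  designing the generator.
* **Response shapes**: logistic; non-monotonic (difference of two
  logistics); or branching — two mutually exclusive modules with a
  Bernoulli(p = 0.5) choice per cell, independent of dose, emulating
  stochastic state commitment at similar doses.
* **Nuisance structure**: per-gene per-batch log-normal factors (sd 0.1),
  TF-ID doublets (5%), a uniform ambient TF-ID UMI rate (1%), and
  cell-cycle programs (80 genes, 0.8 log-fold in cycling cells) optionally
  coupled to dose monotonically or non-monotonically.
* **Pairs**: dominance (the dominant TF's effect applies whenever its dose
  is nonzero), unique_state (both single effects plus a dedicated module
  once both doses exceed their midpoints) and synergy/antagonism
  (shared-module effect scaled by a factor when both TFs are present).

Reproducibility: every per-cell draw uses a seed derived from the master
seed with an integer hash, standing in for counter-based substreams, so a
fixed (config, seed) reproduces outputs byte for byte.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real screens: structured ambient soup, empty droplets
and transcriptome-driven doublet profiles; gene-gene correlation beyond
module co-regulation; batch effects that change module responses rather
than scale means; continuous cell-cycle topology (phases are discrete);
and the correlation-based change statistic's absolute scale on real data.

`simulate_dose_response_obs()` additionally generates observations directly
on the change scale — `change = a + K f(d) + noise`, with the noise
propagated from negative-binomially distributed module counts and centred
exactly using the analytic NB mass function. Plateau-recovery benchmarks
use these observations because the correlation-based change metric is
bounded and nonlinear in expression amplitude, so an absolute plateau
planted in change units is only identifiable on the change scale; the
count-level chain is benchmarked by its own calibration and ranking
properties instead.

## Numerical choices and degenerate inputs

* Logistic fitting treats non-convergence from all starts as an explicit
  flag; such TFs are excluded from classification, and truncation refits
  that fail count as misclassification in the power analysis.
* Quantiles in the physiological-dose comparison are order statistics
  (type 1), making the 5-95% band exactly reproducible by sorting.
* Zero-variance score vectors (change, similarity, densities) are flagged
  rather than propagated as NaN; all-zero cells are dropped at
  normalization with a warning; all-zero genes get p = 1 and a flag in DE.
* Nearest-neighbour ties are broken by cell index; module-score bin ties
  by gene index; both make results independent of input permutation.
* The QC lower-tail outlier rule uses median - nmads x MAD of log total
  counts (lower tail only, nmads = 4 by default); mito/ribo/coding
  thresholds default to 15% / 60% / 75% and are per-experiment
  configuration.
* TF-ID assignment defaults (min 2 UMIs, second/first ratio < 0.2) are
  deliberate, configurable stand-ins; they are echoed in the demux output
  so downstream users can audit them.

## Problem sizes

The bundled tests and the acceptance script run, per invocation: a 30-TF
cohort at 120 cells per TF on the change scale for fitting and power; a
1,300-cell, 700-gene screen for change-metric calibration; twenty 460-cell
replicates for heterogeneity detection; twenty 400-cell replicates for pair
dominance; and a 2,000-gene, 200-cell matrix for DE calibration. These
sizes give each statistic a comfortable margin over its pass threshold
while keeping a full run in tens of seconds on one CPU; they are package
choices, not method limits — all operations scale to full screens.

## Known limitations

* The change statistic saturates near its correlation bound; two TFs with
  very large but different effects can be indistinguishable at plateau.
* Capacity classification inherits the 0.23 functional threshold; cohorts
  measured with different normalization or PC depth may need a re-derived
  threshold.
* Louvain-at-1.2 granularity means cluster *counts* are not biologically
  meaningful per se; only the candidate rule (two clusters in the 5-95%
  band) is used downstream.
* The Fisher phase test treats cells as independent; overdispersed batch
  structure within a TF would make it anti-conservative.
* Dominance edges summarise means over dual cells; dose-dependent reversals
  within a pair are only visible in the binned grids, not in the network.
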
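---
title: "Methods: blended functional-phylogenetic distances and community assembly"
author: "fpdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blended functional-phylogenetic distances and community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpdiv)
```

## The question the package answers

Communities are assembled from a regional species pool by processes that
leave opposite fingerprints on how *similar* co-occurring species are.
Environmental filtering admits only species whose traits suit local
conditions, so co-occurring species are more similar than a random draw
from the pool; limiting similarity (competition) keeps too-similar species
apart, so they are less similar; neutral assembly leaves no signal either
way. `fpdiv` measures similarity on a blend of two axes — ecological traits
and molecular phylogeny — and asks which blend best explains community
structure along an environmental gradient. The motivating system is a
rotifer community sampled at five points at increasing distance from an
aquaculture effluent inflow, three dates per season across three seasons.

## Distances

**Functional (FDist).** Gower's coefficient over eight traits: geometric-
mean body size (µm, numeric), trophi type, feeding type, predator
protection, lorica type, corona type (categorical), saprobic habitat
preference (4 ordered levels) and saprobic tolerance (ordered 1–5). Per
trait, the partial distance is `|a − b| / range` for numeric and ordinal
traits (ordinals enter as integer ranks; a zero range contributes 0) and a
0/1 mismatch indicator for categoricals; the distance is the equal-weight
mean over traits where both species have a value, so it always lies in
[0, 1]. Ordinals-as-ranks is the classic Gower treatment; an NA trait is
dropped from that pair only, and a pair sharing no scored trait is an
error rather than a silent 0.

**Phylogenetic (PDist).** Pairwise Kimura two-parameter divergences from an
aligned COI-like fragment,

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

with `P` and `Q` the transition and transversion proportions over sites
where both sequences carry an unambiguous base (pairwise deletion of gaps
and Ns — this maximizes usable sites per pair). A non-positive logarithm
argument means saturation, and the pair is reported by name rather than
clamped. A neighbour-joining tree is built from the K2P matrix; negative
NJ branches (possible on non-additive inputs) are clamped to zero with the
deficit moved to the sibling branch, so path lengths are approximately
preserved. PDist is the tree's patristic distance matrix divided by its
largest off-diagonal entry, which maps it onto [0, 1] while preserving
zero self-distances and all ratios (min–max rescaling would not). The
tree-mediated route is the default because the branch lengths are what get
standardized; `pdist_route = "direct"` standardizes the K2P matrix itself.

**The blend.** For a weight $\alpha \in [0, 1]$ and integer exponent
$\rho \ge 1$,

$$\mathrm{FPDist}_{ij} = \big(\alpha\,\mathrm{PDist}_{ij}^{\rho}
  + (1-\alpha)\,\mathrm{FDist}_{ij}^{\rho}\big)^{1/\rho}.$$

$\alpha = 0$ is purely functional, $\alpha = 1$ purely phylogenetic;
$\rho = 2$ (the default) makes the blend an elementwise quadratic mean, so
the larger of the two distances dominates slightly. Concordance of the two
matrices is quantified by a Mantel test (Pearson correlation of
lower-triangle vectors, one-tailed "greater", 9999 permutations by
default), since trait conservatism is the reason blending is informative
at all.

## Effect sizes and the alpha sweep

For each sample, the observed statistic is the abundance-weighted mean
pairwise distance
$\mathrm{MPD} = \sum_{i<j} d_{ij} a_i a_j / \sum_{i<j} a_i a_j$ over the
species present — weighting suppresses the influence of rare species. The
null model redraws the sample's richness uniformly without replacement
from the regional pool (every species observed anywhere in the community
matrix) and reattaches the sample's observed abundance values to the drawn
identities; richness is therefore fixed, the abundance vector preserved,
and only identities randomized. 999 randomizations per sample is the
default.

Null MPD distributions are skewed, so a z-score would mislead; instead the
effect size is the probit of the observed value's null quantile,
$ES = \Phi^{-1}(p)$ with the tie-splitting mid-p estimate
$p = (k + (t+1)/2)/(n+1)$, which is bounded away from 0 and 1 and
symmetric. Negative ES means the community is more clustered than the null
(filtering); positive means overdispersed (limiting similarity). A sample
with fewer than two species has no MPD and is carried through as NA.

The sweep evaluates 41 weights $\alpha = 0, 0.025, \dots, 1$. For each
$\alpha$ and season (the three dates per season pooled, n ≤ 15 samples),
an OLS model ES ~ distance-from-inflow is fitted and its adjusted R²
recorded; the optimal $\alpha$ maximizes adjusted R², ties resolving to
the smallest (most functional, most parsimonious) value. Crucially, the
null randomizations for a given sample are *identical across the grid*
(each sample's sub-seed is derived from its site and date, not from
$\alpha$): the argmax of 41 Monte-Carlo-noisy curves would otherwise be
unstable, and pairing removes that jitter without biasing any single
curve. Per-site mean ES at the optimal $\alpha$ gets a percentile
bootstrap CI (999 resamples) over that site's dates; Rao's quadratic
entropy $Q = \sum_{ij} d_{ij} p_i p_j$ at the optimal $\alpha$ summarizes
each sample's diversity.

The linear model uses metres by default (`position = "rank"` switches to
ordinal site rank); distance in metres preserves the design's uneven
spacing.

## What the synthetic generator emulates — and what it does not

`simulate_study()` reproduces the study design's shape: a 24-species pool,
five sites at 0/500/2500/3000/3500 m, three dates in each of three
seasons. A Yule tree is scaled to 0.2 substitutions/site root-to-tip (a
plausible within-class COI scale); sequences (621 sites, the COI barcode
length) evolve under K2P with transition/transversion ratio 2; body size
is exp-Brownian-motion rescaled to 50–1500 µm, and each discrete trait
follows an equal-rates Markov jump process calibrated to about 1.2
expected changes per root-to-tip lineage — enough change to vary, little
enough to be conserved, which the tests verify as a positive FDist–PDist
Mantel correlation on average. `conservatism = "none"` simulates traits on
a tip-shuffled copy of the tree, preserving trait distributions while
destroying the signal.

Assembly rules: *neutral* draws identities uniformly; *filtering* draws
species with probability $\propto \exp(-s \cdot \delta_i^2)$, where
$\delta_i$ is the species' distance (in the chosen matrix) to the
environmental optimum — taken as the pool medoid, so a strongly filtered
community is a tight neighbourhood whose pairwise distances are genuinely
compressed — and the strength $s$ decays linearly from `filter_strength`
(default 40) at 0 m to zero at the farthest site. A 1-D ordination score
was rejected for $\delta$: filtering a single projected axis barely
compresses the full Gower MPD. *Limiting similarity* assembles
sequentially in random order, rejecting any candidate within `min_dist` of
a resident. Because conserved discrete traits produce near-duplicate
phenotypes, the pool supports only a handful of mutually distant species:
greedy packing rarely exceeds 4–5 members at any useful threshold, so the
limiting defaults are `min_dist = 0.10` with richness 3–4, and an
infeasible user-supplied combination errors with advice rather than
silently under-filling. Richness (5–15 otherwise) and log-normal
abundances (meanlog 3, sdlog 1 — median ≈ 20 individuals) are drawn from
sub-streams shared across scenarios, so with one master seed the scenarios
differ only in identity selection; `filter_strength = 0` takes the
identical code path as neutral.

The generator does **not** emulate seasonal succession, density dependence,
observation error in counts, alignment error, or rate variation across
sites and lineages. Passing tests therefore demonstrate that the inference
chain recovers assembly rules *when its own distance models hold*; they do
not certify behaviour under model misspecification on real data.

## Numerical and design choices

- **Determinism.** Every stochastic stage derives a named sub-seed from
  the master seed; per-sample null streams are keyed by site and date, so
  results are invariant to sample order and reruns are byte-identical.
- **Degenerate inputs.** All-zero distance matrices cannot be
  standardized (error); constant off-diagonal distances make Mantel r
  undefined (error); empty and single-species samples yield NA effect
  sizes and are flagged, and a season with fewer than three defined ES
  values yields an NA optimum with a warning.
- **Ties.** Probit ES splits ties symmetrically; the alpha argmax takes
  the smallest maximizing weight; NJ pair selection is delegated to the
  deterministic `ape::nj` implementation.
- **Pool definition.** The regional pool is the union of species observed
  anywhere in the community matrix — the least arbitrary choice; traits
  and alignment may cover more species, but matrices are restricted to
  the pool before analysis.
- **Scales.** Body size enters Gower on the raw µm scale (no log), since
  the range-normalized partial distance is translation-invariant and the
  trait's provenance is a geometric mean already.

## Problem sizes used by the test-suite

Unit and property tests run on 3–24 species and 45-sample designs;
statistical calibration uses 300–1000 replicate draws with 200–1000
nulls each; scenario-recovery checks use 20 seeded studies per scenario
with 199–499 nulls per sample and the full 41-level grid on one season.
These sizes keep each property's Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

- K2P saturation aborts the distance matrix rather than falling back to a
  different model; heavily diverged alignments need a different tool.
- The surrogate-species practice (substituting a close relative when a
  sequence is unavailable) is deliberately not implemented: the alignment
  must cover every community species, and gaps are hard errors.
- Only classic Gower is offered (no Podani ordinal correction, no trait
  weighting); only NJ trees (no likelihood or Bayesian inference); no
  partial Mantel or Spearman variant; no spatial autocorrelation or
  mixed-effects modelling of ES.
- Adjusted R² with n ≤ 15 samples per season is a coarse model-selection
  signal; the paired-null design stabilizes the argmax but cannot add
  information that small seasons lack.
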
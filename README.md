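# fpdiv

Community-assembly inference from blended functional and phylogenetic
species distances, built around rotifer communities sampled along an
aquaculture-effluent gradient. The package is for community ecologists who
have (a) a mixed trait table, (b) an aligned barcode fragment per species
and (c) repeated abundance samples along a gradient, and who want to know
*which process structures those communities* — environmental filtering,
limiting similarity, or neither — and *on which axis* the signal lives:
ecology or phylogeny.

## The method

Two species-distance matrices are built over the regional pool:

- **FDist** — Gower's distance over eight traits (body size in µm; trophi,
  feeding, protection, lorica and corona types; ordered saprobic habitat
  preference and tolerance), always in [0, 1];
- **PDist** — Kimura two-parameter divergences
  *d* = −½ ln[(1 − 2P − Q)√(1 − 2Q)] from the alignment, run through
  neighbour-joining; the tree's patristic distances are standardized to
  [0, 1] by their maximum.

They are blended with a tunable weight α and exponent ρ (default 2):

```
FPDist_ij = ( α · PDist_ij^ρ + (1 − α) · FDist_ij^ρ )^(1/ρ)
```

For every sample, the abundance-weighted mean pairwise FPDist is compared
with 999 null communities of identical richness and abundance vector drawn
from the pool; the effect size is the probit of the observed null
quantile, ES = Φ⁻¹(p). ES < 0 means species are more similar than chance
(environmental filtering), ES > 0 less similar (limiting similarity). The
weight α is swept over 41 values from 0 to 1; per season, the α maximizing
the adjusted R² of ES ~ distance-from-inflow is selected, and per-site
mean ES (bootstrap CI) plus Rao's quadratic entropy Q = Σ d_ij p_i p_j are
reported at that optimum. A Mantel test (9999 permutations) quantifies
FDist–PDist concordance. A synthetic-study generator with known assembly
rules (neutral / filtering / limiting) provides an end-to-end testbed.

## Worked example

Simulate a filtered study and run the full chain:

```r
library(fpdiv)

st  <- simulate_study(scenario_spec("filtering", seed = 42))
res <- run_pipeline(st$traits, st$alignment, st$communities,
                    pipeline_config(seed = 42))
print(res)
```

```
Functional-phylogenetic assembly analysis
  species pool: 24, samples: 45
  Mantel FDist~PDist: r = 0.5171, p = 0.0001 (9999 permutations)
  spring: optimal alpha = 0.2 (adj R^2 = 0.372)
  summer: optimal alpha = 0 (adj R^2 = 0.271)
  autumn: optimal alpha = 0 (adj R^2 = 0.414)
```

The Mantel r says traits are phylogenetically conserved in this pool. The
small optimal α values say the *functional* side carries most of the
explainable gradient signal — the phylogenetic component adds little. The
per-site table (`res$site_summary`) then localizes the signal: mean ES is
significantly negative at the sites nearest the simulated inflow (K1–K2,
where the generator filters hardest) and near zero at the far site, and
Rao's Q (`res$rao`) rises with distance from the inflow. That is exactly
the filtering signature the scenario built in; on `"neutral"` data the
same chain returns ES centred on zero and no significant sites.

The numbered scripts under `analysis/` run this workflow as a narrative —
`01_simulate_data.R` (three scenarios to `results/data/`),
`02_distances.R` (FDist, K2P, bootstrapped NJ tree, Mantel),
`03_alpha_sweep.R` (the sweep above), `04_diversity.R` (Rao's Q by site
and the cross-scenario ES comparison) — each writing tidy CSVs under
`results/`.

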
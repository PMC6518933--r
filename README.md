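# pondscape

Longitudinal habitat-loss biodiversity analysis for pond metacommunities.

## The problem

When a landscape loses most of its habitat patches, species are lost from
the region simply because fewer habitats are sampled — the species–area
relationship guarantees it. The harder and more consequential question is
whether the habitats that *remain* also lose species, which would point to
disrupted spatial processes (colonisation–extinction dynamics across a
thinning habitat network) or to degraded local conditions rather than to
sampling alone. pondscape implements the complete analysis chain for
answering this with two-epoch incidence surveys of a pond network, and is
aimed at community ecologists working with historical resurvey data.

The chain, stage by stage:

1. **Sampling-only null** — sample-based rarefaction of the earlier
   community down to the later footprint, in two currencies: habitat
   number, with the exact hypergeometric expectation
   `E[S_m] = Σ_i [1 − C(n−n_i, m)/C(n, m)]` behind a 2000-run resampling
   ensemble, and total habitat area, with quantile-regression splines
   (τ = 0.025, 0.5, 0.975, pinball loss on a cubic B-spline basis)
   providing the central curve and 95% envelope.
2. **Predictor competition** — per accumulation run, the additive
   penalized-spline model `richness ~ s(sites) + s(area)` scored by
   drop-one explained deviance: does habitat *number* or habitat *area*
   carry the signal?
3. **Network contraction** — each pond's closeness (mean Euclidean
   distance, km, to all other extant ponds) per epoch and its temporal
   change; increases mean the pond became more peripheral.
4. **Diversity change** — α, γ, Whittaker β = γ/ᾱ per epoch, and
   permutation effect sizes (group-label permutation with the original
   unequal group sizes, 200 permutations) for the change in mean local
   richness and in β.
5. **Drivers** — a binomial GLM of regional extinction on species traits
   (√occupancy, log body size, salinity preference) and a Gaussian model
   of local richness change on connectivity, salinity and area change,
   each decomposed by three-set commonality analysis into pure and shared
   adjusted-R² fractions.
6. **Synthetic landscape generator** — a fully parameterised two-epoch
   metacommunity simulator (lognormal pond areas and conductivities,
   Beta-distributed prevalences, Gaussian salinity niches, clustered
   habitat loss, logistic per-incidence relaxation) so every stage runs,
   is tested, and demonstrates parameter recovery with no external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
landscape and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_rarefaction.R
Rscript analysis/03_predictor_competition.R
Rscript analysis/04_network_diversity.R
Rscript analysis/05_drivers.R
```

Stage 1 builds the default world — 116 ponds, 53 sampled in the first
epoch, 30 surviving (24 resurveyed) in the second — and prints:

```
Synthetic landscape (seed 1): 116 ponds, 30 surviving to epoch 2
Epoch 1: 53 sites, gamma = 38, mean alpha = 5.98
Epoch 2: 30 sites, gamma = 25, mean alpha = 2.23
```

Stage 2 is the core contrast. Observed regional loss is 13 species, but
rarefying the epoch-1 community to the remaining footprint expects far
less:

```
Observed net regional loss: 13 species
Expected from losing habitats alone (30 sites): 4.29 (rounded 4), 95% CI [1, 8]
Expected from losing area alone (289.92 ha): 6.23 (rounded 6), 95% CI [2.74, 10.4]
-> observed loss exceeds the sampling-only envelope: species loss is not
   explained by habitat loss alone
```

The observed loss sits far above the envelope: the surviving ponds lost
species beyond what removing habitats from the 1950s landscape would
predict. Stage 4 quantifies the local side of the same story — a loss of
about 3.8 species per pond (permutation p ≈ 0.005) as the network
contracted — and stage 5 asks why, at both scales:

```
Pure adjusted pseudo-R2: rarity 0.672, body size 0.136, preference 0.075

Local drivers over 24 resurveyed ponds:
                  coef      p
(Intercept)    -5.3071 0.0000
d_closeness    -0.7439 0.0052
d_conductivity -0.1961 0.1513
d_log_area      0.5804 0.6137
Pure adjusted R2: connectivity 0.261, salinity 0.036, area -0.022
```

Regionally rare species bore the extinctions (largest pure fraction by
far), and at resurveyed ponds the change in connectivity — not salinity,
not area — explains the richness change: ponds whose closeness index
deteriorated most lost the most species. That is the fingerprint of
connectivity-mediated, delayed species loss rather than a sampling
artefact, here recovered from a world simulated with exactly that
mechanism.

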
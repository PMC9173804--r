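# paleoniche

Ecological niche modelling and population connectivity for Central African
hunter-gatherers (CAHG), as a tested, reusable analysis pipeline.

## The problem

Are the distribution and density of Central African hunter-gatherer
populations shaped by long-term ecological adaptation, and did shifting
paleoclimates drive their demographic fragmentation and reconnection? The
pipeline answers this in six linked stages, each of which is an exported,
unit-tested set of functions:

1. **Niche model** — camp presences (20-km land buffers on a 0.1° grid)
   vs background, fitted by L1-penalized logistic regression over the six
   maximum-entropy feature classes (linear, quadratic, product, hinge,
   threshold, categorical), with the select07 collinearity screen,
   repeated 80/20 cross-validation (rank AUC, Cohen's κ, sensitivity,
   specificity, TSS = sens + spec − 1), a max-sens+spec decision threshold
   τ, and a favorability-GLM alternative
   (F = odds(P) / (n₁/n₀ + odds(P))).
2. **Paleo-projection** — clamped projection of the fitted model onto each
   1,000/2,000-year time slice; binarization at τ; the range-size series
   PPₜ.
3. **Density & metapopulation** — Tukey-fenced camp sizes; OLS slope b of
   density on suitability; quantile-regression wedge envelope (50th–99th
   percentiles, R1 goodness-of-fit); potential population per cell
   PPS = max(0, P̄ + b(s − s̄)); metapopulation = GPPS × GCS / ASA with
   GCS = 123 km², ASA = 1,079 km².
4. **Connectivity** — camps = 0.16 × PPₜ placed at random on presence
   cells; anisotropic travel time by Tobler's hiking function
   W = 6·exp(−3.5·|S + 0.05|) km/h on the 8-connected lattice
   (Dijkstra); neighbours within a 7-h walk.
5. **Archaeological validation** — ¹⁴C register curation (carbonates,
   errors > 1,000 y, bad stratigraphy, missing lab codes, farming
   indicators/chronocultures) and 0.5°-per-slice deduplication; observed
   sites on predicted presences O vs Eₜ = Nₜ·PPₜ/TC; χ² goodness of fit;
   a 1,000-fold date-permutation test with p = (1+k)/(1+n);
   performance-vs-age and soil-style confounder screens.
6. **Genetic connectivity** — IBD segment merging (0.6-cM gaps), length
   classes 1–5 / 5–10 / >10 cM, cross-population sharing probabilities
   with minimum-block filters (4 / 2 / 2); Weir–Cockerham F_ST; rarefied
   private allelic richness per variable site.

A first-class synthetic-data module (`sim_config()`, `gen_*()`) generates
every input with known ground truth — drifting Gaussian-random-field
landscapes, wedge-shaped camp sizes, suitability-enriched or null site
registers, island-model genotypes, preset IBD sharing rates, DEMs with
river barriers — so each stage has parameter-recovery and calibration
tests that run without any download.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on the
synthetic study system (seed 20260929) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate_landscape.R
Rscript analysis/02_fit_niche_model.R
...
Rscript analysis/07_genetic_connectivity.R
```

Stage 2 prints, for example:

```
presence raster: PP = 1331 of TC = 2500 cells (ratio camps/PP = 0.225)
fitted maxent_like model: 19 active features, threshold tau = 0.513
cross-validated skill (100 reps): AUC 0.891, TSS 0.671 (sens 0.85, spec 0.82)
```

meaning: 300 camps paint 1,331 of 2,500 land cells as presences; the
penalized fit keeps 19 features; held-out skill is strong (AUC 0.89), and
the model classifies presences/absences correctly 85%/82% of the time.
Stage 6 prints:

```
archaeological validation: O = 80, E = 50.13 of n = 90 sites
  permutations: mean 68.280, SD 3.274, empirical p = 0.0010 (1000 perms)
```

meaning: 80 of 90 dated sites sit on predicted presences at their own
dates, against 50.1 expected under independence, and no random reshuffling
of the dates does as well (the generator planted exactly this
date-suitability signal, p_suit = 0.8). Stage 7 recovers the genetic
ground truth: F_ST = 0.102 (preset 0.10) and IBD sharing probabilities
0.487 / 0.297 / 0.097 against presets 0.5 / 0.3 / 0.1.

A minimal interactive session:

```r
library(paleoniche)
truth <- gen_landscape_stack(sim_config(seed = 1))
pg    <- rasterize_presences(gen_camps(truth, 300), truth$grid)
model <- fit_enm(pg, get_slice(truth$stack, 0), background_n = 1000)
range_series(model, truth$stack)      # predicted range size per slice
```

## Repository layout

```
R/                  the package: every stage's computation
analysis/01..07     thin narrative drivers over the package
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  headline-quantity recomputation (JSON out)
vignettes/methods.Rmd the models, assumptions and design choices
```
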
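# dispersalSDM

Species distribution models (SDMs) predict where the climate will be
suitable; they are silent on whether a species can actually get there.
`dispersalSDM` is an R package for quantifying that gap: it fits a
presence-background niche model, binarizes it at the TSS-optimal
threshold, and projects species ranges annually to 2100 under two
assumptions run side by side — **unlimited dispersal** (occupancy equals
suitability, the classical SDM reading) and **limited dispersal**
(occupancy can only expand at the species' own annual dispersal speed).
It is aimed at ecologists and biogeographers studying climate-driven
range shifts, extinction risk of poor dispersers, and spread of invasive
species.

## The model in brief

**Niche model.** A Gibbs density over landscape cells,
*p(x) = exp(β·f(x)) / Z*, with linear/quadratic/product features of
min–max-scaled climate variables, fitted by maximizing the L1-penalized
presence log-likelihood

> Σ_presences log p(x) − RM · Σ_f λ⁰_f |β_f|,  λ⁰_f = √(s²_f / n)

(MaxEnt-style default penalties; RM is the regularization multiplier).
Feature class (L, Q, P, LQ, LP, QP, LQP) and RM ∈ {1, 1.5, 2, 2.5, 3}
are tuned by AICc; suitability output is the cloglog transform
*1 − exp(−e^H p(x))*. Evaluation: TSS, Cohen's Kappa at the TSS-optimal
threshold, and the partial-ROC AUC ratio (bootstrap, omission tolerance
E = 0.05).

**Dispersal simulation.** Each year the model is projected onto that
year's climate, thresholded, and masked (cells above 3000 m for the
insect profiles). Limited mode then grows occupancy by per-cell dispersal
events: four cardinal directions, distances from an exponential with
rate 3/d_max truncated at d_max (mean 0.2809·d_max), convex-hull buffers
rasterized to the grid, intersected with the year's suitable cells.
Areas are exact spherical cell areas (R = 6371 km), so range sizes are
equal-area without any reprojection. A ten-species registry (amphibians,
resident birds, invasive insects; d_max from 0.5 to 50 km/yr) and a
virtual-species synthetic-data generator make the whole pipeline runnable
and testable offline.

## Worked example

The default configuration is a fully synthetic demo: a 50 × 50 grid at
0.1°, three bioclim-style variables with a forcing trend (moderate and
high pathway), one virtual species with a known Gaussian niche, and a
2025–2100 simulation horizon.

```r
library(dispersalSDM)
res <- runSpecies(runConfig(masterSeed = 42), quiet = FALSE)
#> stacks ready: RCP4.5-like, RCP8.5-like
#> occurrences: 400 raw -> 303 filtered -> 240 thinned
#> predictors: bio01, bio12
#> model: FC=LQ RM=1.0 AICc=2686.22
#> threshold tau=0.547 TSS=0.732 Kappa=0.640 pAUC=1.575
#> scenario RCP4.5-like: proportion decreased
#> scenario RCP8.5-like: proportion decreased
print(res)
#> SpeciesRunResult 'virtual_species': 240 presences, model FC=LQ RM=1.0, tau=0.547
#> ScenarioSeries 'virtual_species' (RCP4.5-like), 2024-2100
#>   area limited   46421 -> 0 km^2 (dec-inc-dec)
#>   area unlimited 56393 -> 2467 km^2 (decrease)
#>   proportion 82.3% -> 0.0% (decreased)
#> ScenarioSeries 'virtual_species' (RCP8.5-like), 2024-2100
#>   area limited   40534 -> 0 km^2 (decrease)
#>   area unlimited 45942 -> 0 km^2 (decrease)
#>   proportion 88.2% -> NA% (decreased)
```

Reading the output: 400 raw occurrence records survive the quality
filters (coordinates; uncertainty ≤ 10 km or missing; whitelisted basis
of record; year 2000–2024) as 303, and one-per-cell thinning leaves 240
presences. The correlation screen (|r| < 0.7, temperature and
precipitation first) keeps two predictors; AICc tuning picks LQ features
at RM = 1. The model separates presences from background well
(TSS 0.73, Kappa 0.64, partial-AUC ratio 1.58). Under both forcing
pathways the dispersal-limited range (here a bird-like disperser,
12 km/yr) occupies 82–88% of the unlimited range in 2024 and collapses
ahead of it as warming pushes suitability off the landscape — under high
forcing even the unlimited range reaches zero (the `NA%` year), the
limited one having gone extinct decades earlier after one fully
unsuitable anomaly year. This asymmetry — permanent extirpation versus
instant recolonization — is exactly the overestimation that ignoring
dispersal produces.

Per-scenario results are S4 objects: `res$series[["RCP4.5-like"]]` holds
the km² series, standardized curves, proportion curve and pattern labels
(`plot()` draws the two-panel trajectory figure);
`res$runs[[scenario]]$limited` holds the yearly occupancy maps. Passing
`outDir=` to `runConfig()` writes the artifact tree (CSV series, model
JSON, occupancy rasters as ESRI ASCII grids, manifest with MD5 hashes);
reruns with the same config and master seed are bit-identical.

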
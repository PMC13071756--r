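---
title: "Dispersal-constrained species distribution modelling: methods and design"
author: "dispersalSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal-constrained species distribution modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

Correlative species distribution models (SDMs) map where the climate is
suitable; they say nothing about whether a species can *reach* newly
suitable areas as the climate shifts. Assuming unlimited dispersal
overstates future ranges for slow dispersers (and hence understates
extinction risk), while for fast-dispersing invasives the two assumptions
nearly coincide. `dispersalSDM` implements both ends of that comparison
as one pipeline: a presence-background niche model, a TSS-optimal binary
range, and an annual colonization simulation from 2025 to 2100 in which
occupancy can only expand at the species' dispersal speed — run side by
side with the unlimited-dispersal counterfactual, for a moderate and a
high climate-forcing scenario.

# The niche model

The model is a Gibbs density over landscape cells. With feature vector
$f(x)$ built from the environmental variables at cell $x$, the probability
assigned to a cell of the landscape sample (presences plus background) is

$$p(x) = \frac{\exp(\beta \cdot f(x))}{Z}, \qquad
  Z = \sum_{x' \in \text{landscape}} \exp(\beta \cdot f(x')).$$

Fitting maximizes the penalized presence log-likelihood

$$\sum_{i \in \text{presences}} \log p(x_i)
  \;-\; \mathrm{RM} \sum_f \lambda_f^0\, |\beta_f|,$$

with per-feature penalties $\lambda_f^0 = \sqrt{s_f^2 / n}$ ($s_f^2$ the
feature's variance over the $n$ presences, floored at $10^{-4}$), so that
regularization relaxes as presence data accumulate — the same shape as
the canonical MaxEnt default penalties. The regularization multiplier RM
scales all penalties jointly.

Features are built from min–max scaled variables (bounds taken over the
calibration sample, projection values clamped back into $[0,1]$):
linear terms (L), squares (Q) and all pairwise products (P), combined as
one of L, Q, P, LQ, LP, QP, LQP. Hinge and threshold features are
deliberately out of scope. Because a Gaussian niche has a log-quadratic
density, the LQ family can represent such a niche exactly — which is what
makes the virtual-species recovery checks sharp.

The optimizer is FISTA (accelerated proximal gradient) with backtracking
line search and restart on non-monotone steps. The problem is convex, so
the fit is deterministic; the stopping rule is a relative objective change
below $10^{-10}$ (cap 5000 iterations). Coefficients with
$|\beta_f| > 10^{-8}$ count as nonzero for $k$.

**Tuning.** All feature-class × RM candidates (7 × {1.0, 1.5, 2.0, 2.5,
3.0} by default) are fitted and compared by
$\mathrm{AICc} = 2k - 2\mathrm{LL} + 2k(k+1)/(n-k-1)$, with $n$ the
number of thinned presence cells. The minimum-AICc candidate wins; ties
break toward fewer nonzero coefficients, then the simpler feature class
(L < Q < P < LQ < LP < QP < LQP), then smaller RM. Selection is by AICc
alone; 4-fold spatial-block omission (quadrants at the presence medians,
points on a median going to the lower block) is computed for the winner
and *reported*, not used for selection — reporting keeps the validation
information available without making the selection rule two-headed.

**Output scale.** Raw densities are turned into suitabilities with the
complementary log-log transform
$s(x) = 1 - \exp(-e^{H} \, p(x))$, where $H$ is the entropy of the
calibration raw distribution — the modern MaxEnt default output. Both
$Z$ and $H$ are frozen at calibration, so projecting the model onto its
own calibration layers reproduces the calibration suitabilities exactly.

**Background.** The background sample is
$\mathrm{round}(0.01 \cdot n_{\text{valid}} \cdot n_{\text{vars}})$ cells
(capped at $n_{\text{valid}}$), drawn uniformly without replacement with
a named seed stream. Background cells double as pseudo-absences for
TSS/Kappa and thresholding, since a presence-background design has no
true absences.

# Data preparation

*Filtering* retains records that have coordinates, an uncertainty of at
most 10 km **or a missing uncertainty**, a whitelisted basis of record
(HUMAN_OBSERVATION, OBSERVATION, PRESERVED_SPECIMEN,
MACHINE_OBSERVATION), and a collection year in 2000–2024. A missing year
fails the filter: the uncertainty rule's explicit "missing allowed"
exception shows the convention when missingness is tolerated, and no such
exception is stated for years, so the conservative reading is used.

*Thinning* keeps one record per grid cell — the **first in input order**,
a deterministic rule that needs no RNG — and anchors the thinning lattice
to the climate grid itself, so occurrence cells and model cells coincide.
Thinning runs last, after pooling sources.

*Predictor selection* screens the current-period mean layers pairwise
(Pearson $|r| < 0.7$) with a greedy scan in an explicit priority order.
The priority list is where biological judgement enters; the default puts
annual mean temperature and annual precipitation first, which mirrors the
variables most consistently retained for real species. VIF
($1/(1-R^2_j)$, each variable regressed on the other selected ones) is
computed as a *check* with a warning at 10, not a hard filter — the
correlation screen is the active rule, and on |r| < 0.7 subsets VIF
violations are rare.

# Geometry and areas

Rasters are regular longitude/latitude grids: south-west origin,
half-open cell bounds $[\text{edge}, \text{edge}+\text{res})$, cell-center
sampling. These conventions are stated because nothing downstream is
robust to changing them silently.

Cell areas are computed analytically on a sphere of radius $R = 6371$ km:
$A = R^2\,\Delta\lambda\,(\sin\varphi_{\text{top}} -
\sin\varphi_{\text{bot}})$. Any equal-area projection yields the same
sums, so area accounting is projection-free and exactly testable (a 0.1°
cell at the equator is 123.64 km²). The metric size of a cell for
dispersal arithmetic is taken at the cell's own latitude — the east-west
extent shrinks with $\cos\varphi$ — rather than using one global
constant, which avoids a systematic bias at high latitudes; the
meridional size of a 0.1° cell is 11.12 km.

# The dispersal simulation

Each simulated year, for every scenario:

1. project the niche model onto that year's climate layers,
2. binarize at the species' TSS-optimal threshold $\tau$ and apply the
   hard elevation bound (cells above 3000 m are unsuitable for the
   insect profiles regardless of climate),
3. advance occupancy.

In **unlimited** mode occupancy *is* the suitable set (and consumes no
random numbers). In **limited** mode every occupied cell emits one
dispersal event: four directions (the grid cardinals), one distance per
direction drawn from an exponential with rate $\lambda = 3/d_{\max}$
truncated at $d_{\max}$, endpoints converted to lon/lat with the local
metric scale, and the convex hull of the source center plus the four
endpoints rasterized into a buffer (cells whose center falls inside,
vertex cells always included). The new occupancy is
(previous occupancy ∪ all buffers) ∩ this year's suitable set.

Design choices that the underlying method statement leaves open, and how
they were resolved:

- **Kernel rate $\lambda = 3/d_{\max}$.** "Exponential, bounded by the
  maximum" fixes neither the rate nor the truncation behaviour. With
  $\lambda d_{\max} = 3$, 95% of the untruncated mass lies below
  $d_{\max}$, the truncated mean is $0.2809\,d_{\max}$ in closed form,
  and — because the inverse CDF is then linear in $d_{\max}$ for a fixed
  uniform draw — occupancy is provably monotone in $d_{\max}$ under
  common random numbers, which the tests exploit.
- **Buffer geometry.** The hull of source + 4 endpoints is the simplest
  closed "buffer" consistent with four directional draws; a union-of-rays
  alternative would colonize thin spokes only. Degenerate hulls
  (collinear endpoints) degrade to the cells along the segments.
- **Dispersal source set.** Events are emitted from every occupied cell,
  not only from the original occurrence points; a range that has grown
  should disperse from its whole extent. A frontier-only optimization
  (skip cells whose full queen neighbourhood is occupied) is available
  and, with the per-cell seed streams, provably yields a subset of the
  full step — equal whenever draws cannot escape the interior.
- **Extirpation.** Occupied cells that turn unsuitable are removed the
  same year (strict intersection). No persistence buffer, no rescue: a
  single fully-unsuitable year therefore extirpates a limited run
  permanently while the unlimited counterfactual "resurrects" when
  suitability returns — which is precisely the asymmetry between the two
  assumptions the comparison is meant to expose.
- **Initialization (year 2024).** Occupancy starts from the suitable
  cells within $m \cdot d_{\max}$ km of any occurrence point, $m = 1$
  for natives and $m = 10$ for invasives (whose short invasion history
  means known points underestimate the occupied neighbourhood); cells
  containing an occurrence are always included when suitable.
- **Grid refinement.** If $d_{\max}$ is smaller than the metric cell
  size, annual dispersal would be invisible, so the simulation grid is
  refined by $\lceil \text{cell size}/d_{\max} \rceil$ and suitability
  is resampled (nearest-neighbour) to the refined grid. Both modes run
  on the same simulation grid so their areas are directly comparable.
- **Seeding.** One master seed fans out into named streams (climate
  noise, occurrence sampling, background, kernel, bootstrap) via a
  deterministic hash; kernel draws are further keyed by (year, cell,
  round). Reruns are bit-identical, stages can be reproduced in
  isolation, and runs differing only in $d_{\max}$ share draws.

# Range dynamics and classification

Yearly areas are spherical-cell-area sums over occupied cells.
Standardized series divide by the 2024 baseline (the initial occupancy
for the limited run, the current suitable area for the unlimited run);
the proportion curve is $100\,A_{\text{lim}}/A_{\text{unlim}}$, with
years of zero unlimited area flagged undefined rather than dropped.

Trajectories are classified from a centered moving average (window 10 yr)
of the series: if the smoothed range stays within 10% of the baseline the
series is *no-change*; otherwise the sign sequence of smoothed first
differences (runs under 5 yr merged into their longer neighbour) maps
`+`, `+-+`, `-+-`, `-` to linear-increase, inc-dec-inc, dec-inc-dec and
decrease, anything else to *other*. The proportion change compares the
mean of the last five years against the first five with a 5-percentage-
point tolerance (decreased / unchanged / increased). The smoothing
windows and tolerances are declared defaults exposed as arguments, not
recovered values; a centered moving average was preferred over local
regression because it is deterministic and parameter-light.

The built-in ten-species registry spans the full dispersal spectrum the
pipeline is meant to cover — two amphibians at 1 km/yr, five resident
birds between 0.5 and 14 km/yr, three invasive insects between 10 and
50 km/yr (with the 3000 m elevation bound and the 10× initialization
multiplier) — and classifies 4 / 2 / 4 into the >10, 2–10 (boundaries
inclusive) and <2 km/yr classes.

# The synthetic study system

The generator exists so every downstream stage is testable without
external downloads; its defaults *are* the study conditions of the test
suite and are not tuned per test.

Climate: a 50 × 50 grid at 0.1° anchored at 100°E, 25°N, years
2000–2100, three bioclim-style variables. Each variable is a fixed
spatial field (baseline plus north–south and west–east linear gradients)
plus a forcing trend (units/yr × scenario multiplier; 1 for the
moderate, 2 for the high pathway) plus a grid-wide AR(1) anomaly
(stationary SD per variable, coefficient 0.3) shared between scenarios
generated from the same seed. Defaults: temperature 14 °C baseline,
−1.2 °C per degree latitude (a steep, montane-like gradient),
+0.02 °C/yr — about +2 °C by 2100 under moderate and +4 °C under high
forcing, matching the intent of the two pathway intensities; annual
precipitation 900 mm, +40 mm per degree longitude, −0.8 mm/yr;
seasonality as a weaker third axis.

Virtual species: a Gaussian product niche
$s(z) = \exp(-\sum_j (z_j-\mu_j)^2 / 2\sigma_j^2)$ — the simplest truth
with a known optimum, and exactly representable by LQ features. The demo
species ($\mu$ = 12.5 °C, 960 mm, 645; $\sigma$ = 0.8 °C, 45 mm, 25)
occupies roughly the upper tenth of the landscape's suitability range, a
regionally restricted species on this window. Occurrences are sampled
with probability proportional to the period-mean true suitability,
jittered by a positional error (2 km in the demo), and dressed with the
metadata the filters act on: a mixture of uncertainty values (30%
missing, 10% above 10 km), basis-of-record tokens including rejectable
ones, and a 5% share of pre-period years — so the cleaning rules have
real material to reject.

What the generator does **not** emulate: the covariance structure of real
bioclim variables (its fields are additive gradients), GCM physics,
spatially heterogeneous weather anomalies, observation bias fields
(available as a parameter, off by default), land-use masks, and real
coastlines (every cell is valid). Passing the recovery checks therefore
shows the machinery is correct on a system whose truth is known — not
that any particular real species is modelled well.

# Numerical choices and degenerate inputs

- Optimizer tolerances as above; the landscape raw density renormalizes
  to 1 after every fit (checked to $10^{-8}$).
- AICc is $+\infty$ when $n \le k+1$; tuning errors out only if *no*
  candidate is finite.
- Threshold scanning uses the observed suitability values as the
  candidate set and breaks ties toward the smallest threshold; a constant
  surface is an error.
- Partial-ROC: omission tolerance $E = 0.05$, 500 bootstrap iterations
  on 50% presence resamples — the conventional settings for the method;
  the ratio integrates the sensitivity-vs-area curve above
  $1-E$ against the diagonal over the same span.
- Zero-variance variables are flagged and excluded (selection) or
  dropped with a warning (features); a landscape with no informative
  variable fits the uniform maximum-entropy density rather than erroring.
- $d_{\max} = 0$ degenerates to no-dispersal (pure intersection), by
  contract rather than by error.
- Hulls with fewer than three distinct or collinear vertices rasterize
  to the cells along the connecting segments.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
the full demo is one species × two scenarios × 76 years on the 50 × 50
grid (limited + unlimited, under 15 s); unit fixtures use 10–30 cell
grids; the metric cross-checks use 1000 random instances each. These
sizes were chosen so the whole suite documents itself in about a minute
while still exercising every code path at realistic shapes.

# Known limitations

- Dispersal is purely distance-limited: no demographic dynamics, no
  Allee effects, no human-mediated jumps, no barrier layers beyond the
  elevation bound.
- The four dispersal directions are grid-aligned; an optional per-event
  random rotation is not implemented (the hull of four cardinal
  endpoints is already nearly isotropic at the cell scale).
- Only regular geographic grids are supported — no general CRS engine;
  equal-area accounting is analytic rather than via reprojection.
- The evaluation metrics treat background cells as absences; with highly
  incomplete sampling they understate true performance, as in any
  presence-background design.
- Immediate extirpation makes limited runs sensitive to single extreme
  anomaly years; a persistence buffer would be a one-line change in
  `stepDispersal()` but is deliberately not the default (see above).
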
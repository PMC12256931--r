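---
title: "Methods: circuit-theory connectivity among salmon streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit-theory connectivity among salmon streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearcircuit)
```

## The problem this package models

Coastal grizzly and black bears feed on Pacific salmon at spawning
aggregations that pulse at different places and times through the season — a
resource wave. Whether a bear can exploit several pulses depends on the
functional connectivity of the landscape between spawning reaches: rugged
terrain, dense regenerating forest, snowfields, and open-water crossings all
resist movement. `bearcircuit` implements the full modelling chain used to
map that connectivity and to test the movement-cost assumptions against
independent mark–recapture data:

1. an expert-parameterized **cumulative resistance surface** built from
   terrain ruggedness, landcover, and distance-to-shore water classes;
2. a **circuit-theory model** of movement: the raster becomes a resistor
   network, each pair of focal nodes (salmon-reach midpoints or hair-snag
   sites) is connected to a unit current source, and the resulting current
   density maps all possible routes, with pinch points appearing as
   concentrated current;
3. **least-cost corridors**: the cumulative current map is converted to a
   cost surface, one least-cost path is traced per node pair
   (from-everywhere-to-everywhere), the top 5% by accumulated cost are
   ranked, and 1200 m-wide buffered corridors are reported along with their
   overlap with protected areas;
4. **validation**: transits inferred from genetically identified hair
   samples (an individual detected at two sites within one sampling season)
   are regressed on pairwise effective conductance and Euclidean distance
   with Firth's penalized-likelihood logistic regression.

Because the genetic sampling locations of the real system cannot be shared,
the package ships a synthetic-landscape generator that emulates every input
at configurable scale, which is also what makes the whole chain testable.

## Resistance model

Each habitat layer maps to integer resistance 1 (very low) to 6 (very
high):

* **Terrain ruggedness (TRI)**, the Riley neighbourhood form
  $\mathrm{TRI}(c) = \sqrt{\sum_{n \in N_8(c)} (z_n - z_c)^2}$, classed at
  1–25, 25–50, 50–88, 88–139, 139–230, 230–271 → 1…6. The bins follow
  Jenks natural breaks on the source terrain; `jenks_breaks()` provides the
  Fisher–Jenks optimal classifier for re-derivation, but the pipeline
  classifies with these fixed published breaks for reproducibility. Both
  extremes are open-ended: the printed 271 is a dataset maximum, not a law,
  so larger values stay in class 6.
* **Landcover**: mature forest (unharvested, harvested > 75 years ago, or
  projected age over 75), bryoids/shrubland/herbs, and barren rock are
  effectively permeable (1); regenerating forest 10–75 years after harvest
  is the hyper-dense stem-exclusion stage and takes 3; snow and ice take 6.
  Stands younger than 10 years are absent from the published table; we
  treat them as open early-seral ground (resistance 1, configurable),
  consistent with the shrubland class. Water is nodata on this layer.
* **Water**, by Euclidean distance to shore: < 1 km → 3, 1–3 km → 5,
  > 3 km → 6, reflecting that bears swim short crossings readily and are
  increasingly deflected by wide ones. The distance transform is exact
  (Felzenszwalb–Huttenlocher), equivalent to infinitesimal ring buffers.
  Bins are uniformly left-closed/right-open, so exactly 3 km falls in the
  outer band; the published wording does not resolve this boundary.

The three layers are summed equally on each cell's domain (land: TRI +
landcover; sea: TRI + water) and the raw sum is affinely rescaled to the
published 1–10 cumulative scale. A plain sum of 1–6 layers cannot start at
1, so the rescale is our reading of the published range; a constant raw
field maps to 1. The surface is resampled at 150 m and can be clipped to a
study polygon with a 10 km buffer to absorb circuit edge effects.

## Circuit model

Valid cells connect to their eight neighbours; the resistor between cells
$i, j$ is $(r_i + r_j)/2$, times $\sqrt{2}$ on diagonals (the longer hop).
For a node pair we solve the conductance-Laplacian system $L v = b$ with
$+1$ A injected at the source, $-1$ A at the target, and one node of the
component grounded. Branch current is conductance times potential drop;
the per-cell current density is half the sum of absolute incident branch
currents with source and target pinned at the injection — the conventional
current-density map. Effective resistance is $\hat R = v_s - v_t$ and
effective conductance $\hat G = 1/\hat R$; disconnection is data, not
failure ($\hat R = \infty$, $\hat G = 0$): islands are real in this
seascape. Pairwise mode factors each component's reduced Laplacian once
(sparse Cholesky) and reuses the factor across all pairs; every landscape
shipped with the package is far below the ~10^5-cell scale where an
iterative solver would be preferable. Correctness is anchored to
independent oracles in the test suite: the dense pseudo-inverse identity
$\hat R_{st} = L^+_{ss} + L^+_{tt} - 2L^+_{st}$, series/parallel laws,
Kirchhoff conservation, reciprocity, and Rayleigh monotonicity.

## Corridors

Cell conductance for path-finding is cumulative current plus a floor of
$10^{-6} \times \max(I)$ so zero-current cells stay traversable at high
cost; the step cost is distance divided by the mean conductance of the two
cells. One undirected Dijkstra path per pair (costs are symmetric), the top
`ceiling(0.05 n)` by accumulated cost are kept — the ceiling convention
reproduces 453 from 9045 — and buffered discs of radius 600 m swept along
each path dissolve into 1200 m-wide corridors. We read the published
"1200 m buffers" as total corridor width (the corresponding figure caption
says "1200 m-wide corridors"); the width is configurable. Corridor area is
measured on a fine rasterized union (default cell = width/40), so areas are
approximations with error that shrinks linearly in the analysis cell;
path-length overlap with protected polygons is exact (segment clipping
against polygon edges).

## Validation model

Transit edges: for each individual and season (one sampling season per
calendar year), every unordered pair among its detected sites counts as
transited; the table always covers all $n(n-1)/2$ site pairs. The model
`transited ~ z(conductance) + z(distance)` is fit by Firth's
penalized-likelihood logistic regression, which maximizes
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det(X^\top W X)$ via Newton
steps on the modified score
$U^*_r = \sum_i (y_i - \pi_i + h_i(\tfrac12 - \pi_i)) x_{ir}$,
with step-halving on $\ell^*$; convergence at $\max|U^*| < 10^{-8}$ or step
$< 10^{-10}$, at most 100 iterations. The penalty keeps estimates finite
under the complete separation that rare transit data invite, and on a
saturated 2×2 design reduces exactly to the Haldane half-count correction.
Predictors are z-standardized before fitting, so odds ratios are per SD;
the published odds-ratio scale is unstated, and per-SD values of the
published magnitude are the plausible reading. Confidence intervals are
Wald-type; profile-penalized intervals are a possible extension. Prediction
curves hold distance at 5170 m, the radius of an 84 km² circular home
range (`home_range_radius_m(84)`).

## Synthetic landscape: what it emulates, and what it does not

* **Terrain**: spectral-synthesis fractal fields (power-law spectrum,
  exponent 2.2) scaled to `ruggedness_scale` metres of relief; default
  900 m — coastal-range relief at the 150 m cell scale. The sea is the
  lowest `1 - land_fraction` share of cells, so channels and islands emerge
  from the terrain autocorrelation.
* **Landcover**: snow/ice caps the highest `snowice_fraction` of land
  (default 0.05); regenerating forest forms contiguous patches (thresholded
  smooth noise) at `regen_fraction` (default 0.05, matching the low logged
  share of this coast); remaining land splits into forest, shrub, and
  barren by elevation band — a subalpine-to-alpine sequence.
* **Hydrology**: streams descend steepest-gradient from high sources to the
  coast; reach lengths are truncated log-normal (median 1.7 km, bounds
  19 m and 11.3 km — the observed summary statistics of reach length), laid
  mouth-to-source and labelled with salmon species. A stream may carry
  several species' reaches under one watershed code.
* **Sampling**: snag sites are a jittered lattice thinned evenly on land
  (site spacing and detection rates are not published for the real system;
  the defaults are chosen once as field-plausible). Detections follow the
  half-normal encounter model standard in spatial capture–recapture,
  $p = p_0 \exp(-d^2/2\sigma^2)$ per session, with $p_0 = 0.2$, two
  sessions per season, five seasons, and home-range centres uniform over
  the padded site bounding box (padding capped at the box span so the
  large-$\sigma$ limit detects everyone everywhere). The full-scale default
  $\sigma$ is 5170 m; the pipeline's desk-scale default uses extent/8 so
  home ranges still cover a few neighbouring sites.
* **Transits**: Bernoulli outcomes with log-odds linear in standardized
  conductance and distance. Default slopes are the published per-SD odds
  ratios (log 1.66 and log 0.36). The default intercept −3.66 is the logit
  of the observed 54/2145 transit fraction; with nonzero slopes the
  *marginal* rate exceeds `plogis(beta0)` (Jensen), so
  `calibrate_intercept()` solves for the intercept that makes the marginal
  rate hit a target exactly — the parameter-recovery checks use it.

Not emulated: within-season spawn phenology (the resource-wave timing
itself), realistic hydrological routing, tides, species- or sex-specific
movement, and behavioural route choice. Passing tests therefore certify the
*computational chain* — classification, solvers, estimators — and the
statistical recovery of known simulation parameters, not the ecological
fidelity of any particular resistance parameterization to real bears.

## Numerical choices and degenerate inputs

* One master seed fans out to per-stage sub-seeds by fixed offsets; every
  generator is bit-reproducible per seed and restores the caller's RNG.
* Sparse solves are direct Cholesky with a fixed per-component ground node;
  oracle agreement is required to 1e-8 relative in the suite.
* Dijkstra ties follow the deterministic edge insertion order of the graph
  build (row-major cells), so reruns are identical.
* Node merging uses single-linkage components of the "within 150 m"
  relation (the published phrase is ambiguous for chains) with unweighted
  mean centres, iterated to a fixed point so merging is idempotent.
* Snapping moves a node on nodata to the nearest valid cell within 2 cells
  and collapses nodes sharing a cell (ids retained) — co-located sources
  are indistinguishable to the circuit.
* Degenerate cases are defined, not crashed: flat terrain gives TRI 0 and
  an all-land mask; a constant raw resistance field rescales to 1; an
  all-zero current map, an all-water mask, all-0/all-1 outcomes, and
  zero-variance predictors raise informative errors.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at desk scale, chosen as the
package's own reference configuration: 40×40 to 80×80-cell landscapes
(6–12 km at 150 m), 10–15 focal nodes for full circuit/corridor runs, the
full 66-site / 2145-pair design for the validation statistics, 50–60
random graphs (10–200 nodes) for solver oracles, and 100–200 Monte-Carlo
replicates for odds-ratio recovery and coverage. The published full-scale
surface (hundreds of thousands of cells, 134 nodes) is the same computation
at larger n.
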
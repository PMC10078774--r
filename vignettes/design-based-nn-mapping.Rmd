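---
title: "Design-based nearest-neighbor mapping: models, bounds and the bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based nearest-neighbor mapping: models, bounds and the bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnmap)
```

## The inferential setting

`nnmap` treats spatial mapping as a *design-based* problem: the population
is a fixed, non-random object — a bounded scalar field $f$ on a study region
$B$ with values in $[0, L]$ — and all uncertainty comes from the
probabilistic scheme that selects where it is observed. No stochastic model
is placed on $f$. Three population types share one formalism:

* **continuous** — $f$ is a density over the region and any location can be
  observed;
* **areas** — the region is partitioned into $N$ quadrats, $f$ is the
  piecewise-constant per-area density $y_j / \lambda(a_j)$, and sampled
  areas are identified by their centroids;
* **units** — $B$ is a finite set of $N$ point locations with values
  $y_j = f(p_j)$.

Given sampled locations $P_1, \dots, P_n$ with observations $f(P_i)$, the
nearest-neighbor (NN) interpolator at a query $p$ is the observation at the
nearest sampled location, averaged over the set $H_p$ of sampled locations
tied at the minimum distance:

$$\hat f(p) \;=\; I(Q_p)\, f(p) \;+\;
  \frac{I(Q_p^c)}{\mathrm{Card}(H_p)} \sum_{i \in H_p} f(P_i),$$

where $Q_p$ is the event that some $P_i$ coincides with $p$. The map is
piecewise constant on the Voronoi cells of the sample, exact at sampled
support, and — because it is a convex combination of observations — never
leaves the observed range. It is also the $\alpha \to \infty$ limit of the
inverse-distance-weighting interpolator with weights $d^{-\alpha}$, which
`idw_interpolate()` implements as an independent cross-check.

## Error decomposition and miss probabilities

The design expectation of the absolute error at $p$ obeys, for every ball
radius $\delta > 0$,

$$\mathbb E\,|\hat f(p) - f(p)| \;\le\; \Delta(p, \delta)
  + L \,\Pr\{A(p, \delta)\},$$

where $\Delta(p, \delta)$ is the largest jump of $f$ within the closed
$\delta$-ball of $p$ (`oscillation()`) and $A(p, \delta)$ is the *miss
event* that no sampled location falls in that ball. The first term measures
the roughness of the population, the second the spatial balance of the
design. `nnmap` computes the miss probability

* in closed form under uniform random sampling (URS),
  $(1 - \lambda(\text{ball} \cap B)/\lambda(B))^n$, with the clipped ball
  area from the exact circle–rectangle closed form (`circle_rect_area()`,
  validated against quadrature in the tests);
* in closed form under tessellation stratified sampling (TSS) as a product
  over cells, which hits *exactly* zero once the ball covers one cell —
  for any $p$ this happens at radius $\sqrt 2 \cdot s$ with $s$ the cell
  side, the spatial-balance certificate behind uniform consistency;
* by Monte Carlo for any other scheme (`miss_prob_mc()`), using the strict
  inequality $\lVert P_i - p\rVert > \delta$ for the miss event, so
  $\delta = 0$ misses almost surely under continuous designs.

When only per-location hit probabilities $q_i$ and pairwise joint hit
probabilities are available, `miss_count_bound()` bounds the miss
probability through the count of locations in the ball; under independent
equal selections it reduces to $1/(nq)$.

For fields Lipschitz at $p$ with constant $\beta$, choosing
$\delta = t n^{-1/2}$ gives
$\beta t n^{-1/2} + L \Pr\{A(p, t n^{-1/2})\}$
(`lipschitz_error_bound()`); under TSS with $t = \sqrt 2$ the miss term
vanishes and the error decays at the $n^{-1/2}$ rate, a property the test
suite verifies empirically by regressing log Monte-Carlo RMSE on
$\log n$. Map-level accuracy is summarized by the mean integrated absolute
error $\int_B \mathbb E |\hat f - f|\, d\lambda$ (`miae_mc()`), which keeps
improving even for fields with jumps because discontinuity sets of measure
zero only contaminate a vanishing fraction of the integral.

## Sampling designs

`scheme_spec()` describes the designs common in environmental and forest
surveys; one descriptor serves both the original selection and bootstrap
resampling:

| scheme | setting | selection |
|---|---|---|
| URS | continuous | $n$ i.i.d. uniform locations |
| TSS | continuous | one uniform location per cell of a $k \times k$ tessellation |
| SGS | continuous | one uniform offset replicated across all cells |
| SRSWOR | areas/units | $n$ draws without replacement |
| OPSS | areas | one quadrat per block of contiguous quadrats |
| SYS | areas | one within-block position replicated across blocks |
| 3P | units | Bernoulli inclusion with $\pi_j = x_j / L^\*$ |

Design choices that the formal descriptions leave open are fixed as
follows. SGS and SYS use a single shared offset (aligned systematic
selection), the standard reading of "systematic" one-per-stratum selection.
Blocks are $2 \times 5$ in grid rows $\times$ columns by default; both
orientations tile every grid used in the study, so the choice is arbitrary
but fixed. An empty 3P realization (possible, with tiny probability, since
Poisson sampling has random size) would leave the interpolator undefined,
so it is redrawn with a warning. Finite-population distances are computed
between area centroids.

Under 3P sampling the prediction $x_j$ of every unit is known frame-wide,
so mapping goes through the *residuals*: interpolate the observed
prediction errors $e_j = y_j - x_j$ and reconstruct
$\hat y_j = x_j + \hat e_j$ (`residual_interpolate()`). Jumps of the survey
variable that the predictions track cancel in the errors, which is why the
residual map handles discontinuous populations markedly better than direct
interpolation.

## The pseudopopulation bootstrap

To attach an RMSE to the map without a superpopulation model,
`bootstrap_rmse()` treats the estimated map as a complete surrogate
population, redraws $M$ samples from it *with the identical design*, and
estimates

$$\widehat{\mathrm{rmse}}^*_M(p) = \Big[\tfrac 1 M \sum_{m=1}^M
  \{\hat f^*_m(p) - \hat f(p)\}^2\Big]^{1/2}.$$

Two implementation details matter. First, the scheme object is reused
byte-for-byte — same tessellation, same blocks, same $\pi_j$ — never
re-estimated. Second, in the continuous setting the bootstrap observations
are read from the *exact* Voronoi field of the original sample
(nearest-original-point lookup), not from the display grid, avoiding a
double discretization. For the 3P residual workflow
(`threep_bootstrap_rmse()`) the pseudopopulation carries $\hat y_j$, each
replicate redraws a 3P sample with the original frame-level $\pi_j$, and
bootstrap maps are rebuilt as $x_j + \hat e^*_j$.

At points where the field is differentiable with nonzero gradient and the
design guarantees a sampled location within a fixed radius (TSS, SGS and
their finite-population analogues), the expected bootstrap RMSE is at most
three times the true RMSE for $M$ large enough — the estimator is
conservative, not arbitrarily inflated. `conservativeness_mc()` verifies
this by an outer Monte-Carlo loop; at desk scale the observed ratio on the
smooth canonical surface under TSS ($k = 4$) is about $1.5$, comfortably
inside the bound, and the simulation harness reproduces the qualitative
pattern that per-point ratios average above one (mild conservatism) with
occasional local underestimation. No printed threshold exists for "$M$
large enough"; the package defaults to $M = 1000$ and the test suite
includes a stabilization check comparing independent $M$-sample estimates.

## Synthetic populations: what they emulate and what they do not

Three canonical surfaces on the unit square, all rescaled to a maximum of
$L = 10$, emulate the population types met in practice: a smooth monotone
trend (surface 1), a smooth oscillation (surface 2), and a field with a
jump along the internal edges of the upper-right quadrant (surface 3),
standing in for abrupt land-cover transitions. The scaling constants are
not hard-coded: `derive_constants()` grid-searches each unnormalized
surface and refines the maximum by box-constrained local optimization, so
a corrected surface definition would propagate automatically. The printed
definitions of the surfaces are partially ambiguous in their source; the
adopted readings are the unique ones consistent with non-negativity, the
visible text and a maximum of exactly $10$, and each lives in a single
isolated function.

Area populations integrate a surface over $g \times g$ quadrats with a
midpoint rule on an $m \times m$ sub-grid ($m = 20$ by default): exact for
per-quadrat-constant fields, $O(m^{-2})$ otherwise, and safe across the
jumps of surface 3, which lie along quadrat edges for the grid sizes used.
Unit populations follow four point patterns (regular by sequential
thinning at the per-level radius $0.5\,N^{-1/2}$ with a 10 000-rejection
cap; uniform; trended via $(1-u_1^2,\, 1-u_2^2)$; clustered as 10 uniform
cluster centers with circular Gaussian scatter of per-coordinate variance
$0.025$, out-of-region points redrawn), nested by prefix so that growing
the population never relocates existing units. The thinning radius of the
regular pattern is checked against *all* previously accepted points, and
"variance 0.025" is interpreted per coordinate.

These generators reproduce the geometry and value distributions of the
reference simulation design, not real survey data: there is no measurement
error, no positional error, regions are rectangles, and values derive
deterministically from location. Passing tests therefore certify the
estimators' design-based properties under controlled conditions; they say
nothing about model misspecification, which design-based inference
sidesteps by construction, nor about irregular region geometry.

## Numerical choices

* **Tie tolerance.** Coincidence with a sampled location and membership in
  $H_p$ both use an absolute distance tolerance of $10^{-9}$ region units.
  Exact ties only arise on lattices (area centroids, regular unit grids),
  where symmetric distances are bit-identical in floating point; the
  tolerance merely guards quantization noise. Both branches reduce to one
  tie-averaging code path, which honors the indicator form exactly.
* **Search structure.** Nearest neighbors are found with vectorized
  distance matrices, chunked to bound memory; results are validated against
  a brute-force double loop on random instances, so any accelerated index
  would be a drop-in internal change.
* **IDW at large $\alpha$.** Weights are computed on distance *ratios* to
  the per-query minimum, so $\alpha = 200$ neither overflows nor
  underflows the nearest weight.
* **Continuous evaluation.** Maps are evaluated on a regular grid
  (100 × 100 at reference scale) rather than through explicit Voronoi
  polygonization: every downstream functional (MIAE, bootstrap, summary
  tables) is a grid functional. The bootstrap never reads from this grid
  (see above).
* **Oscillation.** The supremum over the $\delta$-ball is approximated on
  a bounding-box grid restricted to the ball, doubling resolution until
  the change is below $10^{-4}$.
* **Per-replication seeding.** Every Monte-Carlo replication seeds R's RNG
  from (master seed, configuration tag, replication index), so single
  replications are reproducible in isolation and configurations are
  order-independent.
* **Undefined ratios.** At support points whose Monte-Carlo RMSE is zero
  (constant fields) the bootstrap ratio is undefined; it is reported as
  `NA` and excluded from summaries with an explicit count, never imputed.

## Monte-Carlo harness and problem sizes

`run_replications()` replicates sampling, mapping and (optionally) the
bootstrap, accumulating per-support-point absolute bias $|$mean error$|$,
RMSE and the ratio of mean bootstrap RMSE to Monte-Carlo RMSE, with
min/avg/max summaries. Absolute bias is $|\mathbb E(\hat f - f)|$ rather
than $\mathbb E|\hat f - f|$, the standard reading, which makes
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{variance}$ an exact
accounting identity that the tests verify to round-off. The ratio
denominator is the same-run Monte-Carlo RMSE, introducing $O(R^{-1/2})$
noise that the reported standard errors quantify.

`full_study()` runs the full population × scheme × size factorial in two
presets. The `"paper"` preset (R = 10 000 replications, M = 1000 bootstrap
samples, all ladder sizes, 100 × 100 evaluation grid) is the cluster-scale
reference design and warns about its cost. The `"desk"` preset — R = 500,
M = 100, the two smallest sizes of each ladder, and a 25 × 25 continuous
evaluation grid — keeps each configuration within minutes on one core
while preserving every qualitative contrast (error decay along the size
ladders, slower maxima decay for the discontinuous surface, ratio above
one); the reduced evaluation grid is the package's own choice for this
preset, trading spatial resolution of the summary maps for tractability.
The test suite and the acceptance script scale further down in the same
proportions.

## Known limitations

* Regions are axis-aligned rectangles; no polygons with holes, no
  projections (the theory is metric-planar, so user data in any planar
  CRS work unchanged).
* No kriging or other model-based interpolators, and no interpolation in
  auxiliary-covariate space; the package is deliberately confined to the
  design-based NN toolchain.
* Bootstrap output is an RMSE surface, not confidence intervals.
* The conservativeness factor of 3 is an upper bound under regularity
  conditions (differentiability with nonzero gradient, guaranteed-coverage
  designs); near discontinuities or under purely systematic schemes the
  ratio can exceed it locally, and the harness reports exactly where.
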
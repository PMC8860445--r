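---
title: "Entropic cell packing: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic cell packing: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(entropack)
```

## The model

A multicellular group of `N` cells divides its total volume `V` into `N`
cell neighborhoods — the Voronoi regions of the cell centers. Treating the
partition as random subject to two constraints, `sum(v_i) = V` and
`v_i >= v_c` (a neighborhood cannot be smaller than the cell body that
anchors it), the distribution realized by the largest number of
microscopic configurations is the shifted gamma ("k-gamma") distribution

$$p(v) = \frac{k^k}{\Gamma(k)}\,
  \frac{(v - v_c)^{k-1}}{(\bar v - v_c)^k}\,
  \exp\!\left(-k\,\frac{v - v_c}{\bar v - v_c}\right),
  \qquad k = \frac{(\bar v - v_c)^2}{\sigma_v^2}.$$

The same argument applies unchanged to areas or solid angles on a closed
surface. Two things make the prediction falsifiable with no fitting
freedom: the shape parameter `k` is fixed entirely by the first two
moments of the measured sizes plus the minimum size, and goodness of fit
is summarized by one number, the root-mean-square P-P residual

$$r_\mathrm{RMS} = \sqrt{\langle (F_i - F(v_{(i)}))^2\rangle},$$

the RMS distance between the empirical CDF at the order statistics and the
model CDF. `estimate_kgamma()` implements the moment matching (population
`1/n` variance; at the sample sizes involved the `1/(n-1)` distinction is
negligible), `pp_rrms()` the diagnostic. The key assumption is the
*absence of spatial correlations* in the partition: neighboring cells must
not share systematic size information beyond the global constraints.
`correlation_function()` (network-distance correlation `C(Q)`),
`extract_subregions()` and `psi6()` quantify exactly the correlations that
break the prediction.

### Conventions that matter

- **Empirical CDF plotting position.** Hazen, `(i - 0.5)/n`. It is
  symmetric, avoids the 0 and 1 endpoints, and for the `n` above a few
  hundred used everywhere here the alternatives (`i/n`, `i/(n+1)`) move
  `r_RMS` by less than the Monte-Carlo scatter. Exposed as an argument of
  `pp_rrms()`.
- **Minimum size `v_c`.** For simulated volumetric groups, the defined
  cell volume (`4/3 pi a b^2` for prolate cells, `4/3 pi r^3` for
  spheres); for bidisperse groups, the smaller cell volume; for
  sphere-surface ensembles, a fixed minimum solid angle of 0.0070 sr (the
  value obtained by minimum-size fitting on real volvocine data, reused
  across surface ensembles); for whole-group volumes at fixed `N`, the
  packing bound `N v_c`. When no defensible minimum exists a priori,
  `fit_min_size()` chooses `v_c` by minimizing the summed squared P-P
  residuals, after removing detached low outliers (a point is an outlier
  when its gap to the next order statistic exceeds twice the span of the
  following thirty — a k-gamma lower tail never does this, a detached
  point always does). Minimum-size fitting is well conditioned only for
  broad distributions (`k` of a few); for steep shapes the density
  vanishes too fast at `v_c` for point identification, and tests treat it
  accordingly.

## The growth simulators

The simulators double as the package's synthetic-data source. Their
defaults are the study conditions; every ensemble statistic quoted in the
tests is computed at these settings.

**Tree-like budding** (`grow_snowflake()`). Prolate cells, semi-axes
`a = 2.88`, `b = c = 2.29` um; seven generations; every cell attempts one
bud per generation. First buds appear at the distal pole (polar angle
uniform within 10 degrees) with probability 0.8, otherwise on the budding
ring at 45 degrees; after three bud scars, each bud reflects to the
proximal side with probability 0.5; azimuths are uniform. Daughters sit
with their long axis along the mother-surface normal (the ellipsoid
gradient at the bud site), attached at their proximal pole. Bonds are
rigid: no relaxation, the growth configuration is frozen. A candidate bud
is eliminated when it *closely overlaps* the existing group, under two
complementary criteria: its scar lies within 1.2 um (the bud-scar
diameter) of an existing scar, or its center falls inside an existing
cell's ellipsoid. The scar criterion alone misses collisions between buds
of different mothers, which produces a spurious heavy tail of
sub-cell-volume neighborhoods; the body criterion is parameter-free.
Under both, ensembles average 92 +/- 11 cells per cluster.

**Sphere-surface placement** (`sample_sphere_poisson()`). Uniform random
points on the unit sphere accepted under a hard-core chord separation
(`d = 0.088` for the 1000-cell ensembles; `d = 2 x 0.198` for the 50-cell
apoptosis groups), by rejection. Uniformity is area-true (`cos(theta)`
uniform). `apply_apoptosis()` then removes one random cell plus nine
random cells flagged within a localization radius `R`; configurations
that cannot flag nine cells signal an error rather than silently killing
fewer (at `R = 0.75` on 50-cell groups the death region holds about seven
cells on average, so ensembles at that radius must redraw infeasible
configurations).

**Aggregation** (`grow_aggregate()`, `grow_polydisperse()`). Unit spheres;
one daughter per cell per generation placed in contact at a uniformly
random point on the mother's surface (a budding-ring placement in the
mother's frame is available as `aggregate_placement = "ring"`, but any
fixed-frame ring makes growth directionally persistent and the clusters
ramified). After *every single division* the group relaxes
quasi-statically — the slow-division limit; batch relaxation of a whole
generation of mutually overlapping newborns explodes the cluster outward.
Six generations give exactly 64 cells. The bidisperse variant seeds one
contacting pair with radii 1 and 2 and passes the mother's radius on with
probability `xi`.

**Palintomy** (`grow_palintomy()`). Unit spheres dividing in synchronous
rounds (daughters placed half-overlapping in a random direction — division
in place) inside a spherical membrane. After each round the membrane
radius is reset so the packing fraction `N v_cell / V_membrane` stays at
`phi0`, then the group relaxes under steric plus membrane forces. `phi0`
defaults to 0.50: dense enough that the membrane, not the cluster
surface, shapes the packing, and comfortably below random close packing
(0.64) so relaxation converges; the shape parameter of the resulting
volume distribution rises with `phi0`, so this single choice sets the
ensemble's `k` scale.

**Patterned growth** (`grow_patterned()`). Unit spheres with chitin-like
permanent bonds. Each cell buds three daughters, one per generation, at
prescribed sites (polar, azimuth) = (0, 0), (90, 90), (90, 270) degrees
in its own frame, each angle perturbed by uniform noise of half-width
`eta`; each daughter's frame is the mother's rotated by `Rz(90 + noise)`.
Five generations produce 28 cells. At `eta = 0` three of the prescribed
sites coincide exactly with existing cells; those buds are removed at
creation, leaving 25 distinct cells and a visibly discrete Voronoi
spectrum. Steric plus bond relaxation follows each round.

### Force laws and relaxation

Forces are harmonic throughout: steric repulsion `ks (|r| - (Ri+Rj))`
inside contact; adhesion `ka (|r| - a (Ri+Rj))` on the branch between
contact and twice contact, with well position `a = 0.9` and the overlap
branch identically zero (the printed discontinuity at contact is part of
the model); membrane confinement proportional to the exact sphere-sphere
lens volume of the cell outside the membrane; and mother-daughter bond
springs. Two readings deserve a note:

- **Adhesion acts through bonds.** The adhesive force couples only
  *bonded* pairs: a bond forms when two cells touch and breaks when
  stretched past twice the contact distance. Applying the pairwise force
  to every pair in range makes the attraction cumulative over ~50
  second-shell neighbors and collapses 64-cell groups into a ball a
  couple of cell radii across (mean neighborhood below `v_c`), for any
  adhesion strength within an order of magnitude of the steric constant —
  the opposite of cells "occupying space". The bond reading matches the
  reformable-bond picture the model represents and leaves the two-cell
  equilibrium (separation exactly at the steric/adhesive crossover)
  unchanged.
- **Bond rest length.** Bud and birth scar coincide at the moment of
  budding, so the bond is a zero-rest-length spring between scars —
  equivalently, for spherical cells, a spring holding the centers at the
  contact distance `Ri + Rj`. A literal scar-to-scar spring with rest
  length 2 would push mother and daughter a full diameter apart.

Relaxation integrates overdamped dynamics (`x <- x + F dt`, mobility 1)
with explicit Euler, step 0.01, until the largest per-cell displacement in
a step falls below `1e-4`, capped at `1e5` iterations with non-convergence
flagged, never silent. Because the adhesive law is discontinuous at
contact, a fixed step limit-cycles across the crossover; the integrator
therefore backs off FIRE-style — halving the step when the force field
reverses against the previous step, growing it by 10% per twenty aligned
steps up to ten times the base step. The growth cap makes the
displacement criterion correspond to a ten-fold smaller residual force, so
two-cell equilibria land within `1e-3` of the analytic balance.

## Tessellation

**3D.** Each cell's polyhedron is the intersection of its bisector
half-spaces against all other centers with the boundary polyhedron's
half-spaces, computed by sequential convex clipping (bisectors sorted by
distance, with a pruning bound) from a bounding cube seeded at the group
radius plus 5 um of padding. Volumes come from fan decomposition;
adjacency from which bisector planes survive with positive face area. The
convex hull, clipping and relaxation kernels live in `src/geometry.cpp`;
volume conservation (`sum(v_i)` equals the boundary volume to 0.1%) and a
Monte-Carlo nearest-center oracle are enforced in the tests.

**Boundary.** The boundary is the convex hull of the cell centers with
every hull vertex displaced radially outward from the center of mass — by
3 um for the yeast-scale morphology and by 1.5 cell radii for unit-cell
morphologies (the same ratio of extension to transverse cell radius;
vertex-only extension moves mid-face boundary planes outward by less than
the vertex displacement, so one radius alone does not contain every
boundary cell). Membrane-confined groups are instead clipped to their
membrane sphere, represented as the circumscribed polyhedron of tangent
planes at 400 Fibonacci-lattice directions (volume within 1% of the
sphere): the membrane is the physical total-volume constraint, and a
hull-of-centers boundary makes the shape parameter swing by factors of
three with the extension choice because nearly every cell of a confined
ball touches the boundary. For whole-group *total* volumes
(`total_volume_ensemble()`), the group volume is the bare hull of the
centers — the minimal hull, with no tessellation padding.

**Surfaces.** Positions on a closed, star-shaped surface are normalized
to the unit sphere; the spherical Delaunay triangulation is the convex
hull of the normalized points, mapped back to the original positions.
Voronoi vertices are the circumcenters of the mapped triangles; each
cell's polygon is ordered in its tangent frame and flattened to its
best-fit plane before the area is computed (at 1000 cells per sphere the
flattening error is far below a percent of area). Gap exclusion flags
Delaunay triangles with circumradius over twice the inradius above 4
(an exposed default; surfaces with real gaps and random slivers both
produce flags) and masks every polygon touching a flagged triangle.
Masked cells keep `NA` sizes; survivors keep their full-surface solid
angles by default, so the surviving sum falls short of `4 pi` by exactly
the masked share (renormalization is available as an option).

## Spatial statistics

`C(Q)` correlates a cell's size deviation with the mean deviation of its
shell at network distance `Q` (breadth-first shells on the Delaunay
graph), normalized by the two population standard deviations. Under a
permutation null its standard deviation is 1.3-1.6 times `1/sqrt(n)` —
shell memberships overlap between nodes — which the tests account for by
averaging over shuffles. Subregion extraction takes every unmasked node
as a candidate center, keeps the ball of network radius `Q0`, and
optionally retains only subregions whose mean size lies in a target
window; overlapping subregions are pooled with multiplicity. The hexatic
order parameter averages `exp(6 i theta_j)` over each cell's neighbors
and then over cells, taking the modulus last (taking it per cell first
cannot distinguish a disordered surface from a crystal). The tangent
plane comes from the principal components of the neighbor cloud, but the
in-plane basis is the projection of a fixed global axis: the two leading
principal directions of a six-fold-symmetric neighborhood are degenerate,
and using them directly randomizes the phase per cell.

## Weakest-link fracture and motility

If a group fractures as soon as any one cell is confined below a critical
neighborhood volume `v*`, the per-cell confinement probability is the
k-gamma lower tail `p* = F(v*)` (closed form via the regularized
incomplete gamma; the quadrature cross-check is a test), and group
survival is geometric, `P(N) = (1 - p*)^N`. `predict_size_distribution()`
holds the slope `log(1 - p*)` fixed by the packing model and fits only an
amplitude to observed log counts, reporting `r^2`; `v*` is an input with
default `2.02 v_c`. The fixed-`N` ensemble (`total_volume_ensemble()`)
grows budding clusters to exactly 100 cells (randomized within-generation
budding order, saturated growth redrawn from a fresh child seed) and
shows that whole-group volumes are themselves k-gamma distributed with a
coefficient of variation several-fold below the single-cell one.

For surface-actuated spherical swimmers, tangential actuation expanded in
the Legendre-derivative basis `V_n` gives a swimming speed set by the
lowest mode alone: `U = (2/3) u_1` for a slip-velocity (squirmer)
description — the package computes both the closed form and the full-sum
quadrature, which agree to `1e-8` — and `U = 2 eps R f_1 / (3 mu)` for a
shear-stress/no-slip description. Any heterogeneity confined to modes
`n >= 2`, such as cell-area disorder, changes the speed by exactly zero.
Interior flow fields of the shear-stress model are not reconstructed;
only the speed relation is implemented.

## Reproducibility, problem sizes, and limits

Every stochastic routine takes a seed; ensembles derive per-replicate
seeds through `child_seed()`, a fixed affine counter modulo a prime below
2^31, so replicates are independent of evaluation order. Identical
configuration and seed give byte-identical cell tables.

The package's standard ensemble sizes — 1000 budding clusters, 10 spheres
of 1000 cells, 50 aggregates, 200 palintomic groups, 500 fixed-N
clusters, 150 patterned groups per noise level — were chosen so the
pooled `k` estimates have Monte-Carlo scatter of a few percent, well
below the spread the protocols themselves leave (`scripts/acceptance.R`
runs them all in about ten minutes on one CPU; the test suite uses the
same or smaller sizes).

What passing these tests does and does not show: the simulators emulate
the geometry of growth — budding angles, scar exclusion, contact
mechanics, confinement — but not cell-cycle timing, growth asynchrony,
nutrient fields, hydrodynamics, or flocculation, and real image-derived
cell centers carry segmentation noise that the simulators do not model.
Agreement between a simulated ensemble and the k-gamma law is therefore
evidence about the *class* of growth rules, not a validation of any one
organism's mechanics. Two protocol-level ambiguities deserve honesty:
aggregation mechanics (adhesion strength, placement rule, relaxation
cadence) move the pooled aggregate `k` over roughly 1-6 across readings
that all satisfy the written description, and the palintomy `k` is
sensitive to the packing fraction, which is a modelling choice here.
Within one fixed, documented reading — the one this package implements —
all ensemble statistics are stable and reproducible.
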
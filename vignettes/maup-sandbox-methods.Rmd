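---
title: "Methods: simulated zonal aggregation for MAUP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated zonal aggregation for MAUP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maupsim)
```

## The problem

Any analysis that consumes areal (polygon-aggregated) population data is
sensitive to the size and configuration of the areal units — the
modifiable areal unit problem (MAUP). A single census geography is one
arbitrary realisation of the zonal partition; to study how scale and
zonation propagate into models (disaggregation, small-area estimation,
regression), one needs *many* realisations of the same population at
many resolutions. `maupsim` produces exactly that: a seeded simulator
that coarsens a census-like tessellation down a schedule of unit
counts, many independent trajectories at a time, while deliberately
preserving the population-density distribution; plus the statistics to
evaluate the results and a mass-preserving disaggregation harness to
exercise them.

## The aggregation procedure

Given a tessellation of $n$ units with areas $a_i$ (km²) and counts
$p_i$, one iteration does:

1. **Quasi-random selection.** Unit $i$ is selected with probability
   proportional to $w_i = 1/(1 + z_i^{\rho})$ where
   $z_i = (a_i - \min a)/(\max a - \min a)$ is the min–max normalised
   area. The curve decreases from 1 at the smallest unit to $1/2$ at
   the largest, so small (typically urban) units are preferred but
   large rural units are still selected occasionally. $\rho$ controls
   the shoulder of the curve; the default $\rho = 4$ keeps the
   selection nearly flat over the bulk of small units. With all areas
   equal the weights degrade to uniform.
2. **Density-similar partner.** The selected unit is dissolved into
   the rook-contiguous neighbour (shared boundary of positive length)
   whose population density is closest in absolute difference. Ties
   break to the lowest uid, so a trajectory is a deterministic
   function of its seed.
3. **Dissolve.** The pair's geometry is unioned, counts are summed,
   the combined unit keeps the partner's uid, and area and density
   are recomputed. Selection weights are recomputed from the *current*
   areas at the next iteration.

This repeats until the level's target count is reached. A *schedule*
(default: 95%, 90%, …, 10% of the base count, targets rounded
half-up) chains levels: each level continues from the previous level's
output under one continuous RNG stream per seed, so a seed's coarse
levels are refinements of its fine levels, not restarts. Every merge
is logged as (seed, iteration, target, merged uid, absorbing uid);
replaying the log on the base tessellation reproduces every level's
membership partition exactly, with no access to the RNG.

The partner criterion is pluggable: `"density-similarity"` is the
procedure above; `"random-neighbour"` is an ablation that picks a
neighbour uniformly at random, used to demonstrate what the
density-similarity rule buys. The phrase "most similar average
population density" admits a second reading — choose the pair whose
merge least reduces the variance of the density distribution — which
is not implemented; pairwise $|\Delta \text{density}|$ is the
operational reading adopted, and the ablation hook is where an
alternative criterion would plug in.

Islands (units with no neighbour) receive selection probability zero;
if targets become unreachable because only islands remain, the run
errors rather than silently violating contiguity. Tessellated inputs
have no islands, but synthetic or user inputs might.

## The synthetic landscape generator

Downstream code is testable without any deposited data because the
generator produces census-like landscapes with the structural features
that drive the simulator's behaviour:

- unit seed points drawn from a mixture of Gaussian **urban cores**
  (fraction 0.7 of units, sd 2 km around each of 3 cores by default)
  over a uniform rural background, Voronoi-tessellated over a 30 km
  square extent — giving many small cells near cores and few large
  rural cells, hence right-skewed, heavy-tailed areas and a strong
  negative rank correlation between area and density (about −0.8 at
  the defaults);
- populations assigned from a smooth core-peaked density surface
  times unit area times multiplicative lognormal noise (sd 0.7 on the
  log scale), then rescaled to a 500,000 total by largest-remainder
  rounding so the total is met exactly;
- a quota (15% by default) of **zero-population units**, taken from
  the largest-area units, mimicking unpopulated open and rural
  parcels; the quota is deterministic per seed rather than i.i.d.
  coin flips so fixtures are stable.

All randomness flows from a single stream keyed by the spec's seed in
a fixed draw order (core centres, mixture components, coordinates,
redraws for out-of-extent or duplicate points, noise), and the
caller's RNG state is restored afterwards; a spec therefore fully
determines a landscape. Defaults were fixed once as a desk-scale
stand-in for a metropolitan census extract. They do **not** attempt to
match any particular city's area quartiles (deliberately out of
scope): the generated area distribution spans roughly three orders of
magnitude, versus about six in extreme mixed-resolution geographies
whose smallest units are individual buildings. No road network, water
mask or temporal dynamics are emulated, so conclusions about those
features of real data are outside what passing tests can show.

## Geometry representation

The package carries its own small planar-geometry kernel (shoelace
areas and centroids, Sutherland–Hodgman half-plane clipping, Voronoi
cells by bisector clipping with an early exit once half the distance
to the next site exceeds the farthest cell vertex, shared-boundary
length by collinear segment overlap, crossing-number containment).
Two representation choices matter to users:

- **Merged units are multipart.** A dissolved unit's geometry is kept
  as the collection of its members' rings (interiors disjoint) rather
  than stitched into one outer ring. Area (sum), rook adjacency
  (summed shared-edge length over member pairs) and point-in-polygon
  (any member) are exact on this representation, and written
  MultiPolygons remain valid GeoJSON; only cartographic rendering of
  interior member edges differs from a stitched union.
- **Gap filling** (morphological tessellation) shrinks each source
  polygon inward (default one tenth of the densification interval),
  densifies its boundary into seed points every 10 m, and groups the
  Voronoi cells of all seed points by source unit. Street corridors
  are absorbed into the nearest unit, counts and uids carry over
  unchanged, and areas/densities are recomputed. The inward offset
  assumes convex or near-convex member rings (true of all
  package-generated geometry); on an input that already partitions
  its extent the operation reproduces the input areas to well within
  the 0.01% sliver tolerance.

Numerical tolerances: boundary/adjacency tolerance 1e-6 m; pairwise
interior overlap tolerance 1e-6 km²; extent coverage sliver tolerance
0.01%; per-unit mass-preservation tolerance 1e-9 relative. Geographic
(longitude/latitude) CRS labels are rejected wherever areas are
computed.

## Evaluation statistics

- **ASR** — average spatial resolution, $\sqrt{\text{mean unit
  area}}$ in km; scale-covariant.
- **Log-scale distribution summaries** — median, mean and 2.5th/97.5th
  percentiles of natural-log area, count and density, pooled across
  all seeds of a level. Zero-count units have no finite log value and
  are excluded from the count and density summaries, with the
  exclusion count reported. Quantiles use the inverse-ECDF definition
  (type 1) so pooling byte-identical seeds is exactly a no-op.
- **Unit-merge frequency** — for each original unit and level, in how
  many seeds the unit was merged with at least one other by that
  level (its uid appears in the seed's cumulative log). Units merged
  in few simulations give any across-seed summary a small effective
  sample; this layer is the metadata for deciding which units to
  trust.
- **NDPI** — per-pixel $(A - B)/(A + B)$ between two population
  rasters, bounded in $[-1, 1]$, with $0/0 \mapsto 0$ by convention
  (both surfaces agree nobody lives there). Antisymmetric by
  construction.
- **Bootstrap intervals** — percentile intervals of the per-cell mean
  (statistic configurable) over resamples, with replacement, of the
  realization axis; 1,000 resamples by default. The per-cell
  effective sample size is returned alongside the surfaces.

## Disaggregation harness

Counts are spread to a reference grid (100 m pixels by default) by
centre containment: each pixel belongs to the unit containing its
centre, ties on shared edges to the lower uid. Within a unit, pixel
values are the unit count times normalised pixel weights (a supplied
weight raster, e.g. from an externally trained regression model, or
uniform shares). Mass preservation is the non-negotiable invariant:
per-unit pixel sums equal the unit count to 1e-9 relative, a unit
with all-zero weights falls back to uniform shares, and a unit too
small to contain any pixel centre places its whole count on the pixel
nearest its centroid — both recorded in the run report, never dropped.
The weight-producing model itself is out of scope by design; the
raster is the interface.

When comparing realisations of an archive, pixels are mapped to
coarsened units through the merge log (a merged unit owns the union of
its members' pixels), so all levels of all seeds share one consistent
pixel assignment.

## What the simulations show, and how strongly

On the default landscape coarsened to 10% of units over 20 seeds
(chain seeds 1–20; the problem sizes throughout — 1,000-unit default
landscapes, 500–2,000-unit conservation sweeps, 400-unit comparison
archives — are the package's chosen desk-scale study conditions):

- population totals are integer-exact and area totals are conserved
  to ~1e-16 relative at every level of every chain;
- the pooled IQR of log density changes by a smaller relative amount
  than the pooled IQR of log area, and by substantially less than
  under the random-neighbour ablation. The two halves of that finding
  are not equally strong: the density-vs-ablation margin is robust
  (the ablation roughly doubles to triples the density-distribution
  disturbance, across every landscape and seed block tried), whereas
  the density-vs-area margin is small and can flip sign for other
  landscape realisations or other 20-seed blocks. Users reproducing
  the comparison should expect the ablation contrast, not a large
  density-vs-area gap;
- the number of zero-count units is non-increasing along every chain
  (a zero can only persist, absorb, or be absorbed) and approaches
  zero at the coarsest levels;
- between-seed disaggregation divergence (mean |NDPI| between two
  seeds' people-per-pixel surfaces) grows by an order of magnitude
  from the finest to the coarsest level, and the largest
  fine-vs-coarse discrepancies concentrate in the largest source
  units.

These are the package's own measurements, recomputed by the test
suite and by `scripts/acceptance.R`; no figure or number above comes
from anywhere else.

## Known limitations

- The geometry kernel targets well-behaved tessellation work:
  convex-clipping operations (intersection areas, offsets) assume
  convex member rings, and no topology repair is attempted beyond
  tolerance-based validation.
- Vector I/O is GeoJSON; raster I/O is ESRI ASCII grid. Both are
  plain-text, GIS-standard formats; binary container formats are not
  written.
- Multipart merged geometries carry interior member edges (see
  above).
- The RNG is R's default Mersenne-Twister via `set.seed()`; runs are
  reproducible across machines for a fixed R version's RNG, but no
  attempt is made to reproduce any external archive's exact merge
  sequences.
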
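---
title: "The landscape integrity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The landscape integrity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lii)
```

This vignette documents the model the package implements, the parameters
that matter, the numerical decisions taken where the method leaves room,
and what the synthetic-landscape tests do and do not demonstrate about real
data.

## The model

The Landscape Integrity Index (LII) is a coarse-filter indicator of
ecological integrity built from three normalized surfaces on a shared 90-m
grid, each running 0 (degraded) to 1 (intact):

1. **Human Influence Index (HII)** — distance-decayed intactness around
   mapped human land uses, composited across layers by cellwise minimum;
2. **species richness** — the count of terrestrial-vertebrate species with
   suitable habitat per 240-m cell, min–max normalized over the analysis
   extent;
3. **inverse vegetation departure** — `(100 − VDEP)/100`, the complement of
   a 0–100 departure-from-reference measure on a 30-m grid.

The three surfaces are averaged with equal weights and smoothed with a
1-km circular moving-window mean. Equal weighting is an explicit modeling
commitment, not an estimate: the index is meant as a transparent general
indicator, and the weights are a user-visible parameter of
`compute_lii()` for sensitivity analysis.

The core assumptions worth stating plainly:

- *proximity is the mechanism*: a layer's ecological effect is a monotone
  function of distance to the nearest mapped feature, saturating at the
  distance of influence D;
- *the worst influence dominates*: at each cell the composite HII is the
  minimum across layers, not a product or sum — influences do not
  accumulate;
- *richness and departure add information not captured by the footprint*,
  so integrity is not merely the absence of humans.

## Parameters

The shipped 16-layer configuration (`default_layer_config()`, stored as
editable YAML in `inst/extdata/hii_layers.yaml`) gives each layer a site
impact score `s` (intactness at distance zero; 0.015 for major highways
and high-density development up to 0.75 for primitive roads), a distance
of influence `D` in meters (200 m for towers and powerlines up to 4,000 m
for the most severe layers), and a decay family. Severe layers decay
logistically (influence stays high near the feature, then relaxes);
mild layers decay linearly. `D` is capped at 4,000 m — the range within
which most reported effects of human development on wildlife occur — and
the loader rejects larger values unless explicitly overridden.

Other tunables, with defaults: moving-window radius 1,000 m (circular;
square available), indicator weights (1/3, 1/3, 1/3), corridor selection
fraction 0.30 of valid non-priority land, expansion threshold LII > 0.70
(the upper-30% integrity cutoff in the landscape this framework was
developed for), resistance floor 1e-6, logistic tail tolerance ε = 0.01.

## Numerical decisions

**Logistic decay form.** Only the curve's endpoints and general shape are
fixed by the published parameterization, so the package commits to:
raw curve `f(d) = 1/(1 + exp(−k(d − D/2)))` with
`k = 2 ln((1−ε)/ε)/D`, so `f(0) = ε` and `f(D) = 1−ε`; then an affine
rescale of `[ε, 1−ε]` onto `[s, 1]`. This is a symmetric S-curve through
`(D/2, (s+1)/2)` that hits the published endpoints exactly; endpoints are
additionally pinned after evaluation so `curve(0) == s` and
`curve(d ≥ D) == 1` hold to the last bit, not merely to rounding. Values
beyond D are clamped at 1 rather than left asymptotic; whether the original
analysis clamped is not stated, and the clamp is our reading of "intactness
reaches 1.0 at D".

**Distances.** Cell-to-cell Euclidean distance is computed center-to-center
with the exact two-pass separable squared-distance transform (lower
envelope of parabolas), which equals the brute-force all-pairs search
exactly — the tests assert this on random grids. A landscape with no
features in a layer yields infinite distances and hence full intactness,
by design: absence of a land use is information, not an error.

**Order of averaging.** "Average the indicators, then smooth" and "smooth
each indicator, then average" are identical operations when the window
footprints coincide (both are linear); the package averages first so a
single focal pass suffices, and a test asserts the commutation to 1e-12.
With nodata present the two orders can differ (cell-wise missingness makes
the mean nonlinear); the package then defines LII as the smoothed
indicator-average, with nodata propagated conservatively (a cell missing
any indicator is missing in the mix).

**Focal window.** Circular, center-distance ≤ radius inclusive, with a
`(1 + 1e-12)` relative slack on the squared-radius comparison so cells at
exactly the radius are included regardless of floating rounding. Edge cells
average over the window's intersection with the grid (no padding).

**Cost distance.** Movement cost between 8-connected neighbors is the mean
of the two cell resistances times center-to-center distance in pixel units
(1 orthogonal, √2 diagonal), accumulated by Dijkstra's algorithm on the
explicit lattice graph (igraph) from a zero-weight virtual vertex tied to
all source cells. A hand-written array Dijkstra serves as an independent
oracle in the tests.

**Resistance transform.** The index itself cannot be the resistance
surface if corridors are to follow the *highest*-integrity land, so
resistance is `max(1 − LII, floor)`; the literal transform remains
available (`literal = TRUE`) for comparison.

**Corridor selection.** "Highest-value 30% of the land area" is read as
the 30% of valid non-priority cells whose corridor values are closest to
the least-cost optimum (lowest cost-sum). Selection is rank-based —
exactly `round(0.30 · n)` cells — with deterministic row-major tie-breaking
at the quantile boundary, which is why the selected share matches the
request to within one cell for any input. Which priority-area pairs to
link is caller-specified; the default is all pairs.

**Post-hoc comparisons.** Ownership-class differences use one-way ANOVA
followed by Tukey HSD on the studentized range (base R's exact
distribution functions) with a hand-rolled insert-absorb compact letter
display at α = 0.01. An exact studentized-range null was preferred over a
permutation approximation because it is deterministic, assumption-explicit,
and available without additional dependencies.

**Degenerate inputs.** Uniform richness (every cell the same count) carries
no discriminating information; the normalized surface becomes a neutral
constant 0.5 with a warning rather than 0/0. All-identical ANOVA groups
return F = 0 directly. Empty feature collections rasterize to all-zero
presence with a warning. Departure values outside [0, 100] are an error
naming the offending range.

**Grid conventions.** Row 1 is the northernmost row; cells are addressed
(row, col) 1-based; a cell's value represents its center. All model grids
share the HII grid's origin; inputs on other resolutions are resampled
(nearest for categorical, bilinear for continuous) onto it.

## The synthetic landscape

`landscape_spec()` fixes the desk-scale study conditions: a 9 × 9 km extent
(100 × 100 cells at 90 m — small enough that every brute-force oracle in
the test suite stays tractable), 5 disjoint priority areas with GAP status
1–2, a three-class ownership partition, 20 species on the 240-m grid, and
a 30-m departure field.

The generator's defaults emulate a predominantly rural, partially roaded
landscape: sparse infrastructure (2 primitive roads, 1 local road,
1 highway, 1 settlement with attendant development rings, 1 each of tower
/ powerline / mine, ~8% cultivated agriculture, single patches of the
managed-landcover classes), species-suitability fields cut so most land is
suitable for most species, and a left-skewed departure field (most cells
little-departed, with localized heavily-departed patches), both with 3-km
correlation length. These choices give the synthetic index a realistic
shape — a broad mid-range with genuine high-integrity and degraded tails —
so that both planning applications are exercised non-trivially: corridors
must trade off against real integrity gradients, and supra-threshold
expansion components exist adjacent to priority areas.

Each sub-generator draws from its own seed-derived stream, so adding a
generator never perturbs the others, and every output is bit-reproducible
from the single master seed — the test suite asserts byte-identical
rasters and reports across repeated runs, including through the
command-line interface.

What passing tests on this landscape **does** show: every operator obeys
its contract (ranges, monotonicity, exactness against independent
oracles), the stages compose, and the pipeline is deterministic. What it
**does not** show: that the index calibrated here matches any real
region's values. Real road networks have topology (grids, hierarchies),
real suitability models encode ecology rather than smoothed noise, real
departure reflects fire regimes and land-use history, and real landscapes
are orders of magnitude larger. Conclusions about a real study area
require the real inputs.

## Known limitations

- No reprojection: all inputs must share one planar CRS in meters.
- Raster I/O is the single-band ESRI ASCII grid; vector I/O is GeoJSON.
  Both are plain text: convenient and portable, but not compact — very
  large rasters belong in binary formats this package does not write.
- The statistical comparisons treat sampled points as independent; no
  spatial-autocorrelation correction is applied, so p-values at dense
  sampling are optimistic.
- Corridor modeling is least-cost only; circuit-theory (current-flow)
  connectivity and pinch-point analysis are out of scope.
- The minimum-composite HII ignores cumulative effects of co-occurring
  land uses; two overlapping moderate influences score no worse than the
  worse of the two.
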
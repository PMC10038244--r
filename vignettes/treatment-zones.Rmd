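---
title: "Mapping mosquito-control treatment zones: methods and design notes"
author: "treatzones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mosquito-control treatment zones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatzones)
```

## The problem

After hurricane flooding, county health authorities need to decide quickly
where ground or aerial mosquito-control insecticide can be applied, where it
must not be applied (protected and biologically sensitive land), and where
application would be wasted (populated areas without larval habitat).
`treatzones` turns a county's standard vector GIS layers — protected-land
polygons with GAP-status and owner-type attributes, stream and river
centerlines, water bodies, wetlands, address points, and census blocks with
total population — into a classified one-square-mile treatment-zone grid
with three classes:

* **Approved** — treatable cells intersecting wetlands (likely mosquito
  habitat);
* **Warning** — treatable cells within the warning distance of the buffered
  sensitive area, flagged because droplet drift could reach protected land;
* **Not Significant** — cells with structures but no wetland habitat, not
  worth treating.

The analysis is a fixed 18-step overlay protocol:

1. select (and dissolve) the county polygon;
2. filter the natural-heritage layer to protected features
   (`GAP_STATUS` 1 or 2, or a federal owner);
3. buffer stream/river centerlines by 50 ft on each side;
4. merge water bodies, buffered streams and filtered heritage polygons
   (concatenation — no dissolve yet);
5. clip the merged layer to the county;
6. buffer the clipped layer outward by 100 ft and dissolve it into the
   single *sensitive area* feature;
7. clip the wetland layer to the county;
8. build a fishnet of 1 mi&sup2; cells indexed to the address points;
9. erase the sensitive area from the grid;
10–13. classify cells within 100 ft of the sensitive area as Warning and
   invert the selection;
14–16. classify the inverted remainder as Approved where it intersects
   wetlands, else Not Significant;
17. merge the classified pieces into one grid;
18. attach census-block total population to the cells.

`runPipeline()` executes the whole chain; each stage is also exported on its
own (`selectCounty()`, `filterHeritage()`, `bufferHydroLines()`, …) so the
intermediate products can be inspected. `summarizeZones()` reports per-class
areas (mi&sup2; at two decimals, acres = mi&sup2; × 640), cell counts and
populations, and `estimateTreatmentCost()` projects application cost and
product quantity from the vetted (Approved + Warning) acres.

## Coordinate systems and units

Every distance in the protocol is quoted in feet and every area in square
miles, so the working CRS defaults to EPSG:2264 (NC State Plane, US survey
foot). Any *projected* CRS may be configured — distances and areas are
always interpreted in the CRS's linear unit — while a geographic (degree)
working CRS is rejected outright. The package carries its own Lambert
conformal conic (2SP, GRS80) projection engine with a small EPSG registry
(4326, 4269, 2264, 32119); round-tripping a county-sized square through the
geographic CRS preserves area to better than 1e-6 relative.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `hydroHalfWidth` | 50 | ft | stream buffer half-width (step 3) |
| `sensitiveBuffer` | 100 | ft | outward buffer of the merged sensitive layer (step 6) |
| `warningDistance` | 100 | ft | inclusive distance defining Warning (steps 10–13) |
| `cellArea` | 5280&sup2; | ft&sup2; | fishnet cell area (1 mi&sup2;) |
| `keepEmptyCells` | `FALSE` | — | retain address-free cells of the bounding block |
| `apportionment` | `area_weighted` | — | population split mode (step 18) |
| `sliverMinArea` | 1 | ft&sup2; | post-erase slivers below this are dropped |
| `workingCRS` | 2264 | EPSG | projected working CRS |

The defaults are the protocol's published values; they can be overridden per
run through `pipelineConfig()`, a YAML config file, or CLI flags
(`inst/cli/treatzone`).

## Geometry engine and numerical choices

All boolean overlay (union, intersection, difference) and offsetting
(buffers) run on the Clipper engine via the `polyclip` package, with an
absolute snapping tolerance of 1e-10 CRS units — verified stable at State
Plane coordinate magnitudes (~3×10^6 ft) and far below every contract
tolerance in the package. Further choices, made once and applied everywhere:

* **Buffer arcs.** Round joins and caps are approximated with at least 64
  segments per quarter circle (arc tolerance 5e-5 × radius), so analytic
  buffer areas (rectangle-plus-caps for a segment; rounded rectangle for a
  square) are matched to better than 1e-3 relative.
* **Fishnet anchoring.** The grid origin is the address bounding-box
  minimum snapped *down* to a multiple of the cell side from the CRS origin.
  This reproduces grid-index behaviour while making cell boundaries
  independent of feature order; a point exactly on a shared cell edge
  retains both adjacent cells (boundary-inclusive).
* **Warning threshold.** "Within 100 ft" is read inclusively (≤); the tie
  set has measure zero either way. The distance is measured from the
  post-erase cell geometry to the *buffered* sensitive layer, not 200 ft
  from the raw layer — the two differ near concave boundaries, and the
  buffered-layer reading follows the step order of the protocol.
* **Warning precedence.** Wetland classification is applied only to the
  inverted (non-Warning) selection, so a wet cell near the sensitive area is
  Warning, exactly as the step order dictates.
* **Intersects predicate.** Boundary contact counts (DE-9IM "intersects"),
  matching select-by-location semantics: a cell sharing only an edge with a
  wetland is Approved. Implemented as positive overlap area *or* boundary
  distance zero (within 1e-9).
* **Merge vs dissolve.** Step 4's merge is feature concatenation; the
  single-feature dissolve happens in step 6, mirroring the distinction
  between the Merge and Dissolve overlay tools.
* **Slivers and repair.** Post-erase fragments of at most 1 ft&sup2; are
  dropped; every layer passes a validity repair (even-odd resolution of
  self-intersections, e.g. bow-ties become two-lobed multi-polygons of the
  summed lobe area; zero-area geometry is dropped and counted) before
  overlay.
* **Population apportionment.** `area_weighted` (default) assigns each cell
  `block_pop × overlap/block_area`, conserving population over covered
  blocks; `block_copy` mirrors a plain intersect-join (each intersecting
  block's full population, documented over-counting) because the protocol's
  step 18 wording is ambiguous between the two.
* **Reporting precision.** Square miles are reported at two decimals and
  acres derived from the rounded value (× 640); internal computation keeps
  full precision.

## The synthetic-county generator

`generateCounty()` emulates the structure of the real input bundles: a
square county (default side 10 mi) at plausible NC State Plane coordinates,
containing smoothed random-walk river centerlines crossing it, star-shaped
lake and wetland blobs, rectangular protected preserves with GAP/owner
attributes drawn from the protocol's vocabulary (both kept and dropped
values), clustered or uniform address points, and an 8×8 census-block tiling
with log-uniform block populations in [10, 1000] (spanning rural to dense).
Wetland blob radii are scaled iteratively until the union covers the target
county fraction within ±2% (default fraction 0.35 — wetland-rich, as in the
coastal-plain counties the protocol was designed for, where wetland cover is
extensive enough that entire grids classify as Approved or Warning). The
seed fully determines the bundle, and generation restores the caller's RNG
state.

What the generator does *not* emulate: the statistical realism of real
hydrography (stream networks are independent walks, not dendritic networks),
census-block topology (blocks are a regular tiling), coastline/estuary
geometry, and attribute richness of agency data. Passing tests therefore
demonstrate the correctness of the overlay logic under realistic geometric
complexity (concave, multi-part, overlapping features), not fidelity to any
particular county.

## The rasterized oracle

`rasterOracle()` re-derives the per-class areas by pixel sampling, sharing
no geometry code with the vector pipeline: polygon masks come from an
even-odd scanline fill at pixel centers, stream buffers from exact
point-to-segment distance bands, the sensitive buffer and warning distances
from Euclidean distance transforms (Felzenszwalb–Huttenlocher), and the
classification from per-cell pixel aggregates using the same cell-level
rules (a cell is dropped when no non-sensitive pixel remains; Warning when
the minimum remaining-pixel distance to the sensitive region is within the
threshold; else Approved when any remaining pixel is wet). Two
discretization corrections are applied, both vanishing as resolution
shrinks:

* distances between two *pixelated* regions measured center-to-center
  overestimate the true region distance by up to one pixel (half a pixel per
  side), so the warning threshold is widened by one resolution unit;
* wetland presence uses "all-touched" rasterization (a pixel counts when a
  wetland boundary passes through its square), because the cell-level
  Approved rule is an intersects predicate and a boundary-grazing wetland
  with arbitrarily small overlap must still register.

Pixel-center sampling makes the area estimates unbiased as resolution
shrinks; on seeded synthetic counties the two routes agree to well under 1%
per class at 10 ft resolution, and the discrepancy shrinks as the
resolution is halved from 40 to 20 to 10 ft.

## Problem sizes used by the checks

The property suite runs the full pipeline and the 10-ft oracle on twenty
seeded 4-mile counties (2 rivers, 2 lakes, 35% wetland cover, 4 preserves,
250 addresses, 4×4 blocks) — large enough to exercise multi-cell grids,
partial erasure and all three classes, small enough to keep the whole suite
interactive. The acceptance script runs the default 10-mile county. These
sizes are the package's own verification choices, not statements about the
protocol's limits; the pipeline itself is routinely run on county-scale
inputs (hundreds of cells).

## Limitations

* The endangered-species (USFWS) administrative review that follows map
  production is out of scope, as are spray-drift physics, flight-path
  planning and arbovirus risk modelling.
* One county per run; statewide batch analysis is deliberately not
  orchestrated here.
* The projection registry covers the CRSs the protocol needs (geographic
  NAD83/WGS84 and the North Carolina State Plane zone in feet and metres);
  other State Plane zones would need registry entries.
* GeoPackage I/O requires a `python` interpreter with `shapely` on the
  PATH (used only for WKB encoding); Shapefile and GeoJSON are native.
* The municipal-boundary layer is a display-only passthrough, as in the
  protocol.
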
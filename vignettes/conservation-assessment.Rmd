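---
title: "Criterion B range metrics, Area of Habitat, and KBA scoping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criterion B range metrics, Area of Habitat, and KBA scoping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbascope)
```

This vignette is the package's account of the science it implements: the
models and procedures, the assumptions behind them, the parameters that
matter, and the design decisions taken where the methodology left genuine
choices open.

## The assessment problem

A narrow-range endemic species known from a handful of georeferenced
collection events needs three things for an IUCN criterion B evaluation: the
geometry of its range (EOO, AOO, localities), evidence about its habitat
(an Area-of-Habitat map and whether the species tracks it better than
chance), and a view of where site-based conservation could act (potential
Key Biodiversity Areas and their protected-area coverage). The package
implements that chain end-to-end and, because the real land-cover and
elevation layers are large external products, pairs it with a synthetic
island generator so that every stage can be exercised and tested
self-contained.

## Geometry: projection, hulls, grids

All areal work happens in a Lambert azimuthal equal-area (LAEA) projection
on the authalic sphere (R = 6 371 007.181 m), centred by default on the
occurrence centroid. Equal-area is the one property range metrics cannot do
without — EOO and AOO are areas — and the azimuthal form keeps distance
distortion negligible at island scale (the test suite checks planar polygon
areas against independently computed ellipsoidal areas to < 0.5 % and
projected distances against a great-circle oracle). Geodesic (on-ellipsoid)
polygon areas are out of scope; at 100-km extents the sphere/ellipsoid
discrepancy is far below the georeferencing uncertainty of historical
records.

The EOO is the area of the minimum convex polygon (convex hull) of the
projected records. The AOO uses the standard 2 × 2 km grid: cells follow a
half-open convention (`floor((coord − origin)/size)`, a point on a shared
edge belongs to the higher-index cell), which makes the grid an exact
partition — every point in exactly one cell. Grid origins default to the
projection origin but are configurable: AOO and KBA triggering genuinely
depend on grid placement, and published values obtained with an unknown
anchoring can shift by a cell. Degenerate inputs (fewer than three distinct
records, collinear sets) yield a zero-area EOO carrying a degeneracy flag;
areas below 1 mm² are treated as floating-point noise of collinear
configurations. Per IUCN guidance the EOO is floored at the AOO when both
are computed.

Coordinates arrive as decimal degrees or as the degree–minute–second strings
found on specimen labels (fractional seconds, hemisphere letter before or
after the digits, several unicode quote variants); the parser rejects
malformed tokens by name, and minutes or seconds outside `[0, 60)`.

## Localities

IUCN subcriterion (a) counts "locations"; published assessments rarely state
the delimitation rule. The package makes it explicit: records closer than a
linkage distance (default 10 km, great-circle) are chained into one locality
— single-linkage clustering, implemented as connected components with a
strict `<` cut. On the bundled seven-site *Nesodexia corsicana* table this
yields five localities (the two northern sites 2 km apart merge, as do the
two Samulaghia seeps 100 m apart), matching the published count. The linkage
distance is a tunable with real leverage near threshold counts; the default
is stated everywhere a count is reported.

The 1907 type locality "Campo di Loro" has no published coordinates. The
bundled table georeferences it to the Campo dell'Oro plain near Ajaccio
(41.93° N, 8.79° E), and the choice is overridable. The EOO is the only
metric sensitive to it: across plausible placements of that one point the
minimum convex polygon spans roughly 3 000–3 275 km² (the acceptance test
documents a ±10 % band around the published 3 012 km², and checks that the
six modern sites alone give ≈3 000 km²). AOO, locality count and the EN
classification are unchanged under any placement on that plain.

## Criterion B classification

The classifier applies the threshold table — B1 on EOO (CR < 100,
EN < 5 000, VU < 20 000 km²), B2 on AOO (CR < 10, EN < 500, VU < 2 000 km²) —
and requires the range condition plus two subcriteria: (a) severe
fragmentation or a locality count at or below the category threshold (CR 1,
EN 5, VU 10), and (b) observed continuing decline. Subcriterion (c), extreme
fluctuations, is not evaluated: assessments of poorly known invertebrates
essentially never have the time series to support it, so with (c) absent the
"two of a/b/c" rule reduces to requiring both (a) and (b). Missing flags are
treated as unmet and noted in the output rather than guessed. The criteria
string is emitted in the conventional compact form (`B1ab+B2ab`). The
classifier is tested against an exhaustive, independently written rule-table
oracle over all threshold bins and flag combinations.

## Area of Habitat

The habitat model is deliberately minimal — the set of land-cover classes
observed at the records, and the observed min–max elevation band — because
that is all a handful of collection events supports; it is a deductive
habitat mask, not a statistical species-distribution model, and the package
stays on that side of the line. Printed record elevations take precedence
over raster-sampled ones, and a printed range such as "25–300 m" contributes
its endpoints to the band. The band is taken without buffer by default
(`elev_buffer_m = 0`); a buffer is available for sensitivity analysis.

`build_aoh()` intersects suitable class, elevation band and an optional
boundary polygon (membership by cell centre), on the land cells of a shared
100 m raster grid. Two domains are produced in a full run: clipped to the
EOO hull (the species' known range) and island-wide (potential distribution
beyond the known localities); the clipped map necessarily nests inside the
island-wide one.

In the assessment driver the habitat model is inferred from modern records
only (collection year ≥ 1950, when a year is known). Historical records
cannot contribute reliable habitat observations, and their relationship to
*current* habitat is exactly the decline evidence subcriterion (b) needs: an
old record falling outside today's mapped habitat indicates habitat loss,
which is how the bundled case's 1907 type locality behaves.

## Hypergeometric validation

The map is validated by asking whether the records sit in habitat more often
than a random draw would: with `N` cells in the domain, `K` of them habitat,
and the records occupying `n` distinct cells of which `k` are habitat, the
upper-tail hypergeometric probability

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

is the chance of at least `k` habitat cells when drawing `n` cells without
replacement. Duplicate records in one cell count once (`n` is the number of
occupied cells, not records) to avoid pseudo-replication — repeated
collecting at one site says nothing extra about the map. The implementation
(`stats::phyper`) is checked against full enumeration of all
$\binom{N}{n}$ draws for every lattice point with `N ≤ 12`. The result
carries a `better_than_random` flag at a configurable `alpha` (default
0.05); only the flag is reported, not a significance claim, since the
sampling model (uniform cells) is itself an idealisation of collecting
effort. The validation domain is the EOO-clipped domain extended by the
records' own cells: hull-vertex records can otherwise fall out of the
discretised domain when their cell centre lies just outside the hull.

## KBA scoping

A 10 × 10 km grid (anchored at the projection origin; the anchor is
configurable so a grid-shift sweep can be run) scans the AOH. Each grid
cell's fraction of the global population is proxied by its share of total
habitat area — the defensible proxy when abundance data do not exist — so
the fractions sum to one over the AOH by construction. A cell triggers
criterion A1 (threatened species, the relevant sub-threshold for a CR/EN
species) at ≥ 0.5 % and criterion B1 (geographically restricted species) at
≥ 10 %; both thresholds are mandatory configuration because they depend on
the species' category. Potential-KBA boundaries are the habitat cells inside
triggering grid cells, kept at raster resolution. One useful consequence of
the area proxy is a hard impossibility bound: a 10-km cell holds at most
100 km² of habitat, so once the global AOH exceeds
`cell_area / b1_fraction = 1 000 km²` no cell can reach the 10 % B1
threshold — scoping a widespread-habitat species under B1 is structurally
null, and the tests assert this property on arbitrary synthetic maps.

The global-population denominator is the EOO-clipped AOH rather than the
island-wide one: the KBA Standard's population fractions refer to the
species' range, and scoping against the wider potential-distribution map
would dilute every cell's share with habitat the species is not known to
occupy. Protected-area coverage is the percentage of potential-KBA cells
whose centres fall inside the protected-area polygons; when the protected
area was generated on the same grid its defining mask is used directly,
which is exactly the cell-centre rule with no ray-casting round-off.
Reproductive-unit minima of the KBA Standard are not evaluated (no such data
in this setting).

## The synthetic landscape generator

The generator emulates the statistical structure the pipeline assumes, not
island ecology:

* **Relief and coastline** — white noise convolved with an isotropic
  Gaussian kernel (`smooth_sigma`, default 10 cells = 1 km; this sets the
  relief and coastline wavelength), tapered radially so land concentrates
  centrally, thresholded at the `sea_fraction` quantile (default 0.35) so
  the land share is exact by construction. Elevation is the rescaled field
  over land (0 to `max_elev`, default 1 500 m), hence smooth and
  autocorrelated like a real digital elevation model.
* **Land cover** — `n_classes` (default 8) elevation bands perturbed by a
  patchy categorical swap from a second smoothed field (top quartile of the
  patch field shifts class), giving a mosaic whose classes correlate with
  elevation but not deterministically — the property the habitat model
  actually relies on.
* **Occurrences** — records respect a declared ground truth (class set plus
  elevation band) with probability `p_in_habitat`; the complement and any
  forced outliers are drawn uniformly from *unsuitable* land, so the
  in-habitat fraction is exactly binomial in `p_in_habitat` and recovery
  tests have sharp expectations. Outliers are flagged historical
  (year < 1950), mirroring an old record stranded outside current habitat.
  Points are jittered uniformly within their cell.
* **Protected area** — a superlevel-set contour of the island field blended
  with inland-tapered seed noise; because the taper vanishes at the
  coastline the polygon is guaranteed to stay inside the coast, and the
  threshold is solved by order statistics so the enclosed land share hits
  the requested coverage within 2 % (cell-count bookkeeping). Coverage
  requests above 0.9 are rejected as infeasible.

Each generator runs on its own seed stream and restores the caller's RNG
state, so adding a generator never perturbs another's output and identical
seeds give bit-identical landscapes.

What the generator does *not* emulate — CORINE class semantics, land-cover
succession, rivers and urban fabric, collection-effort bias along roads —
bounds what passing tests show: they demonstrate the pipeline's arithmetic
and inference are correct under the stated sampling model, not that a real
CLC2018/SRTM assessment is insensitive to those factors.

## Numerical choices and degenerate inputs

* Half-open grid cells with higher-index tie-breaking: the partition
  property holds exactly, at the cost of an arbitrary but documented edge
  rule.
* Convex hulls are computed by the standard planar algorithm and returned
  counter-clockwise; the test suite checks the vertex set against an O(n³)
  orientation oracle.
* Point-in-polygon is even-odd ray casting over one or more rings (so
  contour-derived protected areas with holes behave correctly); points
  exactly on edges follow the crossing rule and are not relied upon.
* Collinear or coincident record sets give EOO 0 with a degeneracy flag
  rather than an error; empty habitat, empty KBA masks and header
  mismatches are errors naming the stage.
* Reports contain no timestamps, so identical configurations produce
  byte-identical JSON; provenance carries the seed, a config hash and input
  file checksums instead.

## Problem sizes

The test suite runs its property checks on landscapes between 100 × 100 and
200 × 200 cells, with one full end-to-end assessment at 500 × 500 cells
(25 km² of 100 m cells — the scale at which the KBA grid holds a few dozen
cells); enumeration oracles run at `N ≤ 12` where exhaustive draws are
cheap. These sizes were chosen so the whole suite completes in well under a
minute while every code path, including the raster ones, runs at a scale
where discretisation effects (one-cell errors) are visible and assertable.

## Known limitations

* The EOO inherits the georeferencing uncertainty of historical records;
  the package reports the sensitivity rather than hiding it.
* Locality delimitation is distance-based only; barriers or threat-based
  "location" definitions (the strict IUCN sense) are not modelled.
* The habitat model is presence-only and deductive; it cannot down-weight a
  class observed once by accident, and a single mis-georeferenced record
  widens the elevation band.
* The hypergeometric validation assumes cells were equally available to
  collectors; strong effort bias would inflate apparent habitat fidelity.
* KBA criteria beyond A1/B1, multi-species aggregation, and formal proposal
  documents are out of scope.
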
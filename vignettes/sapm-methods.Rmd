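---
title: "Mapping fishing fleets' spatial access priorities: model and methods"
author: "sapm"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapm)
```

## The problem

Spatial management of the sea — marine spatial plans, protected areas,
renewable-energy leasing — restricts where fishing can happen. To weigh those
restrictions fairly, a planner needs to know how much each part of the sea
matters *to the fishers themselves*, not just where effort is observed.
Vessel-monitoring (VMS) tracks exist only for larger vessels, record effort
rather than value, and never ask anyone anything. The alternative this package
implements is a participatory survey: skippers draw their priority areas as
polygons and state how important each is, and those responses are scaled up to
the whole fleet with a stratified weighting scheme.

## The model

**Units of priority.** Every full-time-equivalent (FTE) fisher carries a total
spatial access priority (SAP) of 100. Crew are counted pro rata:
`crew = full_time + sum(headcount × months/12)`, so a boat with four
year-round crew plus one member aboard six months has crew 4.5 and a total SAP
of 450.

**Importance values.** Respondents state either the fraction of the year
spent in each area (months, on (0, 12]) or unitless rank weights. Both are
converted to percentages and renormalised to sum to exactly 100 per
respondent-vessel. Renormalising (rather than trusting months to sum to 12)
is a design decision: the 100-per-fisher identity is what makes totals
interpretable, and stated months in interviews rarely sum exactly to a year.
A single area with no stated value receives 100; several unvalued areas share
100 equally. Mixing months and ranks within one respondent is refused rather
than guessed at.

**Density.** An area's priority density is `d = crew × importance / area`
(SAP km⁻², area in km²). Overlapping polygons from one respondent are allowed
and their contributions add; the importance normalisation prevents any
double-counting of the fisher's total mass.

**Stratification and up-scaling.** Vessels are stratified by
port × gear × length class. The default scheme has eight categories:
length bands <7, 7–<9, 9–<10, 10–<15, 15–<20 and ≥20 m, with the 9–<10 m band
split into pots / non-pots (pot boats of that size are often single-handed
while trawl and dredge boats of the same size carry two or more crew — the
package's `crew_gear_difference()` is exactly the pooled t-test that justifies
the split), the ≥20 m band taken as one non-pelagic class, and a dedicated
pelagic category at any length because pelagic crews (8–10) dwarf everything
else. The scheme is config-driven (`default_category_scheme()` is just a data
frame), rows are evaluated in order, and a scheme that leaves any (gear,
length) uncovered raises an error naming the gap.

For each combination, `E = n_vessels × mean_crew(category)` estimates the
stratum's crew from the register count and the *category-level* sample mean,
and `S` is the pro-rata crew actually interviewed there. The weight `W = E/S`
multiplies every density of that stratum's respondents, so the sample stands
in for the stratum: `W × S = E` by construction.

**Donor fallback.** A combination with vessels but no interviews cannot speak
for itself. Its estimated crew is reassigned to a donor: the sampled
combination with the same port and gear whose length class is nearest
(ties broken toward the smaller class — smaller vessels are the chronically
under-sampled stratum, and a deterministic rule is required); when no
same-port sample of that gear exists, the nearest port with that gear is used,
with port distances taken from configured coordinates (Euclidean in the
projected CRS, or great-circle for lon/lat) or, failing coordinates, from a
configured coastal ordering. The donor's weight becomes
`(E_donor + Σ E_represented)/S_donor`. The exact arithmetic of "upweighting
appropriately" was a genuinely open design point; this rule was chosen because
it conserves total estimated crew exactly, which makes the fleet-level audit
(below) possible. A gear with no samples anywhere cannot be up-scaled at all
and raises an error instead of a silent hole in the map.

**Conservation audit.** Three identities hold in exact arithmetic and are
asserted to 10⁻⁶ relative tolerance throughout the tests:

1. per respondent-vessel, `Σ d × A = 100 × crew`;
2. fleet-wide, `Σ W × d × A = 100 × Σ E`;
3. the exact-area raster total equals the vector total.

## Gridding

Rasters live on an axis-aligned grid in the projected CRS (inputs must share
one projected, metre-based CRS; geographic coordinates are refused with
instructions to reproject — on-the-fly reprojection is out of scope). Cells
are half-open `[x, x+cell) × [y, y+cell)`, default 1000 m so each cell is
1 km², with the origin snapped to the cell lattice.

Two rasterization rules are provided because the field's GIS tools are
ambiguous about theirs:

* **exact_area** (default): each cell receives `density × covered fraction`,
  computed by clipping the polygon against the cell rectangle
  (Sutherland–Hodgman against a convex window, exact for simple polygons).
  This conserves mass — the per-km² semantics of SAP plus layer summation
  implicitly assume it — and makes the raster total origin-independent.
* **cell_center**: full density wherever the cell centre falls inside, which
  mimics a plain GIS rasterizer for comparison. It does not conserve mass.

Never-touched cells are tracked as no-data, distinct from true zeros, and are
written as the no-data value in the ESRI ASCII grid exports.

The geometry kernel is the package's own (shoelace areas, convex clipping,
ear-clipping triangulation for exact polygon–polygon intersection areas,
even-odd point-in-polygon), with the clipping loops in C++. Polygons are
simple rings without holes; multipolygons are lists of disjoint parts.
Degenerate inputs — under three distinct vertices, zero area,
self-intersection — are rejected with the offending area named, not repaired:
deterministic rejection was preferred to heuristic repair, which would need a
full geometry engine and can silently change a respondent's answer.

Within-combination overlap (the consistency check behind up-scaling) is the
mean pairwise Jaccard index of respondents' footprints: exact by
triangulation when each footprint is a single polygon, and computed on a fine
grid (default 250 m cells) when a footprint has several parts, since an exact
polygon-set union is not attempted. The toy cases that define the statistic
(identical → 1, disjoint → 0, half-overlapping unit squares → 1/3) all hit
the exact path.

## Validation statistics

* Sample representativeness: a pooled two-sided t-test on vessel length
  (sample vs the active fleet), and chi-squared goodness-of-fit tests of the
  sample's port and gear frequencies against fleet proportions, with small
  ports grouped geographically via an explicit config (the grouping is a
  stated input, not inferred). Pooled rather than Welch variance is the
  default — consistent with `df = n₁ + n₂ − 2` reporting conventions for
  such surveys — and the helper is the same code path everywhere.
* Per-stratum coverage tables (active n, interviewed n, percent to one
  decimal).
* Effort congruency against an external gridded effort layer: the fraction of
  effort-positive cells that carry positive priority ("every fished area
  should have some priority"), plus a Spearman rank correlation over
  effort-positive cells as a pattern diagnostic. This makes a quantitative
  statistic of what is often done by eye.

## The synthetic generator

Raw interview data in studies of this kind are confidential, so the package
carries a generator (`sapm_scenario()`, `generate_population()`,
`draw_interviews()`) whose defaults are the study conditions the pipeline is
meant for: 246 active vessels across 20 ports (three major trawl/dredge ports
plus many minor pot ports along a synthetic coastline at 12 km spacing), a
gear mix dominated by a langoustine (Nephrops) trawl fishery with a large
potting sector, length mixtures per gear shaped like an inshore fleet,
vessel range from port increasing with length (pot boats capped at 8 km,
trawlers up to 60 km), 1–3 priority areas per respondent with Dirichlet
months-of-year importance, and stratified Bernoulli interviewing at 48%
inclusion.

Footprints are annular sectors anchored off the home port. Respondents in one
port-gear-length combination share a combination-level heading and radial
band and receive small individual jitters, so within-combination overlap is
high (the condition that justifies up-scaling) while pot footprints from
different ports barely overlap — the qualitative overlap structure reported
for real fleets.

Two deliberate simplifications:

* **Crew is a deterministic function of the category** (e.g. 9–<10 m pots: 1;
  9–<10 m non-pots: 2 plus a six-month hand; 15–<20 m: 3 plus a six-month
  hand; pelagic: 9). Crew counts of small commercial vessels are largely
  class-determined integers, and this choice makes the census identity exact:
  interviewing the whole synthetic fleet yields every W = 1 and a map
  identical to direct aggregation. With within-category crew variance a
  census would still conserve totals but per-stratum weights would wobble
  around 1 by sampling noise of the category mean.
* Geometry is convex-ish and port-anchored; real respondents draw raggeder,
  multi-part, sometimes distant grounds. Passing tests on synthetic data
  therefore demonstrate the estimator's arithmetic (conservation, weighting,
  gridding), not robustness to every shape a digitising session can produce.

A few respondents own a second vessel of the same port and gear and answer
once per vessel, so respondent and vessel counts differ slightly, as in real
surveys.

## Numerical choices and problem sizes

* All randomness flows from explicit seeds; the same seed reproduces
  bit-identical registers, polygons and rasters.
* Conservation assertions use 10⁻⁶ relative tolerance; identities that are
  exact in floating point (weights under a census, importance renormalisation)
  are asserted at 10⁻¹² or to machine precision.
* The exact-area rasterizer is cross-checked against a 32×32 sub-grid
  point-sampling oracle on random star-shaped polygons; the sub-grid's own
  discretisation error (≤ a few percent of a cell for boundary cells) sets
  that test's tolerance.
* Test suites run the full pipeline at 60–250 vessels and 1 km cells, a few
  seconds per fit; these sizes were chosen as the smallest at which every
  stratum type (sampled, donor-represented, multi-port gear) actually occurs.

## Adaptations

Two documented extensions of the weighting are implemented:
`adapt_processors()` folds shore-based processing employment into a fishery's
estimated crew (allocated across the fishery's combinations pro rata to E,
then weights recomputed), and `adapt_landings()` multiplies each layer's
weight by its fishery's landed value per fisher, turning the map into a
currency-scaled cost surface. Both conserve their respective totals and error
on fisheries that have value but no fishers or no combinations.

## Limitations

* No polygon holes, no geometry repair, no reprojection; inputs must be
  clean simple polygons in one projected CRS. GeoJSON is the interchange
  format; rasters are exported as ESRI ASCII grids.
* The multi-part Jaccard is grid-approximated (resolution configurable).
* The chi-squared tests are goodness-of-fit of sample frequencies against
  fleet proportions; with very small strata the explicit grouping config must
  be used, and the code errors (rather than warns) when expected counts
  vanish.
* The generator emulates survey structure, not any real fleet's geography;
  it is for testing the estimator, not for inference about a real fishery.
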
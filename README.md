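# sapm — Spatial Access Priority Mapping for fishing fleets

`sapm` turns interview-drawn priority polygons from fishers into quantitative,
fleet-wide maps of spatial access priority (SAP), the kind of evidence marine
spatial planners need when weighing closures, marine protected areas or
renewable-energy sites against the livelihoods of a fishing fleet. It is aimed
at fisheries scientists and conservation planners running participatory-GIS
surveys: it takes a vessel register and the survey polygons, scales the sample
up to the whole fleet, and produces per-fishery and fleet rasters, validation
statistics, closure-impact tables and Marxan cost layers.

## The method

Each full-time-equivalent fisher carries a total SAP of 100, distributed over
the areas they draw according to stated importance (fraction of the year spent
there, or rank weights, normalised to sum to 100). Part-year crew count
pro rata: a member aboard for *m* months contributes *m*/12 FTE, so a boat with
four year-round crew plus one extra full-timer for six months has crew 4.5 and
carries total SAP 450.

For one respondent's area the priority density is

> d = C × I / A  (SAP km⁻²)

with C the boat's pro-rata crew, I the importance value and A the polygon area
in km². One fisher spreading everything over 10 km² yields 10 SAP km⁻² — a
tenth of a fisher per square kilometre.

To represent the whole fleet, vessels are stratified by port × gear ×
length class (an eight-category default scheme: five length bands, a pots /
non-pots split at 9–10 m where pot boats carry fewer crew, and a dedicated
pelagic category). For each combination the estimated crew E = (register
count) × (category mean crew from the sample) is divided by the sampled crew S
to give the up-scaling weight W = E/S. Unsampled combinations are represented
by the sampled same-port, same-gear combination of nearest length class (then
by the nearest port with that gear), with the donor's weight inflated so total
estimated crew is conserved. Weighted layers are rasterized onto an equal-area
1 km² grid with an exact-area (mass-conserving) rule and summed, so that

> Σ cells (value × cell area) = Σ areas (W × d × A) = 100 × Σ combinations E.

Relative priority (density ÷ a group's total SAP) makes fisheries of different
size comparable; closure impact reports the fraction of each group's SAP
inside closure polygons; planning-unit costs aggregate SAP mass exactly for
use in Marxan.

## Worked example

The package ships a synthetic-fleet generator mirroring the survey design it
supports (a ~250-vessel inshore fleet across ~20 ports, interviewed at ~48%),
so the full pipeline runs without any confidential data:

```r
library(sapm)
pop <- generate_population(sapm_scenario(n_vessels = 60, n_ports = 6), seed = 7)
smp <- draw_interviews(pop, seed = 7)
fit <- sapm(smp$register, smp$responses, port_coords = smp$port_coords)
summary(fit)
#> Spatial access priority model
#>   fleet: 60 active vessels, 33 interviewed (55.0%)
#>   areas: 60 priority areas from 32 respondents; fisheries: nephrops, other, pots, scallops, whitefish
#>   grid: 87 x 60 cells of 1000 m (exact_area mode)
#>   total SAP: vector 15200.00, raster 15200.00, 100 x estimated crew 15200.00
#>   combinations: 30 (20 sampled, 10 represented via donors)
#>   weights W in [1.000, 12.857]
#>   SAP by fishery:
#>     nephrops       10630.78
#>     ...
#>   raster/vector conservation, relative error: 3.59e-16
```

The totals line is the audit: the map holds exactly 100 SAP per estimated
crew member (here 152 FTE), and rasterization lost nothing. `coef(fit)` gives
the weight table, `plot(fit)` the fleet map, `predict(fit, data.frame(x, y))`
point densities. Closure impact and cost-layer export:

```r
closure <- list(rbind(c(0, 0), c(30000, 0), c(30000, 15000), c(0, 15000)))
closure_impact(fit$layers, closure, by = "fishery")
#>       group sap_inside sap_total fraction
#> 1  nephrops    1998.26   10630.8   0.1880
#> 2     other     141.24    1650.0   0.0856
#> 3      pots     847.36    2100.0   0.4035
#> ...

costs <- export_marxan(fit, tile_planning_units(fit$grid, 3, 1))
sum(costs$cost)   # 15200: the tiling conserves total SAP
```

The pot fleet would lose 40% of its access priority to this closure while
whitefish grounds are untouched — exactly the equity comparison the method is
for.

A command-line pipeline (`inst/cli/sapm.R`, subcommands `simulate`,
`validate`, `map`, `impact`, `export-marxan`) wraps the same functions for
shell use; rasters are written as ESRI ASCII grids, weights and impact tables
as CSV, and every run leaves a provenance record.

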
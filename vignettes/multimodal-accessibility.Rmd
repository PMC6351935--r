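---
title: "Measuring multimodal spatial access to primary care: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multimodal spatial access to primary care: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model behind `sparaccess`, the assumptions it
makes, the parameters that matter, and the design decisions taken where the
methodology leaves genuine choices open. It is the place to look before
trusting a number the pipeline produces.

## The accessibility model

Potential spatial access combines three ingredients: clinic capacity
(providers `S_j`), population demand (`P_k` at dissemination-area
centroids), and travel impedance (minutes `d` over a mode-specific
network). The Enhanced Two-Step Floating Catchment Area method runs in two
passes over a 30-minute catchment divided into three travel-time subzones
with stepwise decay weights `W_r`:

* **Step 1 (supply):** each clinic's provider-to-population ratio is
  `R_j = S_j / Σ_k P_k W(d_kj)`, the sum over population locations inside
  the catchment.
* **Step 2 (demand):** each location's index is `A_i = Σ_j R_j W(d_ij)`
  over the clinics inside its catchment.

The default weights `1.00 / 0.42 / 0.09` over `0–10 / 10–20 / 20–30`
minutes encode the sharp distance decay appropriate to an urban setting
with many competing facilities; in rural applications a flatter scheme
(passed via `decay_scheme()`) would be more realistic. Zone intervals are
closed on the right (`d = 10` is in the first zone; `d = 30` is still
inside the catchment), matching the `d ≤ D_r` form of the zone definition.

Because raw `A_i` values are sensitive to the impedance parameters, we
report the **Spatial Access Ratio** `SPAR_i = A_i / mean(A)`, with the mean
taken unweighted over *all* population locations, zeros included. Whether
zero-access locations belong in the mean is ambiguous in parts of the
literature; including them only rescales every SPAR by a constant, so
ranks, quantile classes, and shortage sets are unaffected. Locations with
`SPAR = 0` — no clinic reachable within the catchment — are the physician
shortage areas; `shortage_summary()` reports their area, population, and
population share (rounded to one decimal, as conventionally printed, with
the exact value alongside).

Two invariants are worth knowing because the tests lean on them. On any
symmetric network, total allocated access conserves supply:
`Σ_i P_i A_i = Σ_j S_j` over clinics with non-empty catchments (each
clinic's providers are distributed across its catchment population and
summed back). And SPAR is invariant to rescaling all `S_j` by a common
factor. A clinic with an empty catchment gets `R_j = 0` and a
`catchment_empty` flag rather than an error; an entirely zero access vector
(no clinics anywhere) is an error, because a SPAR denominator of zero has
no meaningful interpretation.

## Networks by mode

All coordinates must be planar metres; geographic (degree) coordinates are
rejected at load time with a reprojection hint. Graphs connect segments at
endpoints only, with endpoints closer than `snap_tol_m` (default 0.5 m)
merged — generated data emits exactly coincident endpoints, so the
tolerance is a safety net. Travel time is the exact arithmetic conversion
`minutes = metres / (kmh × 1000/60)`; shortest paths are Dijkstra on
minute weights, with an inclusive cutoff (`t ≤ 30`, with a `1e-9` min
floating-point tolerance). Edges are undirected throughout: one-way
streets are out of scope, and symmetry is what makes the supply-conservation
identity exact.

**Driving** uses the road layer with per-class speeds (Collector 50,
Major 65, Expressway 80, Alley 15 km/h). Narrative class vocabularies
("primary highway", "local road", ...) are mapped onto the speed table via
a configurable alias map.

**Walking** uses sidewalks, trails, and pathways at a constant 4.8 km/h.
Municipal sidewalk layers are typically digitized per block and do not
touch across streets, so a naive graph is shattered into one component per
block. `generate_crosswalks()` manufactures the missing crossings: buffer
every road intersection by 18 m, treat the buffer boundary as a circular
line, split it where sidewalks cross it, and keep only the arcs that cross
a road — each retained arc is a crosswalk spanning one road arm from
sidewalk to sidewalk. Circles crossed by fewer than two sidewalk points
yield no arcs (there is nothing to connect). The walking builder then
splits sidewalk lines at arc endpoints so endpoint connectivity joins the
pieces. Crosswalks only ever add edges, so they can only shorten walking
times.

**Multimodal** adds bus and train edges on top of the walking network.
Route polylines are split at their stops/stations; pieces between
consecutive stops become transit edges at the route's class speed when it
has one, otherwise at the bus default 40 km/h or the train speed 45 km/h
(the train speed is a package default; published urban analyses often leave
it unstated). Bus travel time could alternatively be calibrated from
end-to-end scheduled trip times; we use the speed-table reading and expose
the speeds in `speed_map()` so either convention can be configured. Every
stop becomes a node linked to its nearest walking node (within 100 m;
farther stops are a data error, not silently dropped) at walking speed plus
an optional boarding penalty (default 0 — no timetables, headways, or
waiting are modelled). Transit is therefore enterable only at stops, and
the multimodal network contains the walking network as a subgraph, so
multimodal travel times can never exceed walking times. Note the same is
*not* claimed for accessibility indices: Step-1 denominators change with
the mode, so per-location `A_i` values need not nest across modes — only
travel times do.

Clinics and DA centroids are attached to each network by nearest-node
snapping (ties broken by smallest node id). In the multimodal network,
snapping is restricted to walking nodes: people reach clinics from the
sidewalk, not from the middle of a bus route. Both E2SFCA steps share one
facility-by-location travel-time matrix per mode, so the conservation
identity holds to machine precision.

## Spatial statistics

The covariates are the six small-area deprivation variables (proportions
separated/divorced/widowed, living alone, single-parent families, without a
high-school diploma; the employment-population ratio; average income).
Before regression they pass a greedy correlation filter (drop any variable
with |Pearson r| ≥ 0.70 against an already-retained one, scanning in the
given order).

Spatial weights are symmetrized k-nearest-neighbour (k = 8), row
standardized — chosen over contiguity as the default because it is robust
to irregular centroid spacing; queen contiguity on the DA polygons is
available as an alternative. Moran's I uses permutation inference
(999 random relabellings, two-sided, seed required) rather than the
analytic normal approximation, which is unreliable at the moderate n of
area-level work; it is computed both on SPAR values and on OLS residuals.

The spatial-lag model `y = ρWy + Xβ + ε` is fitted by maximum likelihood:
the log-likelihood is concentrated in ρ, the log-determinant
`log|I − ρW|` comes from the eigenvalues of the row-standardized W (real
by construction for a symmetrized neighbour structure), and ρ is searched
over `(1/λ_min, 1/λ_max)` by bounded scalar optimization (tolerance
`1e-8`). Standard errors come from the asymptotic information matrix of
`(β, ρ, σ²)`; the model is compared to OLS by a 1-df likelihood-ratio test
and by AIC with `k = p + 2` parameters (coefficients, ρ, σ²). An all-zero
weights matrix collapses the fit onto OLS with ρ = 0. If the response has
zero variance (see below), the statistics stage records the mode as
degenerate instead of fitting.

`simulate_sar()` provides ground truth
(`y = (I − ρW)^{-1}(Xβ + ε)`) for calibration experiments. At n = 400 and
ρ = 0.5 the ML estimator recovers ρ to within a few hundredths on average,
and the LR test holds its nominal 5% size at ρ = 0; both checks run in the
test suite (100 and 200 seeded replicates respectively).

## The synthetic city

`generate_city()` builds the study fixture: a `blocks_per_side²` grid
(default 20×20 blocks of 200 m — a 4 km city) with

* grid roads, every 5th line a Major, the rest Collectors;
* per-block sidewalk rings inset 6 m, deliberately disconnected so that
  crosswalk generation is *necessary* for walkability (the inset keeps each
  ring inside the 18-m crossing buffer of its corner intersections);
* one dissemination area per block with population drawn uniformly from
  400–700 (the defining size range of that census unit) and a
  population-weighted centroid jittered up to 20 m off the block centre;
* bus corridors on the interior Major rows spanning the central half of the
  city, stops every 400 m, and one full-length central train line with
  stations every 800 m — transit coverage thins toward the periphery, as in
  most real systems;
* clinics whose block is drawn with probability decaying exponentially from
  the city centre (bias 2 by default) and `1 + Poisson(2)` providers,
  reproducing the core-vs-periphery access gradient of real cities;
* covariates built from spatially autoregressive latent fields (ρ = 0.5)
  plus a centre-distance trend, mapped through the logistic function so
  proportions always lie in [0, 1]; income is log-normal. One pair
  (single-parent and no-high-school-diploma) is generated nearly collinear
  (|r| ≥ 0.9) by default to exercise the correlation filter.

Everything is drawn from one seeded generator: identical configs give
byte-identical layers, and `write_city_geojson()` round-trips losslessly.

What the fixture does *and does not* show. Because walking reaches 2.4 km
in 30 minutes while the city spans 4 km and clinics are centre-biased, the
default city yields a strictly positive walking shortage; transit rescues
part of it, and driving covers the whole city within the first decay zone.
Hence the default city reproduces the qualitative ordering *shortage(walk)
> shortage(multimodal) > shortage(drive)*. The weak ordering walk ≥
multimodal is structural (the multimodal graph contains the walking
graph); strictness depends on clinic placement interacting with corridor
coverage, and an occasional seed places a peripheral clinic so that transit
rescues no one (multimodal = walk). Passing tests on this fixture show the
pipeline's arithmetic and invariants; they do not show that real cities
have these magnitudes — real street topology, timetabled transit, one-way
streets, elevation, intersection delays, clinic capacity variation (hours,
full-time equivalents), and competition effects are all absent.

Two degeneracies of the desk-scale fixture are worth flagging. Driving
times across the 4 km default city all fall inside the first decay zone,
so every location gets the identical index and SPAR is exactly 1
everywhere: uniform access, zero shortage — and a constant response on
which autocorrelation or regression would be meaningless, so the
statistics stage skips it and says so. Walking and multimodal SPAR vary
richly and drive the regression stages. Second, quantile classification
with fewer positive values than classes leaves some classes empty; the
classes are cartographic only and feed no statistic.

## Numerical choices and test scale

* Endpoint snap tolerance 0.5 m; crosswalk arc vertices every ≤ 5° of arc;
  split points must lie within 1e-6 m of a segment.
* Stops must lie within 1 m of their route polyline; stop-to-sidewalk links
  within 100 m.
* Floating-point time comparisons use 1e-9 absolute tolerance; supply
  conservation and SPAR normalization hold to 1e-9 relative tolerance.
* Quantile ties are resolved in stable input order; node-snapping ties by
  smallest node id.
* Report CSVs are written at 6 significant digits for stable diffs; the
  JSON report retains full precision.

The test suite runs the full default city (20×20 blocks, ~400 DAs, 30
clinics) through all three modes once, checks the shortest-path engine
against exhaustive path enumeration on 200 random ≤ 8-node graphs, and
calibrates the lag model on 300 simulated datasets of n = 400 — sizes
chosen so the whole suite completes in a few minutes on one CPU while
still exercising every stage at realistic dimensionality.
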
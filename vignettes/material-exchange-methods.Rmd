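---
title: "Evaluating the land-sea material exchange function of intertidal wetlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the land-sea material exchange function of intertidal wetlands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tideflux)
```

## The problem

Intertidal wetlands exchange nutrients and sediment with the sea through
periodic tidal flooding. How much exchange a given patch of flat can
sustain depends on how much the water is slowed on its way there: by the
bare-soil substrate, by micro-topography, and above all by vegetation.
When a dense belt of tall vegetation — in the Yellow Sea flats, the
invasive cordgrass *Spartina alterniflora* — establishes across the
seaward fringe, it acts as a biological embankment: everything landward of
it receives less tidal water, the pioneer *Suaeda salsa* marsh degrades,
and the wetland's material balance shifts.

`tideflux` implements a raster evaluation of this process on a common
grid (the study configuration is 210 rows by 214 columns of 100 m cells,
1 ha per cell):

1. **Surface roughness.** Per-cell Manning roughness is composed
   additively, $n = n_{base} + n_{topo} + n_{vege}$, from a lookup table
   (`roughness_table()`).
2. **Exchange capacity.** Open-water cells are seeded with capacity
   $Ex = 1$; every other cell receives
   $Ex = \max_i \, Ex_i \,(1 - \mu n)$, the maximum over its admissible
   neighbours $i$, with $n$ the roughness of the *receiving* cell and
   $\mu = 0.4$ the attenuation adjustment coefficient (`propagate()`).
3. **Exchange index.** A year's capacity field is compared with a
   pre-disturbance reference year through the per-cell log-ratio
   $H_i = \ln(Ex_i / Ex_0)$ (`exchange_index()`).
4. **Summaries.** Zonal statistics by vegetation belt, areas above/below
   capacity thresholds (0.7 "high", 0.4 "low", strict inequalities), and
   per-belt capacity-bin area tables (`zonal_stats()`,
   `summarize_capacity()`, `bin_area_table()`).

## The roughness model

The lookup defaults are the standard assignments for a muddy tidal flat:

| component | value | applies to |
|---|---|---|
| $n_{base}$ | 0.025 | bare wetland soil (shell/gravel cover $\le$ 25 %) |
| $n_{base}$ | 0.030 | shell/gravel cover > 25 % |
| $n_{topo}$ | 0.001 | typical flat surface without micro-landforms |
| $n_{vege}$, short (S. salsa) | 0.025 / 0.030 / 0.035 | cover < 50 % / 50–75 % / $\ge$ 75 % |
| $n_{vege}$, tall (P. australis, S. alterniflora) | 0.050 / 0.060 / 0.070 | same bins |

So a fully vegetated cordgrass cell on a flat, non-shelly substrate
composes to $0.025 + 0.001 + 0.070 = 0.096$, and a mid-cover S. salsa
cell to $0.056$. Open-sea cells get $n = 0$ so water never attenuates the
signal. Coverage comes either from NDVI through the dimidiate pixel model
($VFC = (NDVI - NDVI_{min})/(NDVI_{max} - NDVI_{min})$, `compute_vfc()`)
or is supplied directly; the bin boundaries are read as
$[0, 0.5)$, $[0.5, 0.75)$, $[0.75, 1]$ so that 75 % cover falls in the
high bin and the partition is total.

Two cautions about the table. First, only the flat $n_{topo}$ value is
standard; a non-flat value is an explicit configuration
(`ntopo_non_flat`), with an optional 3×3 relief classifier
(`classify_relief()`, threshold 0.5 m) as the extension point. Second,
under the default table the smallest composable mean for a vegetated
S. salsa zone is $0.051$; reported zonal means slightly below that (e.g.
0.049) can only arise if unvegetated cells are averaged into the zone or
the topographic term is dropped, so this package range-checks zonal means
against the composable windows ($[0.051, 0.061]$ short,
$[0.076, 0.096]$ tall) rather than asserting any particular mean.

## The propagation and its oracles

The update $Ex(p) = (1 - \mu n(p)) \max_q Ex(q)$ has a unique fixed
point: for each cell, the maximum over all seed-to-cell paths of the
product of $(1 - \mu n)$ over the non-seed cells entered along the path.
`propagate()` computes it by monotone Jacobi sweeps from $Ex = 0$
(seeds pinned at 1), which converge because every factor lies in
$(0, 1]$ and path products cannot improve beyond the best simple path;
the result is therefore independent of sweep order. Convergence is
declared when the max per-cell change drops below `tolerance`
(default $10^{-9}$).

The neighbourhood over which the maximum is taken is a genuine modelling
choice — the original five-neighbour stencil is only defined pictorially
in the source material. Two modes are provided:

* `seaward5` (default): the five neighbours on and beside the sea-facing
  side (for an east-facing coast: E, NE, SE, N, S), i.e. the set a single
  landward sweep would consult;
* `full8`: the full Moore neighbourhood.

By path nesting, `full8` capacity dominates `seaward5` everywhere; on
belt-uniform scenes the two coincide exactly because the straight
landward path is already optimal. Diagonal steps are *not* length
corrected (no $\sqrt 2$ factor): the attenuation formula has no
step-length term, and fidelity to it was preferred over geometric
realism.

Two independent implementations guard the core:
`oracle_exchange()` (naive exhaustive relaxation, scalar loops) and
`oracle_shortest_path()` (log-space reduction: with node weights
$w(p) = -\ln(1 - \mu n(p))$, $Ex = e^{-d}$ for shortest-path distance
$d$ from the seeds, solved with Dijkstra's algorithm via igraph). The
test suite requires all three to agree to $10^{-9}$ per cell on random
grids in both neighbourhood modes.

Seeding is interpreted as the open-water boundary only: seeding all land
at 1 would make propagation vacuous. Reclaimed land, roads and ditches
(`OTHER_LAND`) can optionally be flagged impassable
(`barriers_from_other_land`), reflecting their blocking of tidal
nourishment; the option is off by default because no roughness value is
standard for them. Barrier and nodata cells carry $Ex = 0$, never
traversed; cells disconnected from every seed are flagged `unreachable`.

## The exchange index

$H_i = \ln(Ex_i/Ex_0)$ is computed per cell and aggregated as the
spatial mean of per-cell log-ratios over valid non-sea cells
(`aggregate_index(..., "mean_of_logs")`). The alternative — log of the
ratio of mean capacities — is exposed but not the default: per-cell
aggregation is the only reading consistent with published index series
whose aggregate values are more negative than the log-ratio of the
reported mean capacities, and by Jensen's inequality the per-cell mean of
logs is bounded above by the log of the mean per-cell ratio. Cells with
zero capacity in either year are masked with a warning (a log-ratio is
undefined there).

Capacity-bin area tables use half-open bins $[lo, hi)$ with a closed top
bin so that $Ex = 1$ is kept and interior edges belong to the upper bin;
capacities below the first edge go to an explicit `underflow` column so
per-belt areas are conserved. Areas are native hectares (1 cell = 1 ha)
with km² conversion for headline metrics; headline percentages are
rounded to the nearest integer percent in reports, but the exact
fractions are always returned (a 0.85 → 0.65 mean capacity drop is
reported as 23.5 %, not forced to a rounder figure).

## The synthetic scenario

No study rasters are deposited with the source publication, so the
package ships a generator (`generate_scenario()`) whose defaults *are*
the study conditions, and every claim the tests make about real data is
mediated by it. The default scenario:

* 210 × 214 grid, 100 m cells, sea on the east; years 1980–2017 at the
  study's nine observation dates;
* shore-parallel belts, land to sea: P. australis (104 cells), S. salsa
  (40), mudflat (40), sea (30);
* invasion from 1985 (the first post-reference year; the 1980 reference
  is the pre-invasion ideal state): a cordgrass belt appears seaward of
  the S. salsa belt and widens seaward into the mudflat by 3 cells
  (300 m) per step, reaching 2.4 km by 2017 — within the reported 1–3 km
  belt widths;
* per-class cover means 0.86 (cordgrass), 0.78 (reed), 0.61 (S. salsa)
  matching the reported multi-year zonal means, with truncated-normal
  per-cell dispersion (sd 0.08, exact inverse-CDF sampling so the
  analytic truncated mean in `scenario_truth()` is the estimand);
* elevation: landward-rising linear base (0.3 m at the shore cell,
  +0.0125 m per cell landward) plus per-class accretion per step chosen
  so a cell occupied by one class all series gains the reported per-belt
  totals (S. salsa +0.30 m, reed +0.14 m, cordgrass +1.24 m over the
  eight steps), plus fresh N(0, 0.05 m) noise per year;
* a post-invasion decline of the S. salsa cover mean (0.05 per step,
  floored at 0.20), emulating the documented degradation of the pioneer
  belt once tidal nourishment is reduced.

The S. salsa decline is load-bearing for one qualitative result. In a
pure path-product model, a new seaward belt multiplies the capacity of
*everything* landward of it by the same factor, so the S. salsa and
P. australis zonal indices would tie. Declining S. salsa cover lowers
that belt's own roughness, which relieves paths that cross the whole belt
(ending in P. australis) more than paths ending partway through it
(ending in S. salsa) — mechanistically producing the reported degradation
ordering *S. salsa* > *P. australis* > *S. alterniflora* rather than
hard-coding it. Magnitudes are not expected to match the published maps
(those depend on the real scene), only directions and orderings:
post-invasion mean capacity declines monotonically, high-capacity
(Ex > 0.7) area shrinks, low-capacity (Ex < 0.4) area grows.

What the generator deliberately does not emulate: tidal-creek morphology,
belt sinuosity and patchiness, Landsat radiometry, inter-annual cover
fluctuations of the reed belt, and seaward progradation of the shoreline.
Passing tests therefore demonstrate correctness of the *method* under
zonal geometry, not predictive skill on any particular coast.
`generate_bands()` closes the loop for the NDVI chain: it synthesises
band pairs whose NDVI→VFC recovery is exact to $10^{-6}$ in the
noise-free case (using fixed stretch endpoints 0.05/0.90, since scene
extrema only recover cover fields that actually attain 0 and 1).

## Numerical and I/O choices

* Rasters are read and written as ESRI ASCII grids (plain text,
  single band, nodata sentinel mirrored into the mask). Values are
  printed with 15 significant digits, so continuous round-trips are
  lossless to double precision for practical purposes.
* All layers in an analysis must share one `grid_spec` (shape, cell
  size, origin, sea side); `align_check()` failures are fatal downstream.
* Propagation problem size: the full default run (nine years on the
  210 × 214 grid) completes in a few seconds; convergence needs roughly
  one sweep per shore-normal grid column. The brute-force oracle is
  restricted to grids of at most 400 cells and the verification suite
  exercises it on 8 × 8 grids, twenty random replicates per mode.
* Elevation feeds only the zonal summaries by default ($n_{topo}$ is
  flat everywhere, as only the flat value is standard); terrain inversion
  from survey data is out of scope and elevation is a pluggable input.

## Known limitations

* The five-neighbour stencil is an interpretation (see above); both
  modes are provided and logged in the run manifest.
* The attenuation has no step-length or tidal-stage term: the capacity
  is a static attenuation surface, not a hydrodynamic simulation.
* Whether published capacity fields were computed with a single sweep or
  to convergence is unknowable from the text; this package always
  iterates to the fixed point, which is the only sweep-order-independent
  choice.
* Reported bin-area tables from the study do not reconcile exactly with
  its headline km² figures under either unit reading; the bundled copy is
  treated as a format fixture, and all of this package's own area tables
  conserve area by construction.
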
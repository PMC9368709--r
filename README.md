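# tideflux

Raster evaluation of the **land–sea material exchange function** of
intertidal wetlands, and of how an invasion of tall cordgrass
(*Spartina alterniflora*) degrades it.

Tidal flooding delivers the nutrients and sediment that keep a tidal-flat
ecosystem healthy. How much of that exchange reaches a given cell of the
flat depends on the hydraulic roughness the water crosses on its way from
open sea. `tideflux` models this on a common grid:

* **Manning roughness composition** — per cell,
  `n = n_base + n_topo + n_vege`, from a standard muddy-flat lookup
  (bare soil 0.025, flat micro-topography 0.001, vegetation 0.025–0.070
  by growth form and coverage bin);
* **Exchange-capacity propagation** — sea cells are seeded with
  `Ex = 1` and every other cell receives
  `Ex = max_i( Ex_i × (1 − μ·n) )` over its admissible neighbours, with
  `μ = 0.4`; the fixed point equals the best attenuation product over all
  sea-to-cell paths (verified against a brute-force relaxation oracle and
  an igraph shortest-path oracle in log space);
* **Exchange-function index** — `Hi = ln(Ex_i / Ex_0)` per cell against
  a pre-disturbance reference year, aggregated as the spatial mean of
  per-cell log-ratios;
* **Zonal summaries** — per-belt statistics, capacity-threshold areas
  (high: Ex > 0.7, low: Ex < 0.4) and capacity-bin area tables;
* **A synthetic zoned-wetland generator** — shore-parallel belts
  (reed → *Suaeda salsa* → mudflat → sea) with a cordgrass belt invading
  seaward of the *S. salsa* belt after 1985, per-belt accretion and cover
  statistics matching the reported Yancheng study conditions, so the whole
  pipeline is testable without any satellite data.

It is aimed at coastal-wetland and landscape ecologists who want a
transparent, oracle-checked implementation of the roughness-attenuation
approach to exchange-function mapping.

## Worked example

```r
library(tideflux)

# Reported per-belt elevation gains 1980 -> 2017 from the bundled
# zonal-elevation table:
elev <- read.csv(tideflux_example("yancheng_zonal_elevation.csv"))
zonal_delta(elev, "SUAEDA_SALSA", 1980, 2017)           # 0.30 m
zonal_delta(elev, "PHRAGMITES_AUSTRALIS", 1980, 2017)   # 0.14 m
zonal_delta(elev, "SPARTINA_ALTERNIFLORA", 1980, 2017)  # 1.24 m

# Headline capacity-area changes from the reported first/last-year summary:
cap <- read.csv(tideflux_example("yancheng_capacity_summary.csv"))
headline_metrics(cap)
#>   capacity_drop_fraction high_area_reduction_fraction low_area_fold_increase
#> 1              0.2352941                    0.7141921               3.083238
# i.e. the high-capacity (Ex > 0.7) area shrank by 71 % and the
# low-capacity (Ex < 0.4) area grew about 3-fold.

# End-to-end synthetic invasion scenario (210 x 214 grid, 9 years):
res <- run_pipeline(run_config())
res$per_year[c(1, 9), c("year", "mean_ex", "area_high_km2", "area_low_km2")]
#>   year   mean_ex area_high_km2 area_low_km2
#> 1 1980 0.3115559         71.40       256.08
#> 9 2017 0.2245757         43.17       311.91
subset(res$zonal_index, year == 2017, c(class, mean))
#>                  class       mean
#>           SUAEDA_SALSA -0.6105404
#>   PHRAGMITES_AUSTRALIS -0.5897821
#>  SPARTINA_ALTERNIFLORA -0.3376422
```

The synthetic run reproduces the qualitative invasion response: mean
capacity declines monotonically after the cordgrass belt appears, the
high-capacity area shrinks while the low-capacity area grows, and zonal
index degradation is ordered *S. salsa* > *P. australis* >
*S. alterniflora* — the belt behind the invader loses the most exchange,
the invader itself the least.

The numbered drivers under `analysis/` (`01_simulate_scenario.R` …
`04_sensitivity.R`) run these stages as a narrative workflow and write
their tables under `results/`. See
`vignettes/material-exchange-methods.Rmd` for the model, its assumptions
and the design decisions.

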
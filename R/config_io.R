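#' Save and load a run configuration as YAML
#'
#' Serialises a [run_config()] — scenario, reference year, propagation
#' parameters, roughness table, thresholds — to a single YAML file, so
#' that every modelling constant (mu, the roughness lookup, the 0.7/0.4
#' thresholds, the reference year) is auditable and overridable without
#' touching code. `read_run_config()` reconstructs an equivalent
#' [run_config()]; a round trip reproduces identical pipeline results.
#'
#' Only configurations whose scenario is a [scenario_config()] (not an
#' in-memory scene series) can be serialised.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly. `read_run_config()`:
#'   a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"),
            inherits(config$scenario, "scenario_config"))
  sc <- config$scenario
  g <- sc$grid
  x <- list(
    scenario = list(
      grid = list(n_rows = g$n_rows, n_cols = g$n_cols,
                  cell_size = g$cell_size, origin = as.list(g$origin),
                  sea_side = g$sea_side, nodata_value = g$nodata_value),
      years = as.list(sc$years),
      belt_widths = as.list(sc$belt_widths),
      invasion_year = sc$invasion_year,
      invasion_expansion_rate = sc$invasion_expansion_rate,
      accretion = as.list(sc$accretion),
      coverage_means = as.list(sc$coverage_means),
      coverage_sd = sc$coverage_sd,
      salsa_decline_per_step = sc$salsa_decline_per_step,
      salsa_cover_floor = sc$salsa_cover_floor,
      elevation_noise_sd = sc$elevation_noise_sd,
      shore_elevation = sc$shore_elevation,
      elevation_gradient = sc$elevation_gradient,
      sea_elevation = sc$sea_elevation,
      rng_seed = sc$rng_seed
    ),
    reference_year = config$reference_year,
    propagation = list(mu = config$propagation$mu,
                       neighborhood = config$propagation$neighborhood,
                       tolerance = config$propagation$tolerance),
    roughness = list(
      nbase_default = config$roughness$nbase_default,
      nbase_shelly = config$roughness$nbase_shelly,
      shelly_fraction_threshold = config$roughness$shelly_fraction_threshold,
      ntopo_flat = config$roughness$ntopo_flat,
      ntopo_non_flat = config$roughness$ntopo_non_flat,
      nvege_short = as.list(config$roughness$nvege_short),
      nvege_tall = as.list(config$roughness$nvege_tall),
      nvege_none = config$roughness$nvege_none
    ),
    thresholds = as.list(config$thresholds),
    barriers_from_other_land = config$barriers_from_other_land
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  s <- x$scenario
  scen <- scenario_config(
    grid = grid_spec(s$grid$n_rows, s$grid$n_cols,
                     cell_size = s$grid$cell_size,
                     origin = unlist(s$grid$origin),
                     sea_side = s$grid$sea_side,
                     nodata_value = s$grid$nodata_value),
    years = unlist(s$years),
    belt_widths = unlist(s$belt_widths),
    invasion_year = s$invasion_year,
    invasion_expansion_rate = s$invasion_expansion_rate,
    accretion = unlist(s$accretion),
    coverage_means = unlist(s$coverage_means),
    coverage_sd = s$coverage_sd,
    salsa_decline_per_step = s$salsa_decline_per_step,
    salsa_cover_floor = s$salsa_cover_floor,
    elevation_noise_sd = s$elevation_noise_sd,
    shore_elevation = s$shore_elevation,
    elevation_gradient = s$elevation_gradient,
    sea_elevation = s$sea_elevation,
    rng_seed = s$rng_seed
  )
  rt <- x$roughness
  run_config(
    scenario = scen,
    reference_year = x$reference_year,
    propagation = propagation_params(mu = x$propagation$mu,
                                     neighborhood = x$propagation$neighborhood,
                                     tolerance = x$propagation$tolerance),
    roughness = roughness_table(
      nbase_default = rt$nbase_default, nbase_shelly = rt$nbase_shelly,
      shelly_fraction_threshold = rt$shelly_fraction_threshold,
      ntopo_flat = rt$ntopo_flat, ntopo_non_flat = rt$ntopo_non_flat,
      nvege_short = unlist(rt$nvege_short),
      nvege_tall = unlist(rt$nvege_tall),
      nvege_none = rt$nvege_none
    ),
    thresholds = unlist(x$thresholds),
    barriers_from_other_land = isTRUE(x$barriers_from_other_land)
  )
}
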
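#' Configuration of the synthetic zoned-wetland scenario
#'
#' Describes a multi-year intertidal wetland with shore-parallel vegetation
#' belts ordered land-to-sea as Phragmites australis, Suaeda salsa,
#' (Spartina alterniflora after the invasion year), mudflat, open sea — the
#' zonal pattern typical of silty coastal flats. After `invasion_year` a
#' S. alterniflora belt is inserted seaward of the S. salsa belt and widens
#' seaward into the mudflat by `invasion_expansion_rate` cells per step.
#' Elevation rises landward and accretes per class per step; per-cell
#' vegetation cover is drawn from a truncated normal around per-class
#' means. After the invasion the S. salsa cover mean declines by
#' `salsa_decline_per_step` per step (floored at `salsa_cover_floor`),
#' emulating the degradation of the pioneer belt once tidal nourishment is
#' blocked.
#'
#' Default accretion rates are set so a cell occupied by a class for the
#' whole 1980-2017 series (8 steps) gains approximately the reported
#' per-belt totals: S. salsa +0.30 m, P. australis +0.14 m,
#' S. alterniflora +1.24 m.
#'
#' @param grid A [grid_spec()]; default the 210 x 214 study grid at 100 m.
#' @param years Ordered year labels.
#' @param belt_widths Named widths in cells, land to sea; any shortfall
#'   against the grid width becomes an `OTHER_LAND` landward margin.
#' @param invasion_year First year S. alterniflora is present.
#' @param invasion_expansion_rate Belt widening, cells per step.
#' @param accretion Named per-class elevation gain per step (m).
#' @param coverage_means Named per-class mean VFC.
#' @param coverage_sd Per-cell VFC dispersion.
#' @param salsa_decline_per_step Post-invasion per-step drop of the
#'   S. salsa cover mean.
#' @param salsa_cover_floor Lower bound of the declining S. salsa mean.
#' @param elevation_noise_sd Per-cell elevation noise (m), fresh each year.
#' @param shore_elevation Elevation (m) of the first land cell at the sea
#'   edge.
#' @param elevation_gradient Landward rise (m per cell).
#' @param sea_elevation Elevation assigned to open-sea cells (m).
#' @param rng_seed Integer seed; identical config + seed gives a
#'   bit-identical series.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(
    grid = grid_spec(210, 214, cell_size = 100, sea_side = "east"),
    years = c(1980, 1985, 1990, 1995, 2000, 2005, 2010, 2015, 2017),
    belt_widths = c(PHRAGMITES_AUSTRALIS = 104, SUAEDA_SALSA = 40,
                    MUDFLAT = 40, SEA = 30),
    invasion_year = 1985,
    invasion_expansion_rate = 3,
    accretion = c(MUDFLAT = 0.02, SUAEDA_SALSA = 0.0375,
                  PHRAGMITES_AUSTRALIS = 0.0175,
                  SPARTINA_ALTERNIFLORA = 0.155),
    coverage_means = c(MUDFLAT = 0.05, SUAEDA_SALSA = 0.61,
                       PHRAGMITES_AUSTRALIS = 0.78,
                       SPARTINA_ALTERNIFLORA = 0.86),
    coverage_sd = 0.08,
    salsa_decline_per_step = 0.05,
    salsa_cover_floor = 0.20,
    elevation_noise_sd = 0.05,
    shore_elevation = 0.3,
    elevation_gradient = 0.0125,
    sea_elevation = -1.0,
    rng_seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), length(years) >= 2)
  L <- if (grid$sea_side %in% c("east", "west")) grid$n_cols else grid$n_rows
  if (sum(belt_widths) > L) {
    stop("belt widths exceed the grid width", call. = FALSE)
  }
  if (any(c(accretion, coverage_sd, elevation_noise_sd,
            invasion_expansion_rate, salsa_decline_per_step) < 0)) {
    stop("rates and dispersions must be >= 0", call. = FALSE)
  }
  if (any(coverage_means < 0 | coverage_means > 1)) {
    stop("coverage means must lie in [0, 1]", call. = FALSE)
  }
  if (!invasion_year %in% years) {
    stop("invasion_year must be one of the scenario years", call. = FALSE)
  }
  structure(list(
    grid = grid, years = years, belt_widths = belt_widths,
    invasion_year = invasion_year,
    invasion_expansion_rate = invasion_expansion_rate,
    accretion = accretion, coverage_means = coverage_means,
    coverage_sd = coverage_sd,
    salsa_decline_per_step = salsa_decline_per_step,
    salsa_cover_floor = salsa_cover_floor,
    elevation_noise_sd = elevation_noise_sd,
    shore_elevation = shore_elevation,
    elevation_gradient = elevation_gradient,
    sea_elevation = sea_elevation,
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

# --- deterministic structural bookkeeping (no RNG) -------------------------

# Land-to-sea class code vector for one year (length = shore-normal extent).
belt_profile <- function(config, year_index) {
  cls <- wetland_classes()
  g <- config$grid
  L <- if (g$sea_side %in% c("east", "west")) g$n_cols else g$n_rows
  bw <- config$belt_widths
  inv_idx <- match(config$invasion_year, config$years)
  steps_since <- year_index - inv_idx + 1L
  w_inv <- if (steps_since >= 1) {
    min(config$invasion_expansion_rate * steps_since, bw[["MUDFLAT"]])
  } else 0L
  widths <- c(
    OTHER_LAND = L - sum(bw),
    PHRAGMITES_AUSTRALIS = unname(bw[["PHRAGMITES_AUSTRALIS"]]),
    SUAEDA_SALSA = unname(bw[["SUAEDA_SALSA"]]),
    SPARTINA_ALTERNIFLORA = w_inv,
    MUDFLAT = unname(bw[["MUDFLAT"]]) - w_inv,
    SEA = unname(bw[["SEA"]])
  )
  rep(cls[names(widths)], times = widths)
}

# Expand a land-to-sea profile vector into the grid matrix.
profile_to_matrix <- function(profile, grid) {
  switch(grid$sea_side,
    east = matrix(profile, grid$n_rows, grid$n_cols, byrow = TRUE),
    west = matrix(rev(profile), grid$n_rows, grid$n_cols, byrow = TRUE),
    north = matrix(rev(profile), grid$n_rows, grid$n_cols),
    south = matrix(profile, grid$n_rows, grid$n_cols)
  )
}

# Deterministic (noise-free) elevation profile per year: landward-rising
# base plus per-class accretion accumulated along each column's class
# history.
elevation_profiles <- function(config) {
  cls <- wetland_classes()
  n_years <- length(config$years)
  prof1 <- belt_profile(config, 1L)
  L <- length(prof1)
  sea_code <- cls[["SEA"]]
  d <- rev(cumsum(rev(prof1 != sea_code)))  # landward distance, 0 at sea
  base <- ifelse(prof1 == sea_code, config$sea_elevation,
                 config$shore_elevation +
                   config$elevation_gradient * (d - 1))
  accr_of <- function(codes) {
    a <- rep(0, length(codes))
    for (nm in names(config$accretion)) {
      a[codes == cls[[nm]]] <- config$accretion[[nm]]
    }
    a
  }
  out <- matrix(NA_real_, n_years, L)
  cum <- rep(0, L)
  out[1, ] <- base
  for (t in seq_len(n_years)[-1]) {
    cum <- cum + accr_of(belt_profile(config, t))
    out[t, ] <- base + cum
  }
  out
}

# Post-invasion declining S. salsa cover mean for one year.
salsa_mean_at <- function(config, year_index) {
  inv_idx <- match(config$invasion_year, config$years)
  steps_since <- max(0L, year_index - inv_idx + 1L)
  max(config$salsa_cover_floor,
      config$coverage_means[["SUAEDA_SALSA"]] -
        config$salsa_decline_per_step * steps_since)
}

# Mean of a normal(mu, sd) truncated to [0, 1].
truncnorm_mean <- function(mu, sd) {
  if (sd == 0) return(min(1, max(0, mu)))
  a <- (0 - mu) / sd; b <- (1 - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Inverse-CDF sampler for the same truncated normal.
rtruncnorm01 <- function(n, mu, sd) {
  if (sd == 0) return(rep(min(1, max(0, mu)), n))
  a <- stats::pnorm((0 - mu) / sd); b <- stats::pnorm((1 - mu) / sd)
  mu + sd * stats::qnorm(stats::runif(n, a, b))
}

#' Generate the synthetic multi-year wetland scene series
#'
#' Deterministic given `config$rng_seed`. Each year bundles a vegetation
#' raster, a VFC layer, an elevation layer and the sea (seed) mask, all on
#' one grid. Pre-invasion years contain no S. alterniflora.
#'
#' @param config A [scenario_config()].
#' @return A `scene_series`: `$config`, `$years`, and `$scenes` (one list
#'   per year with `year`, `veg`, `vfc`, `elevation`, `seed_mask`).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$rng_seed)
  cls <- wetland_classes()
  g <- config$grid
  elev_prof <- elevation_profiles(config)
  scenes <- vector("list", length(config$years))
  for (t in seq_along(config$years)) {
    prof <- belt_profile(config, t)
    veg_m <- profile_to_matrix(prof, g)
    elev_m <- profile_to_matrix(elev_prof[t, ], g) +
      matrix(stats::rnorm(g$n_rows * g$n_cols, 0,
                          config$elevation_noise_sd),
             g$n_rows, g$n_cols)
    means <- config$coverage_means
    means[["SUAEDA_SALSA"]] <- salsa_mean_at(config, t)
    vfc_m <- matrix(0, g$n_rows, g$n_cols)
    for (nm in names(means)) {
      sel <- veg_m == cls[[nm]]
      vfc_m[sel] <- rtruncnorm01(sum(sel), means[[nm]], config$coverage_sd)
    }
    seed_m <- veg_m == cls[["SEA"]]
    scenes[[t]] <- list(
      year = config$years[t],
      veg = wx_layer(g, veg_m, "categorical"),
      vfc = wx_layer(g, vfc_m, "continuous"),
      elevation = wx_layer(g, elev_m, "continuous"),
      seed_mask = seed_m
    )
  }
  structure(list(config = config, years = config$years, scenes = scenes),
            class = "scene_series")
}

#' Synthesise NIR/red band rasters from a cover field
#'
#' Inverse of the NDVI-to-VFC chain, for testing that chain end to end:
#' NDVI is mapped affinely from VFC between fixed endpoints (0.05, 0.90)
#' and split into band reflectances at constant total brightness, so
#' [compute_ndvi()] followed by [compute_vfc()] with the returned params
#' recovers the input cover field exactly in the noise-free case.
#'
#' @param vfc Cover [wx_layer()] in `[0, 1]`.
#' @param rng_seed Seed for the optional band noise.
#' @param noise_sd Gaussian noise added to each band (default 0).
#' @return List `nir`, `red` ([wx_layer()]s) and `params`
#'   (the matching [ndvi_params()]).
#' @export
generate_bands <- function(vfc, rng_seed = 1L, noise_sd = 0) {
  stopifnot(inherits(vfc, "wx_layer"))
  ndvi_lo <- 0.05; ndvi_hi <- 0.90
  ndvi <- ndvi_lo + vfc$values * (ndvi_hi - ndvi_lo)
  total <- 0.5
  nir <- total * (1 + ndvi) / 2
  red <- total * (1 - ndvi) / 2
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(rng_seed)
    nir <- pmax(0, nir + stats::rnorm(length(nir), 0, noise_sd))
    red <- pmax(0, red + stats::rnorm(length(red), 0, noise_sd))
  }
  list(
    nir = wx_layer(vfc$grid, matrix(nir, nrow(ndvi), ncol(ndvi))),
    red = wx_layer(vfc$grid, matrix(red, nrow(ndvi), ncol(ndvi))),
    params = ndvi_params(ndvi_min = ndvi_lo, ndvi_max = ndvi_hi)
  )
}

#' Closed-form expectations for a scenario (generator truth)
#'
#' Computes, from the configuration alone and independently of any
#' generated raster: per-year per-class expected zonal elevation means and
#' belt areas, per-year per-class expected cover means (analytic
#' truncated-normal means), and per-class cumulative accretion totals over
#' the series. Used as the oracle in parameter-recovery tests.
#'
#' @param config A [scenario_config()].
#' @return List with `zonal_elevation`, `coverage` and `accretion_totals`
#'   data.frames.
#' @export
scenario_truth <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cls <- wetland_classes()
  g <- config$grid
  across <- if (g$sea_side %in% c("east", "west")) g$n_rows else g$n_cols
  ha <- cell_area_ha(g)
  elev_prof <- elevation_profiles(config)
  zr <- list(); cr <- list()
  for (t in seq_along(config$years)) {
    prof <- belt_profile(config, t)
    means <- config$coverage_means
    means[["SUAEDA_SALSA"]] <- salsa_mean_at(config, t)
    for (nm in setdiff(names(cls), "SEA")) {
      sel <- prof == cls[[nm]]
      if (!any(sel)) next
      zr[[length(zr) + 1]] <- data.frame(
        year = config$years[t], class = nm,
        expected_mean_m = mean(elev_prof[t, sel]),
        width_cells = sum(sel),
        belt_area_ha = sum(sel) * across * ha
      )
      if (nm %in% names(means)) {
        cr[[length(cr) + 1]] <- data.frame(
          year = config$years[t], class = nm,
          expected_mean_vfc = truncnorm_mean(means[[nm]],
                                             config$coverage_sd)
        )
      }
    }
  }
  n_steps <- length(config$years) - 1L
  acc <- data.frame(
    class = names(config$accretion),
    per_step_m = as.numeric(config$accretion),
    steps = n_steps,
    total_m = as.numeric(config$accretion) * n_steps
  )
  list(
    zonal_elevation = do.call(rbind, zr),
    coverage = do.call(rbind, cr),
    accretion_totals = acc
  )
}
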
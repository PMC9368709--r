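# Shared fixture builders: everything is generated in code.

# Uniform-roughness layer with a sea column on the given side.
make_rough <- function(n_rows, n_cols, n = 0.056, sea_side = "east") {
  g <- grid_spec(n_rows, n_cols, sea_side = sea_side)
  wx_layer(g, matrix(n, n_rows, n_cols))
}

# Seed mask covering the sea-facing edge.
edge_seeds <- function(n_rows, n_cols, sea_side = "east") {
  m <- matrix(FALSE, n_rows, n_cols)
  switch(sea_side,
    east = m[, n_cols] <- TRUE,
    west = m[, 1] <- TRUE,
    north = m[1, ] <- TRUE,
    south = m[n_rows, ] <- TRUE
  )
  m
}

# Random roughness field in [0, n_max] with the sea column set to 0.
random_rough <- function(n_rows, n_cols, n_max = 0.1, sea_side = "east") {
  r <- make_rough(n_rows, n_cols, 0, sea_side)
  r$values <- matrix(stats::runif(n_rows * n_cols, 0, n_max),
                     n_rows, n_cols)
  seeds <- edge_seeds(n_rows, n_cols, sea_side)
  r$values[seeds] <- 0
  r
}

# Hand-built exchange_capacity with prescribed land values (for summaries).
fake_capacity <- function(values, sea_side = "east") {
  g <- grid_spec(nrow(values), ncol(values), sea_side = sea_side)
  structure(list(
    layer = wx_layer(g, values),
    params = propagation_params(),
    seed_mask = matrix(FALSE, nrow(values), ncol(values)),
    unreachable = matrix(FALSE, nrow(values), ncol(values))
  ), class = "exchange_capacity")
}

# Small invasion scenario for fast end-to-end tests.
small_scenario <- function(rng_seed = 1L, ...) {
  scenario_config(
    grid = grid_spec(30, 60, cell_size = 100, sea_side = "east"),
    belt_widths = c(PHRAGMITES_AUSTRALIS = 18, SUAEDA_SALSA = 10,
                    MUDFLAT = 16, SEA = 8),
    invasion_expansion_rate = 1,
    rng_seed = rng_seed, ...
  )
}
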
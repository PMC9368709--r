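# Matrix shifted so that out[r, c] = m[r + dr, c + dc] (fill outside).
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(out)
  out[r0:r1, c0:c1] <- m[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  out
}

# Neighbour offsets (dr, dc) a cell may receive capacity from.
# seaward5: the five neighbours on and beside the sea-facing side, so one
# landward sweep visits them all; full8: the whole Moore neighbourhood.
neighbor_offsets <- function(neighborhood, sea_side) {
  full <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                c(1, -1), c(1, 0), c(1, 1))
  if (neighborhood == "full8") return(full)
  switch(sea_side,
    east  = rbind(c(0, 1), c(-1, 1), c(1, 1), c(-1, 0), c(1, 0)),
    west  = rbind(c(0, -1), c(-1, -1), c(1, -1), c(-1, 0), c(1, 0)),
    north = rbind(c(-1, 0), c(-1, -1), c(-1, 1), c(0, -1), c(0, 1)),
    south = rbind(c(1, 0), c(1, -1), c(1, 1), c(0, -1), c(0, 1))
  )
}

#' Parameters of the exchange-capacity propagation
#'
#' @param mu Attenuation adjustment coefficient (default 0.4). Must satisfy
#'   `mu * max(n) < 1` so the per-step factor `1 - mu * n` stays in (0, 1].
#' @param neighborhood `"seaward5"` (five neighbours on and beside the
#'   sea-facing side) or `"full8"` (all eight neighbours).
#' @param tolerance Convergence threshold on the max absolute per-cell
#'   change between sweeps.
#' @param max_iterations Sweep cap; default `n_rows * n_cols` at run time.
#' @return An object of class `propagation_params`.
#' @export
propagation_params <- function(mu = 0.4,
                               neighborhood = c("seaward5", "full8"),
                               tolerance = 1e-9, max_iterations = NULL) {
  neighborhood <- match.arg(neighborhood)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  structure(list(mu = mu, neighborhood = neighborhood,
                 tolerance = tolerance, max_iterations = max_iterations),
            class = "propagation_params")
}

# Shared validation; returns list(factor matrix, blocked matrix, seeds).
prep_propagation <- function(roughness, seed_mask, barriers, params) {
  stopifnot(inherits(roughness, "wx_layer"),
            inherits(params, "propagation_params"))
  if (inherits(seed_mask, "wx_layer")) {
    require_aligned(roughness, seed_mask)
    seed_mask <- !is.na(seed_mask$values) & seed_mask$values != 0
  }
  stopifnot(is.matrix(seed_mask), identical(dim(seed_mask),
                                            dim(roughness$values)))
  if (is.null(barriers)) {
    barriers <- matrix(FALSE, nrow(seed_mask), ncol(seed_mask))
  } else if (inherits(barriers, "wx_layer")) {
    require_aligned(roughness, barriers)
    barriers <- !is.na(barriers$values) & barriers$values != 0
  }
  n <- roughness$values
  if (!any(seed_mask, na.rm = TRUE)) {
    stop("propagation requires at least one seed cell", call. = FALSE)
  }
  if (any(params$mu * n >= 1, na.rm = TRUE)) {
    stop("mu * n must stay below 1 everywhere", call. = FALSE)
  }
  fac <- 1 - params$mu * n
  blocked <- is.na(n) | barriers
  list(factor = fac, blocked = blocked, seeds = seed_mask & !blocked)
}

finish_capacity <- function(ex, prep, roughness, params) {
  ex[prep$blocked] <- 0
  ex[is.na(roughness$values)] <- NA_real_
  unreachable <- !is.na(roughness$values) & !prep$blocked & ex == 0
  structure(list(
    layer = wx_layer(roughness$grid, ex, "continuous"),
    params = params, seed_mask = prep$seeds, unreachable = unreachable
  ), class = "exchange_capacity")
}

#' @export
print.exchange_capacity <- function(x, ...) {
  v <- x$layer$values[!is.na(x$layer$values) & !x$seed_mask]
  cat(sprintf(
    "<exchange_capacity> mu = %g, %s; %d seeds; land Ex mean %.4f [%.4f, %.4f]\n",
    x$params$mu, x$params$neighborhood, sum(x$seed_mask),
    mean(v), min(v), max(v)
  ))
  invisible(x)
}

#' Propagate sea-land exchange capacity across the grid
#'
#' Sea (seed) cells start with exchange capacity `Ex = 1`; every other cell
#' receives `Ex = max_i(Ex_i * (1 - mu * n))`, the maximum over its
#' admissible neighbours `i` of the neighbour's capacity attenuated by the
#' receiving cell's Manning roughness `n`. The returned raster is the unique
#' fixed point of that update — equivalently, for each cell, the maximum
#' over all seed-to-cell paths of the product of `(1 - mu * n)` over the
#' non-seed cells entered along the path. Computed by monotone fixed-point
#' sweeps (vectorised Jacobi iteration), so the result is independent of
#' sweep order. Barrier cells carry `Ex = 0` and are never traversed; cells
#' disconnected from every seed end at `Ex = 0` and are flagged
#' `unreachable`.
#'
#' @param roughness Manning-n [wx_layer()] (e.g. from [compose_manning()]).
#' @param seed_mask Logical matrix or 0/1 [wx_layer()] marking sea cells.
#' @param barriers Optional logical matrix or 0/1 layer of impassable cells.
#' @param params A [propagation_params()].
#' @return An `exchange_capacity` object: `$layer` (Ex in `[0, 1]`),
#'   `$seed_mask`, `$unreachable`, `$params`, plus convergence diagnostics
#'   in `$iterations` and `$residual`.
#' @seealso [oracle_exchange()], [oracle_shortest_path()] for independent
#'   reference computations.
#' @export
propagate <- function(roughness, seed_mask, barriers = NULL,
                      params = propagation_params()) {
  prep <- prep_propagation(roughness, seed_mask, barriers, params)
  offs <- neighbor_offsets(params$neighborhood, roughness$grid$sea_side)
  fac <- prep$factor
  fac[prep$blocked] <- 0
  max_iter <- if (is.null(params$max_iterations)) {
    nrow(fac) * ncol(fac)
  } else {
    params$max_iterations
  }
  ex <- matrix(0, nrow(fac), ncol(fac))
  ex[prep$seeds] <- 1
  iter <- 0L
  repeat {
    iter <- iter + 1L
    nb <- matrix(0, nrow(fac), ncol(fac))
    for (k in seq_len(nrow(offs))) {
      nb <- pmax(nb, shift_matrix(ex, offs[k, 1], offs[k, 2], fill = 0))
    }
    ex_new <- fac * nb
    ex_new[prep$seeds] <- 1
    delta <- max(abs(ex_new - ex))
    ex <- ex_new
    if (delta < params$tolerance) break
    if (iter >= max_iter) {
      stop("propagation did not converge within max_iterations",
           call. = FALSE)
    }
  }
  out <- finish_capacity(ex, prep, roughness, params)
  out$iterations <- iter
  out$residual <- delta
  out
}

#' Brute-force propagation oracle (exhaustive relaxation)
#'
#' Computes the same fixed point as [propagate()] by naive per-cell
#' label-correcting relaxation: repeated full-grid scalar sweeps, each cell
#' re-reading its neighbours from the previous sweep's values, until no cell
#' changes. Deliberately unvectorised and free of any priority structure;
#' intended for verification on small grids.
#'
#' @inheritParams propagate
#' @return An `exchange_capacity` object.
#' @export
oracle_exchange <- function(roughness, seed_mask, barriers = NULL,
                            params = propagation_params()) {
  prep <- prep_propagation(roughness, seed_mask, barriers, params)
  offs <- neighbor_offsets(params$neighborhood, roughness$grid$sea_side)
  nr <- nrow(prep$factor); nc <- ncol(prep$factor)
  if (nr * nc > 400) {
    stop("oracle_exchange is for small grids (<= 400 cells)", call. = FALSE)
  }
  ex <- matrix(0, nr, nc)
  ex[prep$seeds] <- 1
  repeat {
    prev <- ex
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (prep$seeds[r, c] || prep$blocked[r, c]) next
      best <- 0
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (prev[rr, cc] > best) best <- prev[rr, cc]
      }
      ex[r, c] <- best * prep$factor[r, c]
    }
    if (max(abs(ex - prev)) < params$tolerance) break
  }
  finish_capacity(ex, prep, roughness, params)
}

#' Shortest-path propagation oracle (log-space)
#'
#' Second independent reference: with node weight
#' `w(p) = -ln(1 - mu * n(p))` accrued on entering cell `p`, the fixed point
#' satisfies `Ex(p) = exp(-d(p))` where `d(p)` is the shortest-path distance
#' from any seed under the same neighbourhood. Built as an igraph digraph
#' and solved with Dijkstra's algorithm.
#'
#' @inheritParams propagate
#' @return An `exchange_capacity` object.
#' @export
oracle_shortest_path <- function(roughness, seed_mask, barriers = NULL,
                                 params = propagation_params()) {
  prep <- prep_propagation(roughness, seed_mask, barriers, params)
  offs <- neighbor_offsets(params$neighborhood, roughness$grid$sea_side)
  nr <- nrow(prep$factor); nc <- ncol(prep$factor)
  idx <- function(r, c) (c - 1L) * nr + r
  w_node <- -log(prep$factor)          # weight paid on entering a cell
  w_node[prep$seeds] <- 0
  from <- integer(0); to <- integer(0); w <- numeric(0)
  open <- !prep$blocked
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    # receiving cells (r, c) whose neighbour (r+dr, c+dc) is in range
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    rc <- expand.grid(r = r0:r1, c = c0:c1)
    ok <- open[cbind(rc$r, rc$c)] & open[cbind(rc$r + dr, rc$c + dc)]
    rc <- rc[ok, , drop = FALSE]
    from <- c(from, idx(rc$r + dr, rc$c + dc))
    to <- c(to, idx(rc$r, rc$c))
    w <- c(w, w_node[cbind(rc$r, rc$c)])
  }
  src <- nr * nc + 1L
  seeds_i <- which(prep$seeds)
  g <- igraph::make_empty_graph(n = nr * nc + 1L, directed = TRUE)
  ev <- c(as.vector(rbind(rep(src, length(seeds_i)), seeds_i)),
          as.vector(rbind(from, to)))
  g <- igraph::add_edges(g, ev,
                         attr = list(weight = c(rep(0, length(seeds_i)), w)))
  d <- igraph::distances(g, v = src, mode = "out",
                         algorithm = "dijkstra")[1, seq_len(nr * nc)]
  ex <- matrix(exp(-d), nr, nc)
  ex[is.infinite(d)] <- 0
  finish_capacity(ex, prep, roughness, params)
}

#' Summarise exchange capacity over a region
#'
#' Statistics over valid, non-seed (land) cells in a region: mean, min,
#' max, cell count, and the areas above/below the two capacity thresholds
#' (strict inequalities). Areas are reported in km² from the grid's cell
#' area.
#'
#' @param ex An `exchange_capacity` from [propagate()].
#' @param region_mask Optional logical matrix restricting the summary.
#' @param high,low Capacity thresholds; "high" area has `Ex > high`, "low"
#'   area has `Ex < low`.
#' @return A one-row data.frame with columns `mean_ex`, `min_ex`, `max_ex`,
#'   `n_cells`, `area_high_km2`, `area_low_km2`.
#' @export
summarize_capacity <- function(ex, region_mask = NULL, high = 0.7,
                               low = 0.4) {
  stopifnot(inherits(ex, "exchange_capacity"))
  v <- ex$layer$values
  sel <- !is.na(v) & !ex$seed_mask
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(region_mask), dim(v)))
    sel <- sel & region_mask
  }
  if (!any(sel)) stop("empty region in capacity summary", call. = FALSE)
  ha <- cell_area_ha(ex$layer$grid)
  vv <- v[sel]
  data.frame(
    mean_ex = mean(vv), min_ex = min(vv), max_ex = max(vv),
    n_cells = sum(sel),
    area_high_km2 = sum(vv > high) * ha / 100,
    area_low_km2 = sum(vv < low) * ha / 100
  )
}
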
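test_that("zero roughness propagates the seed value unattenuated", {
  r <- make_rough(5, 6, n = 0)
  ex <- propagate(r, edge_seeds(5, 6))
  expect_true(all(ex$layer$values == 1))
})

test_that("one step from the seed applies the attenuation formula once", {
  g <- grid_spec(1, 2)
  r <- wx_layer(g, matrix(c(0.096, 0), 1, 2))
  ex <- propagate(r, matrix(c(FALSE, TRUE), 1, 2))
  expect_equal(ex$layer$values[1, 1], 1 * (1 - 0.4 * 0.096))
  expect_equal(ex$layer$values[1, 2], 1)  # seed exactly 1
})

test_that("a uniform chain follows the closed form (1 - mu n)^j", {
  k <- 10; n <- 0.056
  g <- grid_spec(1, k + 1)
  r <- wx_layer(g, matrix(c(rep(n, k), 0), 1, k + 1))
  seeds <- matrix(c(rep(FALSE, k), TRUE), 1, k + 1)
  for (nb in c("seaward5", "full8")) {
    ex <- propagate(r, seeds, params = propagation_params(neighborhood = nb))
    for (j in seq_len(k)) {
      expect_equal(ex$layer$values[1, k + 1 - j], (1 - 0.4 * n)^j,
                   tolerance = 1e-12)
    }
  }
})

test_that("propagate equals both oracles on random grids", {
  set.seed(11)
  for (rep in 1:20) {
    r <- random_rough(8, 8)
    seeds <- edge_seeds(8, 8)
    for (nb in c("seaward5", "full8")) {
      p <- propagation_params(neighborhood = nb)
      a <- propagate(r, seeds, params = p)$layer$values
      b <- oracle_exchange(r, seeds, params = p)$layer$values
      d <- oracle_shortest_path(r, seeds, params = p)$layer$values
      expect_lt(max(abs(a - b)), 1e-9)
      expect_lt(max(abs(a - d)), 1e-9)
    }
  }
})

test_that("capacity is monotone decreasing in roughness and in mu", {
  set.seed(12)
  for (rep in 1:5) {
    r <- random_rough(8, 8)
    seeds <- edge_seeds(8, 8)
    base <- propagate(r, seeds)$layer$values
    # raise n at a random non-seed cell
    r2 <- r
    cell <- cbind(sample(8, 1), sample(7, 1))
    r2$values[cell] <- r2$values[cell] + 0.05
    bumped <- propagate(r2, seeds)$layer$values
    expect_true(all(bumped <= base + 1e-12))
    # raise mu
    hi_mu <- propagate(r, seeds,
                       params = propagation_params(mu = 0.6))$layer$values
    expect_true(all(hi_mu <= base + 1e-12))
  }
})

test_that("all outputs are bounded in [0, 1] with seeds exactly 1", {
  set.seed(13)
  r <- random_rough(10, 10)
  seeds <- edge_seeds(10, 10)
  ex <- propagate(r, seeds)
  expect_true(all(ex$layer$values >= 0 & ex$layer$values <= 1))
  expect_true(all(ex$layer$values[seeds] == 1))
})

test_that("full8 capacity dominates seaward5 (more admissible paths)", {
  set.seed(14)
  for (rep in 1:5) {
    r <- random_rough(8, 8)
    seeds <- edge_seeds(8, 8)
    e5 <- propagate(r, seeds,
                    params = propagation_params(neighborhood = "seaward5"))
    e8 <- propagate(r, seeds,
                    params = propagation_params(neighborhood = "full8"))
    expect_true(all(e8$layer$values >= e5$layer$values - 1e-12))
  }
})

test_that("the fixed point is independent of sweep order", {
  # Gauss-Seidel sweeps in two different cell orders must land on the same
  # fixed point as the Jacobi implementation.
  set.seed(15)
  r <- random_rough(6, 6)
  seeds <- edge_seeds(6, 6)
  p <- propagation_params(neighborhood = "full8")
  ref <- propagate(r, seeds, params = p)$layer$values
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                c(1, -1), c(1, 0), c(1, 1))
  gauss_seidel <- function(order) {
    fac <- 1 - p$mu * r$values
    ex <- matrix(0, 6, 6); ex[seeds] <- 1
    repeat {
      prev <- ex
      for (i in order) {
        rr <- (i - 1) %% 6 + 1; cc <- (i - 1) %/% 6 + 1
        if (seeds[rr, cc]) next
        best <- 0
        for (k in 1:8) {
          r2 <- rr + offs[k, 1]; c2 <- cc + offs[k, 2]
          if (r2 >= 1 && r2 <= 6 && c2 >= 1 && c2 <= 6 &&
              ex[r2, c2] > best) best <- ex[r2, c2]
        }
        ex[rr, cc] <- best * fac[rr, cc]
      }
      if (max(abs(ex - prev)) < 1e-12) break
    }
    ex
  }
  expect_lt(max(abs(gauss_seidel(1:36) - ref)), 1e-9)
  expect_lt(max(abs(gauss_seidel(36:1) - ref)), 1e-9)
  expect_lt(max(abs(gauss_seidel(sample(36)) - ref)), 1e-9)
})

test_that("barriers block traversal and isolated cells are flagged", {
  g <- grid_spec(5, 5)
  r <- wx_layer(g, matrix(0.03, 5, 5))
  seeds <- matrix(FALSE, 5, 5); seeds[, 5] <- TRUE
  barriers <- matrix(FALSE, 5, 5)
  barriers[2:4, 2:4] <- TRUE; barriers[3, 3] <- FALSE  # ringed interior
  ex <- propagate(r, seeds, barriers = barriers,
                  params = propagation_params(neighborhood = "full8"))
  expect_equal(ex$layer$values[3, 3], 0)
  expect_true(ex$unreachable[3, 3])
  expect_true(all(ex$layer$values[barriers] == 0))
  expect_false(any(ex$unreachable[barriers]))
  # oracle agrees on the blocked topology
  ob <- oracle_exchange(r, seeds, barriers = barriers,
                        params = propagation_params(neighborhood = "full8"))
  expect_equal(ex$layer$values, ob$layer$values, tolerance = 1e-9)
})

test_that("degenerate propagation inputs raise specific errors", {
  r <- make_rough(4, 4, 0.05)
  expect_error(propagate(r, matrix(FALSE, 4, 4)), "at least one seed")
  r_big <- make_rough(4, 4, 3)
  expect_error(propagate(r_big, edge_seeds(4, 4)), "below 1")
  expect_error(oracle_exchange(make_rough(25, 25, 0.01),
                               edge_seeds(25, 25)), "small grids")
})

test_that("capacity summaries convert counts to km2 with strict thresholds", {
  # 100 land cells of Ex = 1 at 100 m cells -> 1.00 km2 above 0.7
  r <- make_rough(10, 11, 0)
  seeds <- matrix(FALSE, 10, 11); seeds[, 11] <- TRUE
  s <- summarize_capacity(propagate(r, seeds))
  expect_equal(s$n_cells, 100)
  expect_equal(s$area_high_km2, 1.00)
  expect_equal(s$area_low_km2, 0)
  # uniform 0.3: everything is below the low threshold
  ex <- fake_capacity(matrix(0.3, 5, 20))
  s2 <- summarize_capacity(ex)
  expect_equal(s2$mean_ex, 0.3)
  expect_equal(s2$area_low_km2, 1.00)
  expect_equal(s2$area_high_km2, 0)
  # strictness: Ex exactly at a threshold counts on neither side
  ex3 <- fake_capacity(matrix(c(0.7, 0.4), 1, 2))
  s3 <- summarize_capacity(ex3)
  expect_equal(s3$area_high_km2, 0)
  expect_equal(s3$area_low_km2, 0)
  expect_error(summarize_capacity(ex3, region_mask = matrix(FALSE, 1, 2)),
               "empty region")
})
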
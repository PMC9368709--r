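test_that("index is zero against itself and log-ratio otherwise", {
  ex0 <- fake_capacity(matrix(0.8, 4, 5))
  hi0 <- exchange_index(ex0, ex0)
  expect_true(all(hi0$layer$values == 0))
  expect_equal(aggregate_index(hi0), 0)
  ex1 <- fake_capacity(matrix(0.8 * exp(-1), 4, 5))
  hi1 <- exchange_index(ex1, ex0)
  expect_equal(as.vector(hi1$layer$values), rep(-1, 20))
  # scalar check on uniform capacities 0.65 vs 0.85
  hi2 <- exchange_index(fake_capacity(matrix(0.65, 2, 2)),
                        fake_capacity(matrix(0.85, 2, 2)))
  expect_equal(aggregate_index(hi2), log(0.65 / 0.85))
  expect_equal(round(log(0.65 / 0.85), 4), -0.2683)
})

test_that("zero-capacity cells are masked with a warning", {
  a <- matrix(0.5, 3, 3); a[2, 2] <- 0
  expect_warning(hi <- exchange_index(fake_capacity(a),
                                      fake_capacity(matrix(0.5, 3, 3))),
                 "masked")
  expect_true(is.na(hi$layer$values[2, 2]))
  expect_equal(sum(!is.na(hi$layer$values)), 8)
  expect_error(suppressWarnings(
    exchange_index(fake_capacity(matrix(0, 2, 2)),
                   fake_capacity(matrix(1, 2, 2)))
  ), "fully masked")
})

test_that("mean of per-cell logs is below log of the mean ratio (Jensen)", {
  set.seed(21)
  for (rep in 1:10) {
    a <- matrix(runif(36, 0.05, 1), 6, 6)
    b <- matrix(runif(36, 0.05, 1), 6, 6)
    hi <- exchange_index(fake_capacity(a), fake_capacity(b))
    # Jensen: E[ln r] <= ln E[r] over the per-cell capacity ratios r
    expect_lte(aggregate_index(hi, "mean_of_logs"), log(mean(a / b)) + 1e-12)
    # the alternative aggregation stays available and finite
    expect_true(is.finite(aggregate_index(hi, "log_of_means")))
  }
})

test_that("change maps reduce to Hi in log mode and Ex difference otherwise", {
  ex0 <- fake_capacity(matrix(0.85, 3, 3))
  ex1 <- fake_capacity(matrix(0.65, 3, 3))
  hi <- exchange_index(ex1, ex0)
  expect_identical(change_map(hi), hi$layer)
  expect_equal(as.vector(change_map(hi, "difference")$values),
               rep(-0.2, 9))
  half <- exchange_index(fake_capacity(matrix(0.4, 3, 3)),
                         fake_capacity(matrix(0.8, 3, 3)))
  expect_equal(as.vector(change_map(half)$values), rep(log(0.5), 9))
})

test_that("zonal statistics aggregate per class over valid cells", {
  g <- grid_spec(3, 3)
  cls <- wetland_classes()
  veg <- wx_layer(g, matrix(c(cls[["SUAEDA_SALSA"]], cls[["SUAEDA_SALSA"]],
                              cls[["PHRAGMITES_AUSTRALIS"]],
                              rep(cls[["MUDFLAT"]], 6)), 3, 3),
                  "categorical")
  target <- wx_layer(g, matrix(c(1, 2, 3, rep(0, 6)), 3, 3))
  zs <- zonal_stats(target, veg)
  sal <- zs[zs$class == "SUAEDA_SALSA", ]
  expect_equal(c(sal$min, sal$max, sal$mean), c(1, 2, 1.5))
  phr <- zs[zs$class == "PHRAGMITES_AUSTRALIS", ]
  expect_equal(c(phr$min, phr$max, phr$mean), c(3, 3, 3))
  expect_false("SPARTINA_ALTERNIFLORA" %in% zs$class)  # absent class omitted
  # uniform layer: min = max = mean everywhere
  zu <- zonal_stats(wx_layer(g, matrix(7, 3, 3)), veg)
  expect_true(all(zu$min == 7 & zu$max == 7 & zu$mean == 7))
})

test_that("zonal table utilities reproduce deltas and grand means", {
  df <- data.frame(year = rep(c(2000, 2010), each = 2),
                   class = rep(c("A", "B"), 2),
                   mean = c(1.0, 2.0, 1.5, 2.2))
  expect_equal(zonal_delta(df, "A", 2000, 2010), 0.5)
  expect_equal(zonal_delta(df, "B", 2000, 2010), 0.2)
  expect_error(zonal_delta(df, "C", 2000, 2010), "no unique row")
  gm <- zonal_grand_means(df, stats = "mean")
  expect_equal(gm$mean[gm$class == "A"], 1.25)
})

test_that("bin areas use half-open bins, a closed top bin, and conserve area", {
  g <- grid_spec(1, 10)
  cls <- wetland_classes()
  veg <- wx_layer(g, matrix(cls[["SUAEDA_SALSA"]], 1, 10), "categorical")
  ex <- fake_capacity(matrix(0.85, 1, 10))
  tab <- bin_area_table(ex, veg)
  expect_equal(tab[["0.8-0.9"]], 10)
  expect_equal(sum(tab[-1]), 10)
  expect_equal(tab$underflow, 0)
  # edge membership: exactly 0.2 goes to the upper bin; 1.0 is kept
  ex2 <- fake_capacity(matrix(c(0.2, 1.0, 0.05, 0.1, 0.9999, rep(0.5, 5)),
                              1, 10))
  t2 <- bin_area_table(ex2, veg)
  expect_equal(t2[["0.2-0.3"]], 1)
  expect_equal(t2[["0.1-0.2"]], 1)      # the 0.1 cell, not the 0.2 cell
  expect_equal(t2[["0.9-1"]], 2)        # 1.0 falls in the closed top bin
  expect_equal(t2$underflow, 1)         # the 0.05 cell is not dropped
  # conservation: bins + underflow sum to the zone area
  expect_equal(sum(t2[-1]), 10)
  # lattice sweep: every capacity lands in exactly one bin
  v <- matrix(seq(0, 1, length.out = 201), 1, 201)
  vg <- wx_layer(grid_spec(1, 201),
                 matrix(cls[["MUDFLAT"]], 1, 201), "categorical")
  t3 <- bin_area_table(fake_capacity(v), vg)
  expect_equal(sum(t3[-1]), 201)
  expect_equal(bin_area_table(fake_capacity(v), vg, units = "km2")[-1] * 100,
               t3[-1], ignore_attr = TRUE)
  expect_error(bin_area_table(ex, veg, bin_edges = c(0.1, 0.1, 0.5)),
               "strictly increasing")
})

test_that("headline metrics reproduce the reported-area arithmetic", {
  s <- data.frame(mean_ex = c(0.85, 0.65),
                  area_high_km2 = c(39.67, 11.34),
                  area_low_km2 = c(17.54, 71.62))
  h <- headline_metrics(s)
  expect_equal(round(100 * h$high_area_reduction_fraction), 71)
  expect_equal(round(h$low_area_fold_increase), 3)
  expect_equal(h$capacity_drop_fraction, (0.85 - 0.65) / 0.85)
  same <- s[c(1, 1), ]
  expect_true(all(headline_metrics(same) == 0))
  expect_error(headline_metrics(transform(s, mean_ex = c(0, 1))),
               "degenerate")
})
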
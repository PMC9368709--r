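test_that("identical config and seed give a bit-identical series", {
  a <- generate_scenario(small_scenario(rng_seed = 9))
  b <- generate_scenario(small_scenario(rng_seed = 9))
  expect_identical(a, b)
  c2 <- generate_scenario(small_scenario(rng_seed = 10))
  expect_false(identical(a$scenes[[1]]$vfc$values, c2$scenes[[1]]$vfc$values))
})

test_that("belts are shore-parallel and ordered land to sea", {
  series <- generate_scenario(small_scenario())
  cls <- wetland_classes()
  for (sc in series$scenes) {
    v <- sc$veg$values
    expect_true(all(apply(v, 2, function(col) length(unique(col)) == 1)))
    expect_true(all(v[, ncol(v) - 0:7] == cls[["SEA"]]))  # sea margin east
    profile <- v[1, ]
    land <- profile[profile != cls[["SEA"]]]
    order_seen <- unique(land)
    expected <- cls[c("OTHER_LAND", "PHRAGMITES_AUSTRALIS", "SUAEDA_SALSA",
                      "SPARTINA_ALTERNIFLORA", "MUDFLAT")]
    expect_equal(order_seen, as.numeric(expected[expected %in% order_seen]),
                 ignore_attr = TRUE)
    expect_identical(sc$seed_mask, v == cls[["SEA"]])
  }
})

test_that("no cordgrass exists before the invasion year", {
  series <- generate_scenario(small_scenario())
  cls <- wetland_classes()
  pre <- series$years < series$config$invasion_year
  for (t in seq_along(series$years)) {
    count <- sum(series$scenes[[t]]$veg$values ==
                   cls[["SPARTINA_ALTERNIFLORA"]])
    if (pre[t]) expect_equal(count, 0) else expect_gt(count, 0)
  }
  # the belt widens monotonically after invasion
  widths <- vapply(series$scenes, function(sc) {
    sum(sc$veg$values[1, ] == cls[["SPARTINA_ALTERNIFLORA"]])
  }, numeric(1))
  expect_true(all(diff(widths[!pre]) >= 0))
})

test_that("reed-belt cover mean is recovered across seeds", {
  cls <- wetland_classes()
  means <- vapply(1:10, function(s) {
    series <- generate_scenario(small_scenario(rng_seed = s))
    sc <- series$scenes[[1]]
    mean(sc$vfc$values[sc$veg$values == cls[["PHRAGMITES_AUSTRALIS"]]])
  }, numeric(1))
  expect_true(all(abs(means - 0.78) < 0.05))
})

test_that("coverage means match the truncated-normal truth within 3 SE", {
  cfg <- small_scenario(rng_seed = 5)
  truth <- scenario_truth(cfg)
  series <- generate_scenario(cfg)
  cls <- wetland_classes()
  for (t in c(1, length(series$years))) {
    sc <- series$scenes[[t]]
    tr <- truth$coverage[truth$coverage$year == series$years[t], ]
    for (i in seq_len(nrow(tr))) {
      sel <- sc$veg$values == cls[[tr$class[i]]]
      se <- cfg$coverage_sd / sqrt(sum(sel))
      expect_lt(abs(mean(sc$vfc$values[sel]) - tr$expected_mean_vfc[i]),
                3 * se + 1e-12)
    }
  }
})

test_that("zonal elevation means match the generator truth within 3 SE", {
  cfg <- small_scenario(rng_seed = 6)
  truth <- scenario_truth(cfg)
  series <- generate_scenario(cfg)
  cls <- wetland_classes()
  for (t in seq_along(series$years)) {
    sc <- series$scenes[[t]]
    tr <- truth$zonal_elevation[truth$zonal_elevation$year ==
                                  series$years[t], ]
    for (i in seq_len(nrow(tr))) {
      sel <- sc$veg$values == cls[[tr$class[i]]]
      expect_equal(sum(sel), tr$width_cells[i] * cfg$grid$n_rows)
      se <- cfg$elevation_noise_sd / sqrt(sum(sel))
      expect_lt(abs(mean(sc$elevation$values[sel]) - tr$expected_mean_m[i]),
                3 * se + 1e-12)
    }
  }
})

test_that("belt areas match widths exactly and zero accretion is flat", {
  cfg <- small_scenario()
  truth <- scenario_truth(cfg)
  y1 <- truth$zonal_elevation[truth$zonal_elevation$year == cfg$years[1], ]
  expect_equal(y1$belt_area_ha,
               y1$width_cells * cfg$grid$n_rows * cell_area_ha(cfg$grid))
  flat <- small_scenario(accretion = c(MUDFLAT = 0, SUAEDA_SALSA = 0,
                                       PHRAGMITES_AUSTRALIS = 0,
                                       SPARTINA_ALTERNIFLORA = 0))
  tf <- scenario_truth(flat)$zonal_elevation
  for (k in c("SUAEDA_SALSA", "PHRAGMITES_AUSTRALIS")) {
    expect_equal(length(unique(tf$expected_mean_m[tf$class == k])), 1)
  }
  expect_true(all(scenario_truth(flat)$accretion_totals$total_m == 0))
})

test_that("per-cell accretion totals are recovered from the elevation series", {
  cfg <- small_scenario(rng_seed = 7)
  truth <- scenario_truth(cfg)
  series <- generate_scenario(cfg)
  cls <- wetland_classes()
  first <- series$scenes[[1]]; last <- series$scenes[[length(series$years)]]
  gain <- last$elevation$values - first$elevation$values
  for (k in c("SUAEDA_SALSA", "PHRAGMITES_AUSTRALIS")) {
    sel <- first$veg$values == cls[[k]] & last$veg$values == cls[[k]]
    se <- cfg$elevation_noise_sd * sqrt(2) / sqrt(sum(sel))
    tot <- truth$accretion_totals$total_m[truth$accretion_totals$class == k]
    expect_lt(abs(mean(gain[sel]) - tot), 3 * se)
  }
  # cordgrass: cells invaded at the first post-invasion step accrete the
  # cordgrass rate for every step of the series
  inv_t <- match(cfg$invasion_year, cfg$years)
  sel <- series$scenes[[inv_t]]$veg$values == cls[["SPARTINA_ALTERNIFLORA"]]
  se <- cfg$elevation_noise_sd * sqrt(2) / sqrt(sum(sel))
  tot <- truth$accretion_totals$total_m[
    truth$accretion_totals$class == "SPARTINA_ALTERNIFLORA"]
  expect_lt(abs(mean(gain[sel]) - tot), 3 * se)
})

test_that("band synthesis inverts the NDVI-VFC chain", {
  set.seed(31)
  g <- grid_spec(12, 12)
  vfc <- wx_layer(g, matrix(runif(144), 12, 12))
  vfc$values[1, 1] <- 0; vfc$values[2, 2] <- 1
  bands <- generate_bands(vfc)
  rec <- compute_vfc(compute_ndvi(bands$nir, bands$red), bands$params)
  expect_lt(max(abs(rec$values - vfc$values)), 1e-6)
  expect_equal(rec$values[1, 1], 0)
  expect_equal(rec$values[2, 2], 1)
})

test_that("scenario configuration is validated", {
  expect_error(scenario_config(belt_widths = c(PHRAGMITES_AUSTRALIS = 200,
                                               SUAEDA_SALSA = 40,
                                               MUDFLAT = 40, SEA = 30)),
               "exceed")
  expect_error(scenario_config(coverage_sd = -1), ">= 0")
  expect_error(scenario_config(invasion_year = 1983), "scenario years")
  expect_error(scenario_config(coverage_means = c(MUDFLAT = 1.2,
                                                  SUAEDA_SALSA = 0.6,
                                                  PHRAGMITES_AUSTRALIS = 0.7,
                                                  SPARTINA_ALTERNIFLORA = 0.8)),
               "\\[0, 1\\]")
})
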
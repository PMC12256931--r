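test_that("elevation generation is deterministic and respects the flat limit", {
  cfg <- test_config()
  e1 <- generate_elevation(cfg)
  e2 <- generate_elevation(cfg)
  expect_identical(e1$values, e2$values)
  expect_gte(min(e1$values), 0)
  expect_equal(max(e1$values), cfg$ruggedness_scale)

  flat <- generate_elevation(test_config(ruggedness_scale = 0))
  expect_true(all(flat$values == 0))
  tri <- terrain_ruggedness_index(flat)
  expect_true(all(tri$values == 0))
})

test_that("a rugged 40x40 terrain occupies several ruggedness classes", {
  cfg <- landscape_config(extent_m = c(6000, 6000), cell_size_m = 150,
                          seed = 7, ruggedness_scale = 500)
  tri <- terrain_ruggedness_index(generate_elevation(cfg))
  layer <- classify_continuous(tri, tri_scheme())
  expect_gte(length(unique(stats::na.omit(as.vector(layer$values)))), 3)
})

test_that("landcover respects fractions, elevation zoning and domains", {
  cfg <- test_config(regen_fraction = 0, snowice_fraction = 0)
  el <- generate_elevation(cfg)
  lc <- generate_landcover(el, cfg)
  lv <- landcover_levels()
  land <- generate_land_mask(el, cfg)$values == 1
  present <- unique(as.vector(lc$values[land]))
  expect_setequal(present, lv[c("mature_forest", "bryoid_shrub_herb",
                                "barren_rock")])
  # water cells carry the water category and only that
  expect_true(all(lc$values[!land] == lv[["water"]]))

  cfg2 <- test_config(snowice_fraction = 0.1)
  el2 <- generate_elevation(cfg2)
  lc2 <- generate_landcover(el2, cfg2)
  land2 <- generate_land_mask(el2, cfg2)$values == 1
  snow <- lc2$values == lv[["snow_ice"]] & land2
  q90 <- stats::quantile(el2$values[land2], 0.9, names = FALSE)
  expect_true(any(snow))
  expect_true(all(el2$values[snow] >= q90))

  # regen occupies roughly its configured share of land
  cfg3 <- test_config(regen_fraction = 0.2)
  el3 <- generate_elevation(cfg3)
  lc3 <- generate_landcover(el3, cfg3)
  land3 <- generate_land_mask(el3, cfg3)$values == 1
  share <- mean(lc3$values[land3] == lv[["regenerating_forest"]])
  expect_gt(share, 0.1); expect_lt(share, 0.3)
})

test_that("streams stay on land and reach lengths respect the truncation", {
  cfg <- test_config(n_streams = 4, reaches_per_stream = 3)
  el <- generate_elevation(cfg)
  land <- generate_land_mask(el, cfg)
  net <- generate_hydrology(el, cfg)
  expect_equal(nrow(net$streams), 4)
  # every reach vertex sits on a land cell and inside the extent
  for (geom in net$reaches$geometry) {
    expect_true(all(geom[, 1] >= 0 & geom[, 1] <= cfg$extent_m[1]))
    expect_true(all(geom[, 2] >= 0 & geom[, 2] <= cfg$extent_m[2]))
    rc <- cell_at_xy(el, geom[, 1], geom[, 2])
    expect_true(all(land$values[rc] == 1))
  }
  # reaches of one stream share its watershed code
  codes <- split(net$reaches$watershed_code, net$reaches$stream_id)
  expect_true(all(vapply(codes, function(x) length(unique(x)) == 1L, TRUE)))
  # two species can hold distinct reach records on one stream
  multi <- vapply(split(net$reaches$species, net$reaches$watershed_code),
                  function(x) length(unique(x)), 0L)
  expect_gte(max(multi), 2)

  # truncated log-normal sampler honours the observed bounds
  draws <- bearcircuit:::with_seed(1, bearcircuit:::rlnorm_trunc(
    10000, log(1700), 1, 19, 11300))
  expect_gte(min(draws), 19)
  expect_lte(max(draws), 11300)
  expect_lt(abs(median(draws) - 1700) / 1700, 0.15)
})

test_that("snag sites land on land, one per cell, with the right pair count", {
  cfg <- test_config()
  el <- generate_elevation(cfg)
  land <- generate_land_mask(el, cfg)
  sites <- generate_snag_sites(cfg, 30, el)
  expect_equal(nrow(sites), 30)
  expect_true(all(land$values[cbind(sites$row, sites$col)] == 1))
  expect_false(any(duplicated(cbind(sites$row, sites$col))))
  expect_identical(sites$x, generate_snag_sites(cfg, 30, el)$x)

  expect_equal(nrow(node_pairs(sites)), 30 * 29 / 2)
  two <- sites[1:2, ]
  expect_equal(nrow(node_pairs(two)), 1)
  expect_error(generate_snag_sites(cfg, 1), "at least 2")
})

test_that("detection simulation respects its limits and model structure", {
  cfg <- test_config()
  sites <- generate_snag_sites(cfg, 12)
  none <- detection_model(baseline_detection_prob = 0)
  expect_equal(nrow(simulate_detections(sites, none, 1)), 0)

  all_seen <- detection_model(n_individuals = c(black_bear = 5L),
                              home_range_sigma_m = 1e9,
                              baseline_detection_prob = 1,
                              n_years = 2, sessions_per_year = 2)
  det <- simulate_detections(sites, all_seen, 1)
  # every individual at every site in every of the 4 sessions
  expect_equal(nrow(det), 5 * 12 * 4)

  mod <- detection_model(n_individuals = c(black_bear = 50L),
                         home_range_sigma_m = 5170,
                         baseline_detection_prob = 0.3, n_years = 1)
  det2 <- simulate_detections(sites, mod, 99)
  multi <- vapply(split(det2$site_id, det2$individual_id),
                  function(s) length(unique(s)) >= 2L, TRUE)
  expect_gt(mean(multi), 0)
  expect_identical(det2, simulate_detections(sites, mod, 99))
})

test_that("transit simulation matches its log-odds model", {
  n <- 2145
  pairs <- tibble::tibble(
    conductance = withr::with_seed(3, stats::rlnorm(n)),
    distance_m = withr::with_seed(4, stats::runif(n, 1400, 102000))
  )
  # null model: ~50% transits
  null_fit <- simulate_transits(pairs, transit_sim_model(0, 0, 0), 11)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(null_fit$transited) - 0.5), 3 * se)

  # calibrated intercept with the anchored slopes gives a rare-event base
  # rate matching the observed 54/2145 transit fraction
  b0 <- calibrate_intercept(pairs)
  cal <- transit_sim_model(beta0 = b0)
  rates <- vapply(1:30, function(s)
    mean(simulate_transits(pairs, cal, s)$transited), 0)
  expect_lt(abs(mean(rates) - 54 / 2145), 0.005)
  # and the Monte-Carlo rate of any model matches its analytic expectation
  dflt <- transit_sim_model()
  zg <- as.numeric(scale(pairs$conductance))
  zdd <- as.numeric(scale(pairs$distance_m))
  analytic <- mean(plogis(dflt$beta0 + dflt$beta_G * zg + dflt$beta_d * zdd))
  mc <- mean(vapply(1:30, function(s)
    mean(simulate_transits(pairs, dflt, s)$transited), 0))
  expect_lt(abs(mc - analytic), 0.005)

  # strongly negative distance effect -> monotone decay over quartiles
  strong <- simulate_transits(pairs, transit_sim_model(
    beta0 = 0, beta_G = 0, beta_d = -3), 5)
  qs <- cut(strong$distance_m,
            stats::quantile(strong$distance_m, 0:4 / 4),
            include.lowest = TRUE)
  freq <- tapply(strong$transited, qs, mean)
  expect_true(all(diff(freq) < 0))

  # degenerate predictor under standardization is an error
  flat <- tibble::tibble(conductance = rep(1, 10),
                         distance_m = 1:10)
  expect_error(simulate_transits(flat, transit_sim_model(), 1),
               "zero-variance")
})
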
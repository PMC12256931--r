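test_that("TRI matches the hand-computed neighbourhood formula", {
  z <- matrix(0, 3, 3); z[2, 2] <- 10
  tri <- terrain_ruggedness_index(grid_create(z, 150))
  expect_equal(tri$values[2, 2], sqrt(8 * 100))
  # corner of the same grid: one neighbour differs by 10
  expect_equal(tri$values[1, 1], 10)

  # translation invariance
  z2 <- matrix(runif(25), 5, 5)
  t1 <- terrain_ruggedness_index(grid_create(z2, 150))
  t2 <- terrain_ruggedness_index(grid_create(z2 + 137, 150))
  expect_equal(t1$values, t2$values)

  expect_error(terrain_ruggedness_index(grid_create(matrix(0, 2, 2), 1)),
               "3x3")
})

test_that("Fisher-Jenks breaks find obvious clusters and are optimal", {
  b <- jenks_breaks(c(1, 2, 3, 100, 101, 102), 2)
  expect_gte(b[2], 3); expect_lt(b[2], 100)

  # k = number of distinct values: every value its own class
  b2 <- jenks_breaks(c(5, 1, 9), 3)
  expect_equal(b2, c(1, 1, 5, 9))

  # optimality against 1000 random break sets
  x <- withr::with_seed(10, stats::rnorm(200))
  k <- 6
  br <- jenks_breaks(x, k)
  wss <- function(breaks) {
    cls <- findInterval(x, breaks[-c(1, length(breaks))] + 1e-12) + 1L
    sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
  }
  ours <- wss(br)
  rand <- withr::with_seed(11, replicate(1000, {
    cuts <- sort(sample(sort(x)[-200], k - 1))
    wss(c(min(x), cuts, max(x)))
  }))
  expect_true(all(ours <= rand + 1e-9))

  expect_error(jenks_breaks(1:10, 1), "at least 2")
  expect_error(jenks_breaks(c(1, 1, 1), 2), "distinct")
})

test_that("published class tables reproduce exactly, with open extremes", {
  tri <- tri_scheme()
  g <- function(x) classify_continuous(grid_create(matrix(x, 1, 1,), 150),
                                       tri)$values[1, 1]
  expect_equal(g(100), 4)   # 88-139 medium-high
  expect_equal(g(0), 1)     # below the first bound
  expect_equal(g(250), 6)   # 230-271 very high
  expect_equal(g(1000), 6)  # beyond the printed maximum
  # exhaustive bin edges and midpoints
  for (k in seq_len(nrow(tri))) {
    expect_equal(g(tri$lower[k]), tri$resistance[k])
    expect_equal(g((tri$lower[k] + tri$upper[k]) / 2), tri$resistance[k])
  }
  # nodata propagates
  expect_true(is.na(classify_continuous(
    grid_create(matrix(NA_real_, 1, 1), 150), tri)$values[1, 1]))
})

test_that("landcover classification follows the stand-age rules", {
  lv <- landcover_levels()
  lc <- grid_create(matrix(lv[["mature_forest"]], 1, 3), 150,
                    levels = names(lv))
  age <- grid_create(matrix(c(80, 40, 5), 1, 3), 150)
  out <- classify_landcover(lc, age)
  expect_equal(as.vector(out$values), c(1, 3, 1))

  snow <- grid_create(matrix(lv[["snow_ice"]], 1, 1), 150,
                      levels = names(lv))
  expect_equal(classify_landcover(snow)$values[1, 1], 6)
  water <- grid_create(matrix(lv[["water"]], 1, 1), 150,
                       levels = names(lv))
  expect_true(is.na(classify_landcover(water)$values[1, 1]))
  bad <- grid_create(matrix(99, 1, 1), 150)
  expect_error(classify_landcover(bad), "99")
})

test_that("distance to shore is the exact Euclidean transform", {
  # cardinal and diagonal adjacency at 150 m cells
  land <- matrix(FALSE, 3, 3); land[1, 1] <- TRUE
  mask <- grid_create(land * 1, 150)
  d <- distance_to_shore(mask)
  expect_equal(d$values[1, 2], 150)
  expect_equal(d$values[2, 2], 150 * sqrt(2))
  expect_equal(d$values[1, 1], 0)

  # random 20x20 mask against the brute-force oracle
  land2 <- withr::with_seed(21, matrix(runif(400) < 0.3, 20, 20))
  land2[5, 5] <- TRUE
  d2 <- distance_to_shore(grid_create(land2 * 1, 150))
  expect_equal(d2$values, oracle_distance_to_land(land2, 150),
               tolerance = 1e-12)

  expect_error(distance_to_shore(grid_create(matrix(0, 3, 3), 150)),
               "no land")
})

test_that("water classification uses the published distance bands", {
  dist <- grid_create(matrix(c(500, 2000, 10000, 0), 1, 4), 150)
  mask <- grid_create(matrix(c(0, 0, 0, 1), 1, 4), 150)
  out <- classify_water(dist, mask)
  expect_equal(as.vector(out$values)[1:3], c(3, 5, 6))
  expect_true(is.na(out$values[1, 4]))  # land is nodata on this layer
})

test_that("cumulative surface rescales to 1-10 and is order-invariant", {
  tri <- grid_create(matrix(c(1, 2, 3, 4), 2, 2), 150)
  lc <- grid_create(matrix(c(1, NA, 3, NA), 2, 2), 150)
  wa <- grid_create(matrix(c(NA, 6, NA, 5), 2, 2), 150)
  cum <- combine_layers(tri, lc, wa)
  expect_equal(min(cum$values), 1)
  expect_equal(max(cum$values), 10)
  # monotone in the raw sum: raw = 2, 8, 6, 9 -> ranks preserved
  raw <- c(2, 8, 6, 9)
  expect_equal(order(as.vector(cum$values)), order(raw))

  # uniform landscape degenerates to 1
  uni <- combine_layers(grid_create(matrix(1, 2, 2), 150),
                        grid_create(matrix(c(2, 2, NA, NA), 2, 2), 150),
                        grid_create(matrix(c(NA, NA, 2, 2), 2, 2), 150))
  expect_true(all(uni$values == 1))

  # overlapping domains are rejected
  expect_error(combine_layers(tri, grid_create(matrix(1, 2, 2), 150),
                              grid_create(matrix(1, 2, 2), 150)),
               "exclusive")
})

test_that("study-area clipping honours the buffer distance", {
  g <- grid_create(matrix(1, 40, 40), 150)  # 6 km square
  # boundary: 1.5 km square in the middle
  poly <- cbind(c(2250, 3750, 3750, 2250), c(2250, 2250, 3750, 3750))
  clipped <- clip_with_buffer(g, poly, buffer_m = 1000)
  ok <- !is.na(clipped$values)
  # every kept centre is within 1000 m of the polygon (oracle re-check)
  nr <- nrow(clipped$values); nc <- ncol(clipped$values)
  rc <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  ctr <- cell_centre(clipped, rc[, 1], rc[, 2])
  d <- bearcircuit:::point_polygon_distance(ctr[, 1], ctr[, 2], poly)
  expect_true(all((d <= 1000) == as.vector(ok)))
  # a cell 9.9 km outside survives a 10 km buffer; one 10.1 km out does not
  big <- grid_create(matrix(1, 1, 3), 100, xmin = 0)
  # centres at x = 50, 150, 250 m; polygon edge at x = 10150
  poly2 <- cbind(c(10150, 10250, 10250, 10150), c(0, 0, 100, 100))
  cl2 <- clip_with_buffer(big, poly2, buffer_m = 10000)
  expect_equal(sum(!is.na(cl2$values)), 2)   # 9900 and 10000 m kept
  expect_error(clip_with_buffer(big, poly2, buffer_m = 100), "no cell")
  # valid cells never increase under clipping
  expect_lte(sum(!is.na(clipped$values)), sum(!is.na(g$values)))
})
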
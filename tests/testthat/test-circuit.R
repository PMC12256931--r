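test_that("raster edges follow the mean-resistance and diagonal rules", {
  v <- matrix(c(2, 4, 6, 8), 2, 2)
  g <- build_graph(grid_create(v, 150))
  e <- g$edges
  find_edge <- function(a, b) {
    k <- which((e$i == a & e$j == b) | (e$i == b & e$j == a))
    e$resistance[k]
  }
  n_of <- function(r, c) g$node_of[(c - 1L) * 2L + r]
  # cardinal neighbours with r = 2 and 4 -> edge resistance 3
  expect_equal(find_edge(n_of(1, 1), n_of(2, 1)), 3)
  # diagonal neighbours r = 2 and 8 -> 5 * sqrt(2)
  expect_equal(find_edge(n_of(1, 1), n_of(2, 2)), 5 * sqrt(2))

  # interior degree 8, corner degree 3
  full <- build_graph(grid_create(matrix(1, 3, 3), 1))
  deg <- tabulate(c(full$edges$i, full$edges$j), full$n)
  ctr <- full$node_of[(2 - 1) * 3 + 2]
  crn <- full$node_of[1]
  expect_equal(deg[ctr], 8)
  expect_equal(deg[crn], 3)

  expect_error(build_graph(grid_create(matrix(c(1, NA), 1, 2), 1)),
               "2 valid cells")
})

test_that("Ohm, series and parallel laws hold on hand-built circuits", {
  two <- graph_from_edges(2, 1, 2, 5)
  sp <- solve_pair(two, 1, 2)
  expect_equal(sp$R_eff, 5)
  expect_equal(abs(sp$branch_currents$current), 1)

  chain <- graph_from_edges(3, c(1, 2), c(2, 3), c(2, 3))
  expect_equal(solve_pair(chain, 1, 3)$R_eff, 5)

  par2 <- graph_from_edges(2, c(1, 1), c(2, 2), c(2, 3))
  expect_equal(solve_pair(par2, 1, 2)$R_eff, 1 / (1 / 2 + 1 / 3))
})

test_that("effective resistance matches the dense pseudo-inverse oracle", {
  reps <- withr::with_seed(1234, replicate(60, {
    n <- sample(10:120, 1)
    g <- random_connected_graph(n)
    st <- sample(n, 2)
    ours <- solve_pair(g, st[1], st[2])$R_eff
    oracle <- oracle_R_eff(g, st[1], st[2])
    abs(ours - oracle) / oracle
  }))
  expect_lt(max(reps), 1e-8)
})

test_that("Kirchhoff conservation holds at every non-focal node", {
  g <- withr::with_seed(77, random_connected_graph(80))
  sp <- solve_pair(g, 1, 40)
  net <- numeric(g$n)
  cur <- sp$branch_currents$current
  for (k in seq_len(nrow(g$edges))) {
    net[g$edges$i[k]] <- net[g$edges$i[k]] - cur[k]
    net[g$edges$j[k]] <- net[g$edges$j[k]] + cur[k]
  }
  expect_lt(max(abs(net[-c(1, 40)])), 1e-9)
  # source/target carry the unit injection
  expect_equal(net[1], -1, tolerance = 1e-9)
  expect_equal(net[40], 1, tolerance = 1e-9)
})

test_that("reciprocity: swapping source and target changes nothing observable", {
  g <- withr::with_seed(5, random_connected_graph(40))
  a <- solve_pair(g, 3, 17)
  b <- solve_pair(g, 17, 3)
  expect_equal(a$R_eff, b$R_eff, tolerance = 1e-12)
  expect_equal(a$node_currents, b$node_currents, tolerance = 1e-9)
})

test_that("Rayleigh monotonicity and parallel-path conductance gain", {
  g <- withr::with_seed(9, random_connected_graph(30))
  base <- solve_pair(g, 2, 25)$R_eff
  worse <- withr::with_seed(10, vapply(1:100, function(k) {
    g2 <- g
    e <- sample(nrow(g2$edges), 1)
    g2$edges$resistance[e] <- g2$edges$resistance[e] * runif(1, 1, 5)
    solve_pair(g2, 2, 25)$R_eff
  }, 0))
  expect_true(all(worse >= base - 1e-12))

  # adding a parallel path strictly increases conductance
  path1 <- graph_from_edges(3, c(1, 2), c(2, 3), c(1, 1))
  g1 <- 1 / solve_pair(path1, 1, 3)$R_eff
  path2 <- graph_from_edges(4, c(1, 2, 1, 4), c(2, 3, 4, 3), c(1, 1, 2, 2))
  g2 <- 1 / solve_pair(path2, 1, 3)$R_eff
  expect_gt(g2, g1)
})

test_that("pairwise solve fills matrices, accumulates current, scales linearly", {
  v <- withr::with_seed(31, matrix(runif(100, 1, 10), 10, 10))
  grid <- grid_create(v, 150)
  g <- build_graph(grid)
  nodes <- focal_node_set(c("a", "b", "c", "d"),
                          x = c(75, 1425, 75, 1425),
                          y = c(75, 75, 1425, 1425))
  nodes <- snap_to_grid(nodes, grid)
  res <- pairwise_all(g, nodes)
  expect_equal(res$n_pairs, 6)
  expect_true(isSymmetric(res$R_eff))
  expect_true(all(res$R_eff[upper.tri(res$R_eff)] > 0))
  expect_equal(res$G_eff[1, 2], 1 / res$R_eff[1, 2])

  # cumulative current bounded by the number of pairs, non-negative
  cc <- res$cumulative_current$values
  expect_true(all(cc >= 0))
  expect_true(all(cc <= res$n_pairs + 1e-9))

  # doubling all resistances doubles R, halves G, leaves current unchanged
  g2 <- g; g2$edges$resistance <- g2$edges$resistance * 2
  res2 <- pairwise_all(g2, nodes)
  expect_equal(res2$R_eff, 2 * res$R_eff, tolerance = 1e-9)
  expect_equal(res2$G_eff, res$G_eff / 2, tolerance = 1e-9)
  expect_equal(res2$cumulative_current$values, cc, tolerance = 1e-9)
})

test_that("disconnected pairs are data, not failures", {
  # two 2-cell islands separated by a nodata channel
  v <- matrix(c(1, 1, NA, NA, 1, 1), 2, 3)
  grid <- grid_create(v, 150)
  g <- build_graph(grid)
  left <- c(1, 1); right <- c(1, 3)
  sp <- solve_pair(g, left, right)
  expect_true(is.infinite(sp$R_eff))
  nodes <- snap_to_grid(
    focal_node_set(c("L", "R"),
                   x = c(cell_centre(grid, 1, 1)[1], cell_centre(grid, 1, 3)[1]),
                   y = c(cell_centre(grid, 1, 1)[2], cell_centre(grid, 1, 3)[2])),
    grid)
  res <- pairwise_all(g, nodes)
  expect_true(is.infinite(res$R_eff["L", "R"]))
  expect_equal(res$G_eff["L", "R"], 0)
  expect_equal(effective_conductance(matrix(c(0, 5, 5, 0), 2, 2))[1, 2], 0.2)
})
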
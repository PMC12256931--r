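# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: dense pseudo-inverse for effective
# resistance, exhaustive enumeration for least-cost paths, brute force for
# the distance transform, and generic numeric optimization for the Firth
# likelihood.

# Build a resistance_graph by hand from an explicit edge list (bypasses the
# raster topology builder so hand-built circuits can be tested directly).
graph_from_edges <- function(n, i, j, resistance) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(i, j))
  structure(list(
    n = n, cell = seq_len(n), row = rep(1L, n), col = seq_len(n),
    node_of = seq_len(n),
    edges = tibble::tibble(i = i, j = j, resistance = resistance),
    component = igraph::components(g)$membership,
    nrow = 1L, ncol = n, cell_size = 1, xmin = 0, ymax = 1
  ), class = "resistance_graph")
}

# Random connected graph: spanning tree plus extra edges, positive random
# resistances.
random_connected_graph <- function(n, extra = n) {
  perm <- sample(n)
  ti <- perm[-1]
  tj <- perm[vapply(2:n, function(k) sample(k - 1L, 1L), 0L)]
  more <- matrix(replicate(extra, sample(n, 2L)), nrow = 2L)
  i <- c(ti, more[1L, ]); j <- c(tj, more[2L, ])
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  graph_from_edges(n, i, j, stats::runif(length(i), 0.1, 10))
}

# Dense-oracle effective resistance: R_st = L+_ss + L+_tt - 2 L+_st with the
# Moore-Penrose pseudo-inverse of the conductance Laplacian.
oracle_R_eff <- function(graph, s, t) {
  n <- graph$n
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    c_ij <- 1 / graph$edges$resistance[k]
    L[i, j] <- L[i, j] - c_ij; L[j, i] <- L[j, i] - c_ij
    L[i, i] <- L[i, i] + c_ij; L[j, j] <- L[j, j] + c_ij
  }
  Lp <- MASS::ginv(L)
  Lp[s, s] + Lp[t, t] - 2 * Lp[s, t]
}

# Exhaustive least-cost oracle: minimum accumulated cost over all simple
# paths between two nodes of a cost graph (depth-first enumeration).
oracle_lcp_cost <- function(cost_graph, s, t) {
  n <- cost_graph$n
  adj <- vector("list", n)
  e <- cost_graph$edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- rbind(adj[[e$i[k]]], c(e$j[k], e$cost[k]))
    adj[[e$j[k]]] <- rbind(adj[[e$j[k]]], c(e$i[k], e$cost[k]))
  }
  best <- Inf
  visited <- rep(FALSE, n)
  dfs <- function(v, acc) {
    if (acc >= best) return(invisible())
    if (v == t) { best <<- acc; return(invisible()) }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (r in seq_len(NROW(nb))) {
      u <- nb[r, 1L]
      if (!visited[u]) dfs(u, acc + nb[r, 2L])
    }
    visited[v] <<- FALSE
  }
  dfs(s, 0)
  best
}

# Brute-force distance transform oracle: all-pairs minimum distance from
# each FALSE cell to the nearest TRUE cell, in metres.
oracle_distance_to_land <- function(land, cell_size) {
  nr <- nrow(land); nc <- ncol(land)
  li <- which(land, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (land[r, c]) next
    out[r, c] <- sqrt(min((li[, 1] - r)^2 + (li[, 2] - c)^2)) * cell_size
  }
  out
}

# Independent penalized log-likelihood for the Firth model (rewritten from
# the definition, not shared with package internals).
oracle_firth_pll <- function(beta, y, X) {
  eta <- X %*% beta
  p <- 1 / (1 + exp(-eta))
  W <- as.numeric(p * (1 - p))
  I <- t(X) %*% (X * W)
  sum(y * eta - log(1 + exp(eta))) + 0.5 * log(det(I))
}

# Small raster cost graph with random positive costs, for LCP tests.
random_cost_grid <- function(nr, nc, cell_size = 1) {
  cur <- matrix(stats::runif(nr * nc, 0.2, 5), nr, nc)
  current_to_cost(grid_create(cur, cell_size), epsilon = 0)
}

# Tiny landscape config used across tests (fast but non-trivial).
test_config <- function(seed = 42, ...) {
  landscape_config(extent_m = c(6000, 6000), cell_size_m = 150,
                   seed = seed, ...)
}
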
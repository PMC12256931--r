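#' Build the raster resistor network
#'
#' Every valid (non-nodata) cell becomes a node; each cell connects to its
#' eight immediate neighbours (cardinal and diagonal). The resistor between
#' neighbouring cells i and j carries resistance `(r_i + r_j) / 2`,
#' multiplied by `sqrt(2)` for diagonal neighbours to account for the longer
#' hop - the standard raster circuit convention.
#'
#' @param resistance cumulative-resistance `bc_grid` (values > 0 on valid
#'   cells).
#' @return A `resistance_graph`: node/cell lookup tables, an edge tibble
#'   `(i, j, resistance)`, connected-component labels, and the source grid's
#'   georeferencing.
#' @export
build_graph <- function(resistance) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- which(!is.na(v))                 # linear (column-major) indices
  if (length(valid) < 2L) stop("need at least 2 valid cells")
  if (any(v[valid] <= 0)) stop("resistance values must be positive")
  node_of <- rep(NA_integer_, nr * nc)
  node_of[valid] <- seq_along(valid)

  # neighbour offsets: E, S, SE, SW (each undirected edge built once)
  offs <- list(c(0L, 1L, FALSE), c(1L, 0L, FALSE),
               c(1L, 1L, TRUE), c(1L, -1L, TRUE))
  rows_v <- (valid - 1L) %% nr + 1L
  cols_v <- (valid - 1L) %/% nr + 1L
  ii <- integer(0); jj <- integer(0); rr <- numeric(0)
  for (o in offs) {
    r2 <- rows_v + o[[1L]]; c2 <- cols_v + o[[2L]]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    j2 <- node_of[lin2]
    keep <- !is.na(j2)
    i1 <- node_of[valid[ok]][keep]; j1 <- j2[keep]
    res <- (v[valid[ok]][keep] + v[lin2][keep]) / 2
    if (o[[3L]]) res <- res * sqrt(2)
    ii <- c(ii, i1); jj <- c(jj, j1); rr <- c(rr, res)
  }

  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(valid) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  structure(list(
    n = length(valid),
    cell = valid, row = rows_v, col = cols_v,
    node_of = node_of,
    edges = tibble::tibble(i = ii, j = jj, resistance = rr),
    component = comp,
    nrow = nr, ncol = nc,
    cell_size = resistance$cell_size,
    xmin = resistance$xmin, ymax = resistance$ymax
  ), class = "resistance_graph")
}

# Sparse conductance Laplacian of a resistance_graph.
graph_laplacian <- function(graph) {
  e <- graph$edges
  cond <- 1 / e$resistance
  n <- graph$n
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(cond, cond), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

#' Solve the circuit for one focal-node pair
#'
#' Injects `injection` amperes at `source` and extracts it at `target`
#' (Laplacian linear system `L v = b`, one node grounded), then reads off
#' node potentials, branch currents (conductance times potential drop),
#' per-cell node currents (half the sum of absolute incident branch
#' currents, with source and target fixed at the injection), and the
#' effective resistance `R = (v_source - v_target) / injection`.
#'
#' @param graph a `resistance_graph`.
#' @param source,target node indices (1..n) or focal-node rows/cols given as
#'   `c(row, col)`.
#' @param injection injected current (default 1).
#' @return List with `potentials`, `branch_currents` (edge tibble plus
#'   `current`), `node_currents`, `R_eff`; for a disconnected pair,
#'   `R_eff = Inf` and currents are zero.
#' @export
solve_pair <- function(graph, source, target, injection = 1) {
  s <- resolve_node(graph, source); t <- resolve_node(graph, target)
  if (s == t) stop("source and target must differ")
  if (graph$component[s] != graph$component[t]) {
    return(list(potentials = rep(NA_real_, graph$n),
                branch_currents = transform(graph$edges, current = 0),
                node_currents = rep(0, graph$n), R_eff = Inf))
  }
  sol <- solve_component(graph, graph$component[s])
  v <- sol$solve_rhs(s, t) * injection
  pair_currents(graph, v, s, t, injection)
}

# Map c(row, col) or a plain node index to the node index.
resolve_node <- function(graph, node) {
  if (length(node) == 2L) {
    lin <- (node[2L] - 1L) * graph$nrow + node[1L]
    id <- graph$node_of[lin]
    if (is.na(id)) stop("cell (", node[1L], ",", node[2L], ") is nodata")
    return(id)
  }
  as.integer(node)
}

# Factor the Laplacian of one component once (grounding its last node) and
# return a closure solving L v = e_s - e_t for full-graph potentials.
solve_component <- function(graph, comp_id) {
  members <- which(graph$component == comp_id)
  n_c <- length(members)
  local <- rep(NA_integer_, graph$n)
  local[members] <- seq_len(n_c)
  L <- graph_laplacian(graph)[members, members, drop = FALSE]
  ground <- n_c                      # ground the last node of the component
  Lr <- L[-ground, -ground, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE)
  solve_rhs <- function(s, t) {
    ls <- local[s]; lt <- local[t]
    b <- numeric(n_c)
    b[ls] <- b[ls] + 1; b[lt] <- b[lt] - 1
    x <- as.numeric(Matrix::solve(ch, b[-ground]))
    v_local <- append(x, 0, after = ground - 1L)
    v <- rep(NA_real_, graph$n)
    v[members] <- v_local
    v
  }
  list(members = members, solve_rhs = solve_rhs)
}

# Branch/node currents and effective resistance from a potential vector.
pair_currents <- function(graph, v, s, t, injection = 1) {
  e <- graph$edges
  drop <- v[e$i] - v[e$j]
  drop[is.na(drop)] <- 0
  cur <- drop / e$resistance
  node_cur <- numeric(graph$n)
  acur <- abs(cur)
  agg_i <- rowsum(acur, e$i)
  agg_j <- rowsum(acur, e$j)
  node_cur[as.integer(rownames(agg_i))] <- agg_i[, 1L]
  node_cur[as.integer(rownames(agg_j))] <-
    node_cur[as.integer(rownames(agg_j))] + agg_j[, 1L]
  node_cur <- node_cur / 2
  node_cur[c(s, t)] <- injection
  bc <- e
  bc$current <- cur
  list(potentials = v, branch_currents = bc, node_currents = node_cur,
       R_eff = (v[s] - v[t]) / injection)
}

#' Pairwise circuit solve over a focal node set
#'
#' Solves the circuit for every unordered pair of focal nodes (one sparse
#' Cholesky factorization per connected component, reused across pairs),
#' accumulating the per-pair node-current maps into a cumulative current
#' grid and filling the symmetric effective-resistance and
#' effective-conductance matrices. Pairs in different components get
#' `R = Inf`, `G = 0`, and contribute no current.
#'
#' @param graph a `resistance_graph`.
#' @param nodes a snapped `focal_nodes` tibble (valid `row`/`col`).
#' @param keep_pair_maps retain each pair's node-current grid (memory-heavy;
#'   default FALSE).
#' @return A `circuit_result`: `R_eff` and `G_eff` matrices (node ids as
#'   dimnames), `cumulative_current` `bc_grid`, `n_pairs`, and optionally
#'   `pair_maps`.
#' @export
pairwise_all <- function(graph, nodes, keep_pair_maps = FALSE) {
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 focal nodes")
  node_idx <- vapply(seq_len(n), function(k) {
    lin <- (nodes$col[k] - 1L) * graph$nrow + nodes$row[k]
    id <- graph$node_of[lin]
    if (is.na(id)) stop("focal node ", nodes$node_id[k],
                        " sits on a nodata cell; snap nodes first")
    id
  }, 0L)

  R <- matrix(0, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  cum <- numeric(graph$n)
  pair_maps <- if (keep_pair_maps) list() else NULL
  factors <- list()
  pairs <- utils::combn(n, 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    s <- node_idx[a]; t <- node_idx[b]
    if (graph$component[s] != graph$component[t]) {
      R[a, b] <- R[b, a] <- Inf
      next
    }
    key <- as.character(graph$component[s])
    if (is.null(factors[[key]]))
      factors[[key]] <- solve_component(graph, graph$component[s])
    v <- factors[[key]]$solve_rhs(s, t)
    pc <- pair_currents(graph, v, s, t)
    R[a, b] <- R[b, a] <- pc$R_eff
    cum <- cum + pc$node_currents
    if (keep_pair_maps)
      pair_maps[[paste(nodes$node_id[a], nodes$node_id[b], sep = "|")]] <-
        pc$node_currents
  }

  cur <- matrix(NA_real_, graph$nrow, graph$ncol)
  cur[graph$cell] <- cum
  structure(list(
    R_eff = R,
    G_eff = conductance_from_resistance(R),
    cumulative_current = grid_create(cur, graph$cell_size, graph$xmin,
                                     graph$ymax),
    node_idx = node_idx, n_pairs = ncol(pairs),
    pair_maps = pair_maps
  ), class = "circuit_result")
}

conductance_from_resistance <- function(R) {
  G <- 1 / R
  G[is.infinite(R)] <- 0        # disconnected pairs conduct nothing
  diag(G) <- NA_real_
  G
}

#' Effective conductance matrix
#'
#' `G = 1 / R` elementwise; disconnected pairs (infinite resistance) get 0;
#' the diagonal is undefined (NA).
#'
#' @param result a `circuit_result` from [pairwise_all()], or a resistance
#'   matrix.
#' @return Symmetric conductance matrix.
#' @export
effective_conductance <- function(result) {
  R <- if (inherits(result, "circuit_result")) result$R_eff else result
  conductance_from_resistance(R)
}
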
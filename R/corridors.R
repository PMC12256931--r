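#' Convert a cumulative current map to a traversal-cost graph
#'
#' Cells with high current are cheap to traverse: per-cell conductance is
#' `current + epsilon` (the floor keeps zero-current cells traversable at
#' high cost), and the cost of stepping between neighbouring cells is the
#' inter-centre distance divided by the mean conductance of the two cells.
#' Doubling the current halves every cost.
#'
#' @param current cumulative-current `bc_grid` (values >= 0).
#' @param epsilon conductance floor; default `1e-6 * max(current)`.
#' @return A `cost_graph` with the same topology as [build_graph()] but an
#'   edge `cost` column.
#' @export
current_to_cost <- function(current, epsilon = NULL) {
  v <- current$values
  ok <- !is.na(v)
  if (!any(ok) || max(v[ok]) <= 0) stop("current map is all zero")
  if (any(v[ok] < 0)) stop("current must be non-negative")
  eps <- epsilon %||% (1e-6 * max(v[ok]))
  cond <- v + eps
  # reuse the resistor-network topology builder on the conductance grid
  g <- build_graph(grid_create(cond, current$cell_size, current$xmin,
                               current$ymax))
  e <- g$edges
  diag_edge <- abs(g$row[e$i] - g$row[e$j]) == 1L &
    abs(g$col[e$i] - g$col[e$j]) == 1L
  d <- ifelse(diag_edge, sqrt(2), 1) * current$cell_size
  mean_cond <- (cond[g$cell[e$i]] + cond[g$cell[e$j]]) / 2
  g$edges$cost <- d / mean_cond
  g$edges$resistance <- NULL
  class(g) <- c("cost_graph", class(g))
  g
}

#' From-everywhere-to-everywhere least-cost paths
#'
#' One least-cost (Dijkstra) path per unordered focal-node pair over the
#' cost graph, with the accumulated cost and metric arc length of each path.
#' Costs are symmetric, so one undirected path serves both directions.
#'
#' @param cost a `cost_graph` from [current_to_cost()].
#' @param nodes a snapped `focal_nodes` tibble.
#' @return A `path_set` tibble: pair_id, node_a, node_b, accumulated_cost,
#'   length_m, cells (list of node-index vectors), coords (list of
#'   coordinate matrices). Disconnected pairs are omitted and listed in the
#'   `omitted` attribute.
#' @export
fete_lcps <- function(cost, nodes) {
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 focal nodes")
  node_idx <- vapply(seq_len(n), function(k) {
    lin <- (nodes$col[k] - 1L) * cost$nrow + nodes$row[k]
    id <- cost$node_of[lin]
    if (is.na(id)) stop("focal node ", nodes$node_id[k], " sits on nodata")
    id
  }, 0L)
  g <- igraph::make_empty_graph(n = cost$n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(cost$edges$i, cost$edges$j))
  igraph::E(g)$weight <- cost$edges$cost

  rows <- list(); omitted <- list()
  for (a in seq_len(n - 1L)) {
    to <- node_idx[(a + 1L):n]
    sp <- igraph::shortest_paths(g, from = node_idx[a], to = to,
                                 mode = "all", output = "vpath")
    dd <- igraph::distances(g, v = node_idx[a], to = to, mode = "all")
    for (k in seq_along(to)) {
      b <- a + k
      if (is.infinite(dd[1L, k])) {
        omitted[[length(omitted) + 1L]] <-
          tibble::tibble(node_a = nodes$node_id[a], node_b = nodes$node_id[b])
        next
      }
      cells <- as.integer(sp$vpath[[k]])
      coords <- cbind(
        x = cost$xmin + (cost$col[cells] - 0.5) * cost$cell_size,
        y = cost$ymax - (cost$row[cells] - 0.5) * cost$cell_size
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair_id = paste(nodes$node_id[a], nodes$node_id[b], sep = "|"),
        node_a = nodes$node_id[a], node_b = nodes$node_id[b],
        accumulated_cost = dd[1L, k],
        length_m = polyline_length(coords),
        cells = list(cells), coords = list(coords)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pair_id = character(), node_a = character(),
                   node_b = character(), accumulated_cost = numeric(),
                   length_m = numeric(), cells = list(), coords = list())
  class(out) <- c("path_set", class(out))
  attr(out, "omitted") <- if (length(omitted)) dplyr::bind_rows(omitted) else NULL
  out
}

#' Rank least-cost paths and keep the top fraction
#'
#' Keeps the `ceiling(fraction * n)` paths with the smallest accumulated
#' cost (ties broken by pair id), attaching a `rank` column. The published
#' analysis keeps the top 5%: 9045 paths yield 453.
#'
#' @param paths a `path_set`.
#' @param fraction fraction in (0, 1] (default 0.05).
#' @return The top paths, ranked.
#' @export
rank_paths <- function(paths, fraction = 0.05) {
  if (!nrow(paths)) stop("empty path set")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  keep <- ceiling(fraction * nrow(paths))
  ord <- order(paths$accumulated_cost, paths$pair_id)
  out <- paths[ord[seq_len(keep)], ]
  out$rank <- seq_len(keep)
  out
}

#' Buffer top paths into candidate corridors
#'
#' Sweeps a disc of radius `width_m / 2` along each path (total corridor
#' width `width_m`) and dissolves overlaps, rasterizing the union on a fine
#' analysis grid. Returns the corridor mask and its dissolved area.
#'
#' @param paths a `path_set` (typically from [rank_paths()]).
#' @param width_m total corridor width in metres (default 1200).
#' @param resolution analysis cell size for the rasterized union (default
#'   `width_m / 40`).
#' @return List: `mask` (`bc_grid`, 1 inside a corridor), `area_m2`
#'   (dissolved), `width_m`.
#' @export
buffer_corridors <- function(paths, width_m = 1200, resolution = NULL) {
  if (width_m < 0) stop("`width_m` must be >= 0")
  if (!nrow(paths) || width_m == 0)
    return(list(mask = NULL, area_m2 = 0, width_m = width_m))
  r <- width_m / 2
  res <- resolution %||% (width_m / 40)
  all_xy <- do.call(rbind, paths$coords)
  xr <- range(all_xy[, 1]) + c(-r - res, r + res)
  yr <- range(all_xy[, 2]) + c(-r - res, r + res)
  nc <- ceiling(diff(xr) / res); nr <- ceiling(diff(yr) / res)
  cx <- xr[1] + (seq_len(nc) - 0.5) * res
  cy <- yr[2] - (seq_len(nr) - 0.5) * res
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  dmin <- matrix(Inf, nr, nc)
  for (p in paths$coords) {
    if (nrow(p) == 1L) {
      dmin <- pmin(dmin, sqrt((X - p[1, 1])^2 + (Y - p[1, 2])^2))
      next
    }
    for (s in seq_len(nrow(p) - 1L)) {
      dmin <- pmin(dmin, point_segment_distance(X, Y, p[s, 1], p[s, 2],
                                                p[s + 1L, 1], p[s + 1L, 2]))
    }
  }
  inside <- dmin <= r
  mask <- grid_create((inside) * 1, res, xmin = xr[1], ymax = yr[2])
  list(mask = mask, area_m2 = sum(inside) * res^2, width_m = width_m)
}

#' Path length inside and outside protected areas
#'
#' Splits every path segment at its crossings with the protected-area
#' polygon edges and attributes each piece by a point-in-polygon test,
#' reporting per-path and total lengths and the fraction of accumulated
#' path length outside protection.
#'
#' @param paths a `path_set`.
#' @param protected list of polygon rings (two-column vertex matrices); an
#'   empty list means nothing is protected.
#' @return List: `per_path` tibble (pair_id, length_m, inside_m, outside_m),
#'   `total_length_m`, `outside_length_m`, `fraction_outside`.
#' @export
overlap_with_polygons <- function(paths, protected) {
  if (is.matrix(protected)) protected <- list(protected)
  per <- lapply(seq_len(nrow(paths)), function(k) {
    p <- paths$coords[[k]]
    inside <- 0
    if (length(protected) && nrow(p) >= 2L) {
      for (s in seq_len(nrow(p) - 1L)) {
        inside <- inside + segment_length_inside(p[s, ], p[s + 1L, ],
                                                 protected)
      }
    }
    len <- polyline_length(p)
    tibble::tibble(pair_id = paths$pair_id[k], length_m = len,
                   inside_m = inside, outside_m = len - inside)
  })
  per <- dplyr::bind_rows(per)
  tot <- sum(per$length_m)
  outl <- sum(per$outside_m)
  list(per_path = per, total_length_m = tot, outside_length_m = outl,
       fraction_outside = if (tot > 0) outl / tot else NA_real_)
}
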
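#' Focal node sets
#'
#' Labelled points between which connectivity is computed: salmon-reach
#' midpoints or hair-snag sites. Stored as a tibble with one row per node;
#' `member_ids` records original ids folded into a node by merging or
#' snapping.
#'
#' @param node_id unique node identifiers.
#' @param x,y coordinates (m).
#' @param source `"reach_midpoint"` or `"snag_site"`.
#' @param watershed_code,species optional labels carried from reaches.
#' @param row,col optional grid cell indices (filled by [snap_to_grid()]).
#' @param member_ids optional list of original ids per node.
#' @return A `focal_nodes` tibble.
#' @export
focal_node_set <- function(node_id, x, y, source = "reach_midpoint",
                           watershed_code = NA_character_,
                           species = NA_character_,
                           row = NA_integer_, col = NA_integer_,
                           member_ids = NULL) {
  if (anyDuplicated(node_id)) stop("node ids must be unique")
  out <- tibble::tibble(
    node_id = as.character(node_id), x = x, y = y, source = source,
    watershed_code = watershed_code, species = species,
    row = as.integer(row), col = as.integer(col),
    member_ids = member_ids %||% as.list(as.character(node_id))
  )
  class(out) <- c("focal_nodes", class(out))
  out
}

#' Midpoint of a species' reaches along a stream
#'
#' Concatenates the reach parts in the order given (downstream to upstream),
#' and returns the point at half the total arc length; the midpoint always
#' lies on one of the reaches. With a single reach this is its arc-length
#' centre.
#'
#' @param reaches list of two-column coordinate matrices (the reach parts,
#'   ordered downstream to upstream), or a single matrix.
#' @return Length-2 numeric vector (x, y).
#' @export
reach_midpoint <- function(reaches) {
  if (is.matrix(reaches)) reaches <- list(reaches)
  if (!length(reaches)) stop("no reach geometry supplied")
  lens <- vapply(reaches, polyline_length, 0)
  total <- sum(lens)
  if (total <= 0) stop("reach geometry has zero length")
  half <- total / 2
  cum <- 0
  for (i in seq_along(reaches)) {
    if (half <= cum + lens[i] + 1e-12) {
      p <- point_at_arclength(reaches[[i]], half - cum)
      return(stats::setNames(as.numeric(p), c("x", "y")))
    }
    cum <- cum + lens[i]
  }
  p <- point_at_arclength(reaches[[length(reaches)]], lens[length(lens)])
  stats::setNames(as.numeric(p), c("x", "y"))
}

#' Derive focal nodes from a stream network
#'
#' One candidate node per (watershed, species): the arc-length midpoint of
#' all reaches of that species on that stream (parts ordered downstream to
#' upstream as generated).
#'
#' @param network a `stream_network` from [generate_hydrology()].
#' @return A `focal_nodes` tibble (unmerged, unsnapped).
#' @export
reach_midpoints <- function(network) {
  reaches <- network$reaches
  if (!nrow(reaches)) stop("stream network has no reaches")
  key <- paste(reaches$watershed_code, reaches$species, sep = "|")
  groups <- split(seq_len(nrow(reaches)), key)
  pts <- t(vapply(groups, function(idx) {
    reach_midpoint(reaches$geometry[idx])
  }, c(x = 0, y = 0)))
  ids <- names(groups)
  parts <- strsplit(ids, "|", fixed = TRUE)
  focal_node_set(
    node_id = sprintf("N%03d", seq_along(groups)),
    x = pts[, 1], y = pts[, 2], source = "reach_midpoint",
    watershed_code = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L)
  )
}

#' Merge nodes within a radius into mean centres
#'
#' Nodes within `radius_m` of one another are grouped by single-linkage
#' connected components and each component is replaced by its unweighted
#' mean centre. Merging is repeated until stable, so the result is
#' idempotent and independent of input order.
#'
#' @param nodes a `focal_nodes` tibble.
#' @param radius_m merge radius in metres (default 150, the resistance-cell
#'   resolution).
#' @return A merged `focal_nodes` tibble.
#' @export
merge_nodes <- function(nodes, radius_m = 150) {
  if (radius_m < 0) stop("`radius_m` must be >= 0")
  repeat {
    n <- nrow(nodes)
    if (n <= 1L) return(nodes)
    d <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
    adj <- d <= radius_m
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    if (max(comp) == n) return(nodes)
    ord <- order(vapply(split(seq_len(n), comp), min, 0L))
    merged <- lapply(split(seq_len(n), comp)[ord], function(idx) {
      first <- function(v) { v <- v[!is.na(v)]; if (length(unique(v)) == 1L) v[1L] else NA_character_ }
      tibble::tibble(
        node_id = nodes$node_id[min(idx)],
        x = mean(nodes$x[idx]), y = mean(nodes$y[idx]),
        source = nodes$source[min(idx)],
        watershed_code = first(nodes$watershed_code[idx]),
        species = first(nodes$species[idx]),
        row = NA_integer_, col = NA_integer_,
        member_ids = list(unlist(nodes$member_ids[idx], use.names = FALSE))
      )
    })
    nodes2 <- dplyr::bind_rows(merged)
    class(nodes2) <- class(nodes)
    if (nrow(nodes2) == nrow(nodes)) return(nodes2)
    nodes <- nodes2
  }
}

#' Snap focal nodes to valid grid cells
#'
#' Assigns each node its containing cell; a node landing on nodata (e.g. a
#' reach mouth snapped into the sea) moves to the nearest valid cell within
#' a 2-cell window. Nodes that end up sharing a cell collapse to one node
#' (member ids retained), since the circuit model cannot distinguish
#' co-located sources.
#'
#' @param nodes a `focal_nodes` tibble.
#' @param grid a `bc_grid` whose NA cells are off-limits.
#' @param max_cells search window radius in cells (default 2).
#' @return A `focal_nodes` tibble with `row`/`col` filled, coordinates moved
#'   to cell centres, one node per cell.
#' @export
snap_to_grid <- function(nodes, grid, max_cells = 2L) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rc <- cell_at_xy(grid, nodes$x, nodes$y)
  rows <- rc[, 1]; cols <- rc[, 2]
  for (i in seq_len(nrow(nodes))) {
    r <- rows[i]; c <- cols[i]
    if (!is.na(r) && !is.na(grid$values[r, c])) next
    # search the window for the nearest valid cell centre
    if (is.na(r)) stop("node ", nodes$node_id[i], " lies outside the grid")
    rr <- max(1L, r - max_cells):min(nr, r + max_cells)
    cc <- max(1L, c - max_cells):min(nc, c + max_cells)
    win <- expand.grid(row = rr, col = cc)
    valid <- !is.na(grid$values[as.matrix(win)])
    if (!any(valid))
      stop("node ", nodes$node_id[i], " is farther than ", max_cells,
           " cells from any valid cell")
    win <- win[valid, , drop = FALSE]
    ctr <- cell_centre(grid, win$row, win$col)
    d <- (ctr[, 1] - nodes$x[i])^2 + (ctr[, 2] - nodes$y[i])^2
    j <- which.min(d)   # ties: first in row-major window order
    rows[i] <- win$row[j]; cols[i] <- win$col[j]
  }
  out <- nodes
  out$row <- as.integer(rows); out$col <- as.integer(cols)
  ctr <- cell_centre(grid, out$row, out$col)
  out$x <- ctr[, 1]; out$y <- ctr[, 2]
  # collapse nodes sharing a cell
  cell <- (out$col - 1L) * nr + out$row
  if (anyDuplicated(cell)) {
    keep <- !duplicated(cell)
    for (dup in which(duplicated(cell))) {
      tgt <- which(cell == cell[dup])[1L]
      out$member_ids[[tgt]] <- unique(c(out$member_ids[[tgt]],
                                        out$member_ids[[dup]]))
    }
    out <- out[keep, ]
  }
  out
}

#' Unordered node pairs with Euclidean distances
#'
#' @param nodes a `focal_nodes` tibble.
#' @return Tibble with columns site_a, site_b (a < b in node order) and
#'   `distance_m`; n(n-1)/2 rows.
#' @export
node_pairs <- function(nodes) {
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 nodes")
  idx <- utils::combn(n, 2L)
  tibble::tibble(
    site_a = nodes$node_id[idx[1L, ]],
    site_b = nodes$node_id[idx[2L, ]],
    distance_m = sqrt((nodes$x[idx[1L, ]] - nodes$x[idx[2L, ]])^2 +
                      (nodes$y[idx[1L, ]] - nodes$y[idx[2L, ]])^2)
  )
}
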
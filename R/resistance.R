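#' Terrain ruggedness index (Riley et al. form)
#'
#' For each cell, the square root of the summed squared elevation
#' differences to its (up to eight) neighbours:
#' `TRI(c) = sqrt(sum_n (z_n - z_c)^2)`. Edge cells use the neighbours that
#' exist; NA neighbours are skipped; water cells participate like any other
#' (flat water contributes zero).
#'
#' @param elevation elevation `bc_grid` in metres, at least 3x3.
#' @return A `bc_grid` of TRI values (NA where elevation is NA).
#' @export
terrain_ruggedness_index <- function(elevation) {
  z <- elevation$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("elevation grid must be at least 3x3")
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    shifted <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    shifted[rs, cs] <- z[rs + dr, cs + dc]
    d2 <- (shifted - z)^2
    d2[is.na(d2)] <- 0
    acc <- acc + d2
  }
  out <- sqrt(acc)
  out[is.na(z)] <- NA_real_
  grid_create(out, elevation$cell_size, elevation$xmin, elevation$ymax)
}

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification minimizing the within-class sum of squared
#' deviations (dynamic programming over sorted values), the criterion behind
#' "Jenks natural breaks". Deterministic.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes (>= 2).
#' @return Numeric vector of `k + 1` ordered breaks: the minimum, the k-1
#'   interior cut points (upper edge of each class), and the maximum.
#' @export
jenks_breaks <- function(values, k) {
  values <- values[is.finite(values)]
  if (k < 2L) stop("`k` must be at least 2")
  ux <- sort(unique(values))
  if (length(ux) < k) stop("need at least `k` distinct values")
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  ssq <- function(i, j) {   # within-class SS of x[i..j]
    s <- cs[j + 1L] - cs[i]; s2 <- cs2[j + 1L] - cs2[i]
    s2 - s^2 / (j - i + 1L)
  }
  # D[m, j]: minimal total SS splitting x[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)     # index of the first element of the last class
  for (j in seq_len(n)) { D[1L, j] <- ssq(1L, j); B[1L, j] <- 1L }
  for (m in 2:k) {
    for (j in m:n) {
      best <- Inf; arg <- m
      for (i in m:j) {
        v <- D[m - 1L, i - 1L] + ssq(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      D[m, j] <- best; B[m, j] <- arg
    }
  }
  cuts <- numeric(k - 1L)
  j <- n
  for (m in k:2) {
    i <- B[m, j]
    cuts[m - 1L] <- x[i - 1L]
    j <- i - 1L
  }
  c(x[1L], cuts, x[n])
}

#' Classification scheme for a continuous resistance layer
#'
#' Ordered, non-overlapping bins mapping a continuous input (e.g. TRI,
#' distance to shore) to integer resistance values 1-6. Bins are
#' left-closed, right-open except the last (closed); values below the first
#' bound take the first class and values above the last bound take the last
#' class (open-ended extremes).
#'
#' @param lower,upper bin bounds (equal length, ordered, non-overlapping).
#' @param resistance integer resistance per bin, each in 1-6.
#' @param label optional bin labels.
#' @return A `classification_scheme` tibble.
#' @export
classification_scheme <- function(lower, upper, resistance, label = NULL) {
  if (length(lower) != length(upper) || length(lower) != length(resistance))
    stop("`lower`, `upper`, `resistance` must have equal length")
  if (any(upper <= lower)) stop("each bin needs upper > lower")
  if (is.unsorted(lower) || any(lower[-1] < upper[-length(upper)] - 1e-9))
    stop("bins must be ordered and non-overlapping")
  if (any(resistance != round(resistance) | resistance < 1 | resistance > 6))
    stop("resistance values must be integers in [1, 6]")
  out <- tibble::tibble(lower = lower, upper = upper,
                        resistance = as.integer(resistance),
                        label = label %||% rep(NA_character_, length(lower)))
  class(out) <- c("classification_scheme", class(out))
  out
}

#' Published resistance schemes for bears
#'
#' The expert-parameterized class-to-resistance tables used by the
#' cumulative surface: terrain ruggedness in six Jenks classes (1-25, 25-50,
#' 50-88, 88-139, 139-230, 230-271 mapping to resistance 1-6), and open
#' water by distance to shore (< 1 km -> 3, 1-3 km -> 5, > 3 km -> 6).
#'
#' @return A `classification_scheme`.
#' @export
tri_scheme <- function() {
  classification_scheme(
    lower = c(1, 25, 50, 88, 139, 230),
    upper = c(25, 50, 88, 139, 230, 271),
    resistance = 1:6,
    label = c("very low", "low", "low-medium", "medium-high", "high",
              "very high")
  )
}

#' @rdname tri_scheme
#' @export
water_scheme <- function() {
  classification_scheme(
    lower = c(0, 1000, 3000),
    upper = c(1000, 3000, Inf),
    resistance = c(3L, 5L, 6L),
    label = c("low-medium", "high", "very high")
  )
}

#' Classify a continuous grid into a resistance layer
#'
#' @param grid continuous input `bc_grid`.
#' @param scheme a [classification_scheme()].
#' @param provenance tag recorded on the layer (`"tri"`, `"water"`, ...).
#' @return A resistance `bc_grid` (integer values; NA propagates).
#' @export
classify_continuous <- function(grid, scheme, provenance = "tri") {
  v <- grid$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  edges <- c(-Inf, scheme$upper[-nrow(scheme)], Inf)
  cls <- findInterval(v, edges, left.open = FALSE)   # below first bound -> 1
  out[] <- scheme$resistance[cls]
  out[is.na(v)] <- NA_real_
  res <- grid_create(out, grid$cell_size, grid$xmin, grid$ymax)
  attr(res, "provenance") <- provenance
  res
}

#' Classify landcover into a resistance layer
#'
#' Mature forest (non-harvested, harvested > 75 years ago, or projected age
#' over 75), bryoid/shrubland/herb, and barren rock take resistance 1;
#' regenerating forest (harvested 10-75 years ago, the hyper-dense
#' stem-exclusion stage) takes 3; snow/ice takes 6; water is nodata on this
#' layer (it is covered by the water layer instead). Stands younger than 10
#' years are treated as open early-seral ground (resistance 1,
#' `young_stand_resistance` to override).
#'
#' @param landcover categorical `bc_grid` coded as [landcover_levels()].
#' @param stand_age optional `bc_grid` of stand age in years; forest cells
#'   aged 10-75 are reclassified as regenerating.
#' @param young_stand_resistance resistance for stands < 10 years old.
#' @return A resistance `bc_grid`.
#' @export
classify_landcover <- function(landcover, stand_age = NULL,
                               young_stand_resistance = 1L) {
  lv <- landcover_levels()
  v <- landcover$values
  known <- is.na(v) | v %in% lv
  if (!all(known)) {
    bad <- unique(v[!known])
    stop("unknown landcover categories: ", paste(bad, collapse = ", "))
  }
  map <- c(1, 1, 1, 3, 6, NA)[match(v, lv)]
  out <- matrix(map, nrow(v), ncol(v))
  if (!is.null(stand_age)) {
    a <- stand_age$values
    forest <- !is.na(v) & v == lv[["mature_forest"]] & !is.na(a)
    out[forest & a >= 10 & a <= 75] <- 3
    out[forest & a < 10] <- young_stand_resistance
  }
  out[is.na(v)] <- NA_real_
  res <- grid_create(out, landcover$cell_size, landcover$xmin, landcover$ymax)
  attr(res, "provenance") <- "landcover"
  res
}

#' Euclidean distance to shore
#'
#' For every sea cell, the straight-line distance (m) from its centre to
#' the nearest land cell centre; 0 on land. Exact (Felzenszwalb-Huttenlocher
#' two-pass distance transform), equivalent to concentric ring buffering at
#' infinitesimal ring width.
#'
#' @param water_mask `bc_grid` where 1 (or TRUE) marks land and 0 marks
#'   water, as produced by [generate_land_mask()].
#' @return A `bc_grid` of distances in metres.
#' @export
distance_to_shore <- function(water_mask) {
  land <- water_mask$values == 1
  if (!any(land)) stop("mask has no land cells")
  d <- edt_squared(land) * water_mask$cell_size^2
  grid_create(sqrt(d), water_mask$cell_size, water_mask$xmin, water_mask$ymax)
}

# Exact squared Euclidean distance transform (in cell units) to the nearest
# TRUE cell: 1-D parabola lower envelopes applied along columns then rows.
edt_squared <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  f <- matrix(Inf, nr, nc)
  f[mask] <- 0
  for (j in seq_len(nc)) f[, j] <- edt_1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- edt_1d(f[i, ])
  f
}

edt_1d <- function(f) {
  n <- length(f)
  if (all(is.infinite(f))) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      }
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  # first parabola may be at an Inf cell if f[1] was Inf; drop such vertices
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

#' Classify open water by distance to shore
#'
#' Sea cells take resistance by distance band (< 1 km -> 3, 1-3 km -> 5,
#' > 3 km -> 6); land cells are nodata on this layer.
#'
#' @param distance `bc_grid` from [distance_to_shore()].
#' @param water_mask land/water `bc_grid` (1 = land).
#' @param scheme distance bins; defaults to [water_scheme()].
#' @return A resistance `bc_grid`.
#' @export
classify_water <- function(distance, water_mask, scheme = water_scheme()) {
  layer <- classify_continuous(distance, scheme, provenance = "water")
  layer$values[water_mask$values == 1] <- NA_real_
  layer
}

#' Combine the three resistance layers into the cumulative surface
#'
#' Sums the layers equally on each cell's domain (land: terrain + landcover;
#' sea: terrain + water) and affinely rescales the raw sum to the published
#' 1-10 cumulative resistance scale. A constant raw surface maps to 1.
#'
#' @param tri terrain-ruggedness resistance layer (defined everywhere).
#' @param landcover landcover resistance layer (land only).
#' @param water water resistance layer (sea only).
#' @param scale_min,scale_max output range (defaults 1 and 10).
#' @return A `bc_grid`, the cumulative resistance surface.
#' @export
combine_layers <- function(tri, landcover, water,
                           scale_min = 1, scale_max = 10) {
  lc <- landcover$values; wa <- water$values
  if (any(!is.na(lc) & !is.na(wa)))
    stop("landcover and water layers overlap; domains must be exclusive")
  other <- ifelse(is.na(lc), wa, lc)
  raw <- tri$values + other
  if (!any(!is.na(raw))) stop("no cell carries a complete set of layers")
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) < .Machine$double.eps) {
    out <- ifelse(is.na(raw), NA_real_, scale_min)
  } else {
    out <- scale_min + (scale_max - scale_min) * (raw - rng[1]) / diff(rng)
  }
  grid_create(matrix(out, nrow(raw), ncol(raw)),
              tri$cell_size, tri$xmin, tri$ymax)
}

#' Clip a grid to a study-area polygon with an edge-effect buffer
#'
#' Cells whose centres fall farther than `buffer_m` outside the polygon are
#' set to nodata; the grid is cropped to the buffered bounding box. The
#' buffer absorbs circuit edge effects near the study boundary.
#'
#' @param grid a `bc_grid`.
#' @param boundary two-column vertex matrix of the study-area polygon.
#' @param buffer_m buffer distance in metres (default 10000).
#' @return The clipped `bc_grid`.
#' @export
clip_with_buffer <- function(grid, boundary, buffer_m = 10000) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rc <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  ctr <- cell_centre(grid, rc[, 1], rc[, 2])
  d <- point_polygon_distance(ctr[, 1], ctr[, 2], boundary)
  keep <- matrix(d <= buffer_m, nr, nc)
  if (!any(keep)) stop("no cell centre lies within the buffered boundary")
  v <- grid$values
  v[!keep] <- NA_real_
  rows <- range(which(rowSums(keep) > 0))
  cols <- range(which(colSums(keep) > 0))
  v <- v[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  grid_create(v, grid$cell_size,
              xmin = grid$xmin + (cols[1] - 1L) * grid$cell_size,
              ymax = grid$ymax - (rows[1] - 1L) * grid$cell_size,
              crs = grid$crs, levels = grid$levels)
}
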
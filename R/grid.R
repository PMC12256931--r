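#' Georeferenced raster grid
#'
#' A minimal raster container used throughout the package: a numeric (or
#' integer-coded categorical) matrix plus the georeferencing needed to map
#' cells to coordinates. Rows run north to south, columns west to east, so
#' `values[1, 1]` is the north-west cell. `NA` marks nodata. Coordinates are
#' in a projected, metric CRS; the origin is the top-left cell corner.
#'
#' @param values numeric matrix, rows north to south.
#' @param cell_size cell edge length in metres (> 0).
#' @param xmin x coordinate of the west (left) edge.
#' @param ymax y coordinate of the north (top) edge; defaults to
#'   `nrow(values) * cell_size` so that the south edge sits at y = 0.
#' @param crs free-text CRS tag carried along with the grid.
#' @param levels optional character vector naming integer codes of a
#'   categorical grid (`values` then holds indices into `levels`).
#'
#' @return An object of class `bc_grid`.
#' @export
grid_create <- function(values, cell_size, xmin = 0, ymax = NULL,
                        crs = "local-metric", levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (is.null(ymax)) ymax <- nrow(values) * cell_size
  structure(
    list(values = values, cell_size = cell_size,
         xmin = xmin, ymax = ymax, crs = crs, levels = levels),
    class = "bc_grid"
  )
}

#' @export
dim.bc_grid <- function(x) dim(x$values)

#' @export
print.bc_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<bc_grid> %d x %d cells @ %g m, %d valid\n",
              nrow(x$values), ncol(x$values), x$cell_size, length(v)))
  if (!is.null(x$levels)) {
    cat("  categorical:", paste(x$levels, collapse = ", "), "\n")
  } else if (length(v)) {
    cat(sprintf("  range: [%g, %g]\n", min(v), max(v)))
  }
  invisible(x)
}

#' Coordinates of cell centres
#'
#' @param grid a `bc_grid`.
#' @param row,col cell indices (1-based, row 1 is the northern edge).
#' @return A two-column matrix of x/y centre coordinates.
#' @export
cell_centre <- function(grid, row, col) {
  cbind(x = grid$xmin + (col - 0.5) * grid$cell_size,
        y = grid$ymax - (row - 0.5) * grid$cell_size)
}

#' Cell containing a point
#'
#' Points exactly on an interior cell edge belong to the cell to the
#' south/east of the edge; points on the outer boundary are clamped inside.
#'
#' @param grid a `bc_grid`.
#' @param x,y point coordinates.
#' @return A two-column matrix of row/col indices; `NA` outside the extent.
#' @export
cell_at_xy <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell_size) + 1L
  row <- floor((grid$ymax - y) / grid$cell_size) + 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col[col == nc + 1L & x == grid$xmin + nc * grid$cell_size] <- nc
  row[row == nr + 1L & y == grid$ymax - nr * grid$cell_size] <- nr
  bad <- row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values north to south.
#'
#' @param grid a `bc_grid`.
#' @param path file path.
#' @param digits significant digits written (default 10).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `bc_grid`.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  v <- grid$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata)) stop("data collide with NODATA sentinel")
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(v, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  grid_create(m, cell_size = val[["cellsize"]], xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + nr * val[["cellsize"]])
}
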
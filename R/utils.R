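# Internal helpers: seed management and small numerics.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are bit-reproducible per
#' seed without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan a master seed out to per-stage sub-seeds by fixed offsets, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(elevation = 101L, landcover = 211L, hydrology = 307L,
               sites = 401L, detections = 503L, transits = 601L,
               individuals = 701L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2048L + offsets[[stage]]
}

# Truncated log-normal sampling by inverse-CDF, exact on the bounds.
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# Length of a polyline given as a 2-column coordinate matrix.
polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
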
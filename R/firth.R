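#' Build the transit edge list from detection histories
#'
#' An individual detected at two or more distinct sites within one sampling
#' season (year) is assumed to have transited between each pair of those
#' sites. The output covers every unordered site pair: `transited` is 1 if
#' any individual-season supports the pair, with `support` counting the
#' supporting individual-seasons; Euclidean distances between site centres
#' are attached.
#'
#' @param detections detection tibble (individual_id, species, site_id,
#'   year, session).
#' @param sites `focal_nodes` tibble of the snag sites.
#' @return Transit tibble: site_a, site_b (a before b in site order),
#'   transited (0/1), support, distance_m; n(n-1)/2 rows.
#' @export
build_transit_edges <- function(detections, sites) {
  unknown <- setdiff(unique(detections$site_id), sites$node_id)
  if (length(unknown))
    stop("detections reference unknown sites: ",
         paste(unknown, collapse = ", "))
  pairs <- node_pairs(sites)
  key <- paste(pairs$site_a, pairs$site_b, sep = "|")
  support <- stats::setNames(integer(length(key)), key)
  site_rank <- stats::setNames(seq_len(nrow(sites)), sites$node_id)

  if (nrow(detections)) {
    per_season <- split(detections$site_id,
                        paste(detections$individual_id, detections$year))
    for (visited in per_season) {
      s <- unique(visited)
      if (length(s) < 2L) next
      s <- s[order(site_rank[s])]
      idx <- utils::combn(length(s), 2L)
      k <- paste(s[idx[1L, ]], s[idx[2L, ]], sep = "|")
      support[k] <- support[k] + 1L
    }
  }
  pairs$transited <- as.integer(support > 0L)
  pairs$support <- as.integer(support)
  pairs[, c("site_a", "site_b", "transited", "support", "distance_m")]
}

#' Firth's penalized-likelihood logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l*(b) = l(b) + 0.5 * log det(X'WX)`, `W = diag(pi (1 - pi))`, by Newton
#' iteration on the modified score
#' `U*_r = sum_i (y_i - pi_i + h_i (0.5 - pi_i)) x_ir`, where `h_i` are the
#' diagonals of the penalized hat matrix. The penalty keeps estimates
#' finite under complete separation and removes the leading-order
#' small-sample bias - the standard remedy for rare-event (unbalanced)
#' outcomes. Wald standard errors come from the inverse information at the
#' optimum; step-halving guards the iteration.
#'
#' @param y 0/1 response vector.
#' @param X design matrix including an intercept column.
#' @param max_iter maximum Newton iterations (default 100).
#' @param tol convergence: max absolute modified score below `tol` (1e-8)
#'   or step shorter than `step_tol` (1e-10).
#' @param step_tol see `tol`.
#' @return A `firth_fit`: coefficients, se, odds ratios with 95% Wald CI,
#'   p-values, fitted probabilities, hat diagonals, penalized
#'   log-likelihood, convergence record.
#' @export
firth_logistic <- function(y, X, max_iter = 100L, tol = 1e-8,
                           step_tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  if (nrow(X) != length(y)) stop("X and y dimensions differ")
  if (nrow(X) < ncol(X)) stop("more parameters than observations")
  sds <- apply(X, 2L, stats::sd)
  if (sum(sds == 0) > 1L)
    stop("design has a constant non-intercept column")
  p <- ncol(X)
  beta <- numeric(p)
  pll_old <- firth_pll(beta, y, X)
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- fitted_weights(beta, X)
    pi_i <- w$pi; W <- w$w
    XtWX <- crossprod(X, X * W)
    info_inv <- tryCatch(solve(XtWX), error = function(e)
      stop("singular information matrix"))
    h <- rowSums((X %*% info_inv) * X) * W
    U <- crossprod(X, y - pi_i + h * (0.5 - pi_i))
    trace <- c(trace, max(abs(U)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- as.numeric(info_inv %*% U)
    # step-halving on the penalized likelihood
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      pll_new <- firth_pll(beta_new, y, X)
      if (is.finite(pll_new) && pll_new >= pll_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (sqrt(sum((lambda * step)^2)) < step_tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
    pll_old <- pll_new
  }
  if (!converged)
    stop("Firth iteration did not converge; score trace: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  w <- fitted_weights(beta, X)
  XtWX <- crossprod(X, X * w$w)
  info_inv <- solve(XtWX)
  se <- sqrt(diag(info_inv))
  h <- rowSums((X %*% info_inv) * X) * w$w
  z <- beta / se
  ci_lo <- beta - 1.959963984540054 * se
  ci_hi <- beta + 1.959963984540054 * se
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), nm),
    se = stats::setNames(se, nm),
    odds_ratio = stats::setNames(exp(as.numeric(beta)), nm),
    or_ci_lower = stats::setNames(exp(ci_lo), nm),
    or_ci_upper = stats::setNames(exp(ci_hi), nm),
    p_value = stats::setNames(2 * stats::pnorm(-abs(z)), nm),
    fitted = w$pi, hat = as.numeric(h),
    penalized_loglik = firth_pll(beta, y, X),
    iterations = it, converged = converged,
    vcov = info_inv, y = y, X = X
  ), class = "firth_fit")
}

fitted_weights <- function(beta, X) {
  eta <- as.numeric(X %*% beta)
  pi_i <- stats::plogis(eta)
  list(pi = pi_i, w = pmax(pi_i * (1 - pi_i), 1e-12))
}

# Penalized log-likelihood l(b) + 0.5 log det(X'WX).
firth_pll <- function(beta, y, X) {
  w <- fitted_weights(beta, X)
  ll <- sum(y * log(w$pi) + (1 - y) * log(1 - w$pi))
  ld <- determinant(crossprod(X, X * w$w), logarithm = TRUE)
  ll + 0.5 * as.numeric(ld$modulus)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized-likelihood logistic regression\n")
  tab <- data.frame(
    beta = x$coefficients, se = x$se, OR = x$odds_ratio,
    ci_low = x$or_ci_lower, ci_high = x$or_ci_upper, p = x$p_value
  )
  print(signif(tab, 4))
  cat(sprintf("converged in %d iterations; penalized logLik %.4f\n",
              x$iterations, x$penalized_loglik))
  invisible(x)
}

#' Validate a resistance surface against observed transits
#'
#' Fits `transited ~ z(conductance) + z(distance)` by Firth regression. A
#' positive conductance association (odds ratio above 1) indicates the
#' resistance surface captures real movement costs; distance is included
#' because nearer site pairs are more likely to be transited regardless.
#'
#' @param transits transit tibble with `transited`, `conductance`,
#'   `distance_m` columns (see [build_transit_edges()]; conductance must be
#'   attached from the circuit model first).
#' @param standardize z-standardize the two predictors (default TRUE), so
#'   odds ratios are per SD.
#' @return List: `fit` (a `firth_fit`), `report` tibble (term, OR, CI, p),
#'   and the standardization constants (`center`, `scale`).
#' @export
validate_surface <- function(transits, standardize = TRUE) {
  y <- transits$transited
  if (all(y == 0) || all(y == 1))
    stop("transit outcomes are all ", y[1], "; no information to fit")
  g <- transits$conductance; d <- transits$distance_m
  if (any(!is.finite(g)) || any(!is.finite(d)))
    stop("conductance and distance must be finite for all pairs")
  ctr <- c(conductance = 0, distance_m = 0)
  scl <- c(conductance = 1, distance_m = 1)
  if (standardize) {
    ctr <- c(conductance = mean(g), distance_m = mean(d))
    scl <- c(conductance = stats::sd(g), distance_m = stats::sd(d))
    if (any(scl == 0)) stop("cannot standardize a zero-variance predictor")
    g <- (g - ctr[1]) / scl[1]
    d <- (d - ctr[2]) / scl[2]
  }
  X <- cbind(`(Intercept)` = 1, conductance = g, distance_m = d)
  fit <- firth_logistic(y, X)
  report <- tibble::tibble(
    term = names(fit$coefficients),
    beta = as.numeric(fit$coefficients),
    odds_ratio = as.numeric(fit$odds_ratio),
    ci_lower = as.numeric(fit$or_ci_lower),
    ci_upper = as.numeric(fit$or_ci_upper),
    p_value = as.numeric(fit$p_value)
  )
  list(fit = fit, report = report, center = ctr, scale = scl,
       standardize = standardize)
}

#' Predicted transit-probability curve over conductance
#'
#' Evaluates the fitted model over a grid of conductance values with
#' distance held fixed (default 5170 m, the radius of an 84 km2 circular
#' home range: `sqrt(84e6 / pi)` m, the average coastal male black bear
#' home range).
#'
#' @param validation result of [validate_surface()].
#' @param conductance_grid conductance values to evaluate.
#' @param distance_fixed_m fixed distance in metres.
#' @return Tibble: conductance, probability. Strictly monotone in
#'   conductance when its coefficient is nonzero; bounded in (0, 1).
#' @export
predict_transit_curve <- function(validation, conductance_grid,
                                  distance_fixed_m = home_range_radius_m()) {
  b <- validation$fit$coefficients
  zg <- (conductance_grid - validation$center[["conductance"]]) /
    validation$scale[["conductance"]]
  zd <- (distance_fixed_m - validation$center[["distance_m"]]) /
    validation$scale[["distance_m"]]
  eta <- b[["(Intercept)"]] + b[["conductance"]] * zg + b[["distance_m"]] * zd
  tibble::tibble(conductance = conductance_grid,
                 probability = stats::plogis(eta))
}

#' Radius of a circular home range
#'
#' @param area_km2 home-range area (default 84 km2, the average coastal
#'   male black bear home range).
#' @return Radius in metres (`sqrt(area / pi)`), ~5170 m for 84 km2.
#' @export
home_range_radius_m <- function(area_km2 = 84) {
  sqrt(area_km2 * 1e6 / pi)
}
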
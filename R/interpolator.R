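# Nearest-neighbor interpolation of sampled spatial values.
#
# The interpolated value at a query point is the observed value at its
# nearest sampled location; when several sampled locations are (numerically)
# tied at the minimum distance, their observations are averaged. A query
# coinciding with a sampled location returns the observation there, so the
# map is exact on the sample.

# Core tie-averaging NN evaluation, vectorized over queries and chunked to
# bound the size of the distance matrix.
nn_values <- function(sx, sy, sv, qx, qy, tie_tol = 1e-9,
                      chunk = 2^21) {
  n <- length(sv)
  nq <- length(qx)
  out <- numeric(nq)
  rows_per_chunk <- max(1L, as.integer(chunk / n))
  start <- 1L
  while (start <= nq) {
    end <- min(nq, start + rows_per_chunk - 1L)
    i <- start:end
    d <- sqrt(outer(qx[i], sx, `-`)^2 + outer(qy[i], sy, `-`)^2)
    dmin <- d[cbind(seq_along(i), max.col(-d, ties.method = "first"))]
    H <- d <= dmin + tie_tol
    out[i] <- as.vector(H %*% sv) / rowSums(H)
    start <- end + 1L
  }
  out
}

# normalize query input: matrix/data.frame of points or a grid_spec
query_points <- function(query) {
  if (inherits(query, "grid_spec")) {
    g <- grid_centers(query)
    list(x = g$x, y = g$y, grid = query)
  } else {
    p <- as_points(query)
    list(x = p[, 1], y = p[, 2], grid = NULL)
  }
}

#' Nearest-neighbor interpolation at query locations
#'
#' Builds the piecewise-constant nearest-neighbor map from a sample of
#' observed locations: the interpolated value at each query point is the
#' observation at its nearest sampled location, averaging over all sampled
#' locations whose distance is within `tie_tol` of the minimum. The map is
#' constant on the Voronoi cells of the sampled locations, exact at sampled
#' locations, and its values never leave the observed range.
#'
#' @param sample An `"nn_sample"` (see [draw_sample()], [as_nn_sample()]).
#' @param query Query locations: an `m` x 2 matrix / data frame of
#'   coordinates, or a [grid_spec()] describing a regular evaluation grid
#'   (queried at cell centers).
#' @param tie_tol Absolute distance tolerance (in region units) deciding both
#'   coincidence with a sampled location and membership in the tied
#'   nearest-neighbor set. Exact ties arise on lattices; the tolerance only
#'   guards floating-point quantization.
#' @return Object of class `"estimated_map"`: a data frame with columns `x`,
#'   `y`, `value`, with the generating sample and any grid attached as
#'   attributes.
#' @examples
#' s <- as_nn_sample(c(0, 1), c(0, 1), c(0, 8))
#' nn_interpolate(s, rbind(c(0.5, 0.5)))$value  # 4: exact two-way tie
#' @export
nn_interpolate <- function(sample, query, tie_tol = 1e-9) {
  stopifnot(inherits(sample, "nn_sample"))
  if (length(sample$values) == 0L) stop("empty sample", call. = FALSE)
  q <- query_points(query)
  v <- nn_values(sample$points[, 1], sample$points[, 2], sample$values,
                 q$x, q$y, tie_tol)
  structure(data.frame(x = q$x, y = q$y, value = v),
            sample = sample, grid = q$grid,
            setting = sample$setting,
            class = c("estimated_map", "data.frame"))
}

#' Nearest-neighbor map of an area population
#'
#' Interpolates per-area densities over all areas of the population from a
#' sample of areas: a sampled area keeps its own observed density (its
#' centroid distance is zero); an unsampled area receives the tie-averaged
#' density of the nearest sampled centroid(s). The full-region map is the
#' piecewise-constant field over quadrats.
#'
#' @param indices Indices of the sampled areas.
#' @param area_pop An [area_population()].
#' @param values Observed densities of the sampled areas; defaults to the
#'   population densities (use bootstrap pseudo-values to override).
#' @param tie_tol See [nn_interpolate()].
#' @return An `"estimated_map"` over all area centroids, with a `density`
#'   alias column and the population attached.
#' @export
nn_map_areas <- function(indices, area_pop, values = NULL, tie_tol = 1e-9) {
  stopifnot(inherits(area_pop, "area_population"))
  a <- area_pop$areas
  indices <- as.integer(indices)
  if (length(indices) == 0L || any(indices < 1L | indices > nrow(a))) {
    stop("invalid sampled area indices", call. = FALSE)
  }
  if (is.null(values)) values <- a$density[indices]
  v <- nn_values(a$cx[indices], a$cy[indices], values, a$cx, a$cy, tie_tol)
  structure(data.frame(x = a$cx, y = a$cy, value = v),
            sample = list(indices = indices, values = values),
            population = area_pop, setting = "areas",
            class = c("estimated_map", "data.frame"))
}

#' Nearest-neighbor map of a unit population
#'
#' As [nn_map_areas()], with unit locations as the support: sampled units
#' keep their observed value, unsampled units receive the tie-averaged value
#' of their nearest sampled unit(s).
#'
#' @param indices Indices of the sampled units.
#' @param unit_pop A `"unit_population"` with values attached.
#' @param values Observed values of the sampled units (defaults to the
#'   population values).
#' @param tie_tol See [nn_interpolate()].
#' @return An `"estimated_map"` over all unit locations.
#' @export
nn_map_units <- function(indices, unit_pop, values = NULL, tie_tol = 1e-9) {
  stopifnot(inherits(unit_pop, "unit_population"))
  u <- unit_pop$units
  indices <- as.integer(indices)
  if (length(indices) == 0L || any(indices < 1L | indices > nrow(u))) {
    stop("invalid sampled unit indices", call. = FALSE)
  }
  if (is.null(values)) {
    if (is.null(u$value)) stop("unit population has no values", call. = FALSE)
    values <- u$value[indices]
  }
  v <- nn_values(u$x[indices], u$y[indices], values, u$x, u$y, tie_tol)
  structure(data.frame(x = u$x, y = u$y, value = v),
            sample = list(indices = indices, values = values),
            population = unit_pop, setting = "units",
            class = c("estimated_map", "data.frame"))
}

#' Residual nearest-neighbor interpolation under 3P sampling
#'
#' Under probability-proportional-to-prediction sampling the prediction error
#' `e_j = y_j - x_j` of every sampled unit is known. Interpolating the errors
#' instead of the values and reconstructing `yhat_j = x_j + ehat_j` exploits
#' the predictions available for the whole frame; jumps in the survey
#' variable that are tracked by the predictions leave only small jumps in the
#' errors, which is why this variant maps discontinuous populations well.
#'
#' @param indices Indices of the sampled units.
#' @param unit_pop A `"unit_population"` with `value`, `prediction` columns.
#' @param errors Observed prediction errors of the sampled units; defaults to
#'   `value - prediction` (override with bootstrap pseudo-errors).
#' @param tie_tol See [nn_interpolate()].
#' @return An `"estimated_map"` of reconstructed values over all units, with
#'   the interpolated error surface in attribute `"errors"`. Sampled units
#'   reproduce their true values exactly.
#' @export
residual_interpolate <- function(indices, unit_pop, errors = NULL,
                                 tie_tol = 1e-9) {
  stopifnot(inherits(unit_pop, "unit_population"))
  u <- unit_pop$units
  if (is.null(u$prediction)) {
    stop("residual interpolation needs predictions for every unit",
         call. = FALSE)
  }
  indices <- as.integer(indices)
  if (is.null(errors)) errors <- u$value[indices] - u$prediction[indices]
  ehat <- nn_values(u$x[indices], u$y[indices], errors, u$x, u$y, tie_tol)
  v <- u$prediction + ehat
  structure(data.frame(x = u$x, y = u$y, value = v),
            sample = list(indices = indices, errors = errors),
            population = unit_pop, errors = ehat, setting = "units",
            class = c("estimated_map", "data.frame"))
}

#' Inverse-distance-weighted interpolation
#'
#' The IDW interpolator with weight function `d^(-alpha)`: a convex
#' combination of all observations with weights decaying in distance. As
#' `alpha` grows the weight mass concentrates on the nearest sampled
#' location, so IDW converges to the nearest-neighbor interpolator; the
#' package uses it as an independent cross-check of the NN map. Weights are
#' computed on distance ratios to the minimum, which keeps large `alpha`
#' numerically stable.
#'
#' @inheritParams nn_interpolate
#' @param alpha Positive decay exponent.
#' @return An `"estimated_map"`.
#' @export
idw_interpolate <- function(sample, query, alpha = 2, tie_tol = 1e-9) {
  stopifnot(inherits(sample, "nn_sample"), alpha > 0)
  if (length(sample$values) == 0L) stop("empty sample", call. = FALSE)
  q <- query_points(query)
  sx <- sample$points[, 1]; sy <- sample$points[, 2]; sv <- sample$values
  d <- sqrt(outer(q$x, sx, `-`)^2 + outer(q$y, sy, `-`)^2)
  dmin <- d[cbind(seq_along(q$x), max.col(-d, ties.method = "first"))]
  v <- numeric(length(q$x))
  at <- dmin <= tie_tol   # coincides with a sampled location
  if (any(at)) {
    H <- d[at, , drop = FALSE] <= tie_tol
    v[at] <- as.vector(H %*% sv) / rowSums(H)
  }
  if (any(!at)) {
    r <- d[!at, , drop = FALSE] / dmin[!at]   # ratios >= 1, no overflow
    w <- r^(-alpha)
    v[!at] <- as.vector(w %*% sv) / rowSums(w)
  }
  structure(data.frame(x = q$x, y = q$y, value = v),
            sample = sample, grid = q$grid, setting = sample$setting,
            class = c("estimated_map", "data.frame"))
}

#' @export
print.estimated_map <- function(x, ...) {
  cat(sprintf("estimated map on %d support points (%s setting), range [%g, %g]\n",
              nrow(x), attr(x, "setting") %||% "?", min(x$value), max(x$value)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
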
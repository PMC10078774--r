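# Finite populations of areas and of units.

#' Finite population of areas from a surface
#'
#' Partitions the unit square into a `g` x `g` grid of equal quadrats and
#' builds a finite population of areas: the amount of the survey variable in
#' quadrat `j` is the integral of the surface over the quadrat (midpoint rule
#' on an `m` x `m` sub-grid per quadrat), and the per-area density is
#' `total / area`. Sampled areas are identified by their centroids.
#'
#' The midpoint rule is exact for fields that are constant within quadrats and
#' is O(m^-2) otherwise; the jump set of canonical surface 3 lies along
#' quadrat edges for the grid sizes used in the simulation study, so the rule
#' never integrates across a jump there.
#'
#' @param surface Surface id (1, 2, 3) or a vectorized function `f(x, y)`.
#' @param g Grid side; the population has `N = g^2` areas.
#' @param m Sub-grid side of the midpoint quadrature per quadrat.
#' @param region Study region (canonical ids require the unit square).
#' @return Object of class `"area_population"`: a list with `areas` (a
#'   data frame with one row per quadrat: `row`, `col`, `cx`, `cy` centroid,
#'   `total`, `density`), `g`, `region` and `cell_area`.
#' @examples
#' ap <- area_population(1, g = 10)
#' nrow(ap$areas)     # 100
#' @export
area_population <- function(surface, g, m = 20L, region = study_region()) {
  stopifnot(g >= 1, m >= 1)
  g <- as.integer(g); m <- as.integer(m)
  fld <- if (inherits(surface, "population_field")) surface else
    population_field(surface, region = region)
  region <- fld$region
  sx <- region$width / g
  sy <- region$height / g
  # midpoint nodes within one quadrat, replicated over quadrats
  off <- (seq_len(m) - 0.5) / m
  idx <- expand.grid(col = seq_len(g), row = seq_len(g))
  totals <- numeric(g * g)
  nodes_x <- rep(off, times = m)   # m^2 offsets in [0,1)^2
  nodes_y <- rep(off, each = m)
  for (j in seq_len(g * g)) {
    x0 <- region$xmin + (idx$col[j] - 1) * sx
    y0 <- region$ymin + (idx$row[j] - 1) * sy
    v <- fld$f(x0 + nodes_x * sx, y0 + nodes_y * sy)
    totals[j] <- mean(v) * sx * sy
  }
  areas <- data.frame(
    row = idx$row, col = idx$col,
    cx = region$xmin + (idx$col - 0.5) * sx,
    cy = region$ymin + (idx$row - 0.5) * sy,
    total = totals,
    density = totals / (sx * sy)
  )
  structure(list(areas = areas, g = g, region = region,
                 cell_area = sx * sy, L = fld$L),
            class = "area_population")
}

#' @export
print.area_population <- function(x, ...) {
  cat(sprintf("area population: %d x %d quadrats (N = %d), total amount %g\n",
              x$g, x$g, nrow(x$areas), sum(x$areas$total)))
  invisible(x)
}

#' Nested unit populations with a given spatial pattern
#'
#' Generates nested finite populations of units on the unit square following
#' one of four spatial point patterns. Population sizes are nested by prefix:
#' the first `sizes[1]` locations form the smallest population, the first
#' `sizes[2]` the next, and so on.
#'
#' Patterns:
#' * `"regular"` — sequential uniform proposals; while filling the population
#'   up to size `sizes[k]`, a proposal closer than `0.5 * sizes[k]^(-1/2)` to
#'   any previously accepted location is discarded.
#' * `"random"` — i.i.d. uniform locations.
#' * `"trended"` — locations `(1 - u1^2, 1 - u2^2)` from independent uniform
#'   `u1`, `u2`, concentrating units near the upper-right corner.
#' * `"clustered"` — 10 uniform cluster centers; at each nesting level every
#'   cluster receives 50 locations from a circular Gaussian centered at its
#'   center with per-coordinate variance 0.025; locations falling outside the
#'   region are discarded and regenerated.
#'
#' @param pattern One of `"regular"`, `"random"`, `"trended"`, `"clustered"`.
#' @param sizes Strictly increasing population sizes (clustered sizes must be
#'   multiples of the 10 x 50 cluster layout).
#' @param region Study region (unit square for the canonical setup).
#' @param max_tries Cap on consecutive rejections when thinning the regular
#'   pattern; exceeding it is an error.
#' @return List of `"unit_population"` objects, one per size, sharing their
#'   common prefix of locations exactly. Each has a data frame `units` with
#'   columns `x`, `y` (values are attached later with
#'   [assign_surface_values()]).
#' @examples
#' pops <- unit_pattern("random", sizes = c(50, 100))
#' identical(pops[[2]]$units[1:50, ], pops[[1]]$units)
#' @export
unit_pattern <- function(pattern = c("regular", "random", "trended", "clustered"),
                         sizes = c(500L, 1000L, 1500L),
                         region = study_region(),
                         max_tries = 10000L) {
  pattern <- match.arg(pattern)
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1L, all(diff(sizes) > 0L), sizes[1] >= 1L)
  N <- max(sizes)
  xy <- switch(pattern,
    random = cbind(stats::runif(N), stats::runif(N)),
    trended = {
      u1 <- stats::runif(N); u2 <- stats::runif(N)
      cbind(1 - u1^2, 1 - u2^2)
    },
    regular = regular_pattern(sizes, region, max_tries),
    clustered = clustered_pattern(sizes, region)
  )
  if (pattern %in% c("random", "trended")) {
    # map to the region if it is not the unit square
    xy[, 1] <- region$xmin + xy[, 1] * region$width
    xy[, 2] <- region$ymin + xy[, 2] * region$height
  }
  lapply(sizes, function(n) {
    structure(list(
      units = data.frame(x = xy[seq_len(n), 1], y = xy[seq_len(n), 2]),
      pattern = pattern, region = region, L = surface_L()
    ), class = "unit_population")
  })
}

# sequential thinning: proposals rejected when nearer than the level
# threshold 0.5 * sizes[k]^(-1/2) to any previously accepted point
regular_pattern <- function(sizes, region, max_tries) {
  N <- max(sizes)
  pts <- matrix(NA_real_, N, 2L)
  level <- 1L
  tries <- 0L
  i <- 0L
  while (i < N) {
    if (i >= sizes[level]) level <- level + 1L
    dmin <- 0.5 / sqrt(sizes[level])
    cand <- c(region$xmin + stats::runif(1) * region$width,
              region$ymin + stats::runif(1) * region$height)
    ok <- i == 0L ||
      min((pts[seq_len(i), 1] - cand[1])^2 +
          (pts[seq_len(i), 2] - cand[2])^2) >= dmin^2
    if (ok) {
      i <- i + 1L
      pts[i, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(
          "regular pattern: %d consecutive rejections at point %d (cap %d)",
          tries, i + 1L, max_tries), call. = FALSE)
      }
    }
  }
  pts
}

clustered_pattern <- function(sizes, region) {
  n_clusters <- 10L
  per_level <- 50L
  if (any(sizes %% (n_clusters * per_level) != 0L)) {
    stop("clustered pattern sizes must be multiples of 500 (10 clusters x 50 points)",
         call. = FALSE)
  }
  centers <- cbind(region$xmin + stats::runif(n_clusters) * region$width,
                   region$ymin + stats::runif(n_clusters) * region$height)
  sd <- sqrt(0.025)
  draw_cluster_points <- function(center, k) {
    out <- matrix(NA_real_, k, 2L)
    got <- 0L
    while (got < k) {
      need <- k - got
      cand <- cbind(stats::rnorm(need, center[1], sd),
                    stats::rnorm(need, center[2], sd))
      keep <- in_region(region, cand[, 1], cand[, 2])
      if (any(keep)) {
        kept <- cand[keep, , drop = FALSE]
        out[got + seq_len(nrow(kept)), ] <- kept
        got <- got + nrow(kept)
      }
    }
    out
  }
  levels <- max(sizes) / (n_clusters * per_level)
  blocks <- vector("list", levels)
  for (lv in seq_len(levels)) {
    pts <- lapply(seq_len(n_clusters), function(c)
      draw_cluster_points(centers[c, ], per_level))
    blocks[[lv]] <- do.call(rbind, pts)
  }
  do.call(rbind, blocks)
}

#' @export
print.unit_population <- function(x, ...) {
  cat(sprintf("unit population: N = %d (%s pattern)%s\n",
              nrow(x$units), x$pattern,
              if (!is.null(x$units$value)) ", values attached" else ""))
  invisible(x)
}

#' Attach survey-variable values to a unit population
#'
#' Evaluates a surface at the unit locations and stores the values as the
#' units' survey variable.
#'
#' @param pop A `"unit_population"`.
#' @param surface Surface id (1, 2, 3) or a vectorized function `f(x, y)`.
#' @return The population with a `value` column added.
#' @export
assign_surface_values <- function(pop, surface) {
  stopifnot(inherits(pop, "unit_population"))
  fld <- if (inherits(surface, "population_field")) surface else
    population_field(surface, region = pop$region)
  pop$units$value <- fld$f(pop$units$x, pop$units$y)
  pop$L <- fld$L
  pop
}

#' Discard units below a value threshold
#'
#' Removes from a unit population all units whose survey-variable value is
#' below `l`, as done in surveys where units under a measurement threshold
#' (minimum tree height, basal area, ...) are not part of the frame. The
#' retained units keep their original order, so nested populations truncated
#' with the same threshold remain nested.
#'
#' @param pop A `"unit_population"` with values attached.
#' @param l Threshold; units with `value >= l` are retained.
#' @return The truncated population.
#' @export
truncate_units <- function(pop, l) {
  stopifnot(inherits(pop, "unit_population"), is.numeric(l), length(l) == 1L)
  if (is.null(pop$units$value)) {
    stop("assign values before truncating", call. = FALSE)
  }
  if (l < 0 || l >= pop$L) stop("need 0 <= l < L", call. = FALSE)
  keep <- pop$units$value >= l
  if (!any(keep)) stop("truncation removed every unit", call. = FALSE)
  pop$units <- pop$units[keep, , drop = FALSE]
  rownames(pop$units) <- NULL
  pop$l <- l
  pop
}

#' Linear expert predictions and 3P inclusion probabilities
#'
#' Attaches to each unit an expert prediction that grows linearly with the
#' true value, `x_j = a + b y_j` with `b = 1 - rho (L + l) / (L - l)` and
#' `a = (1 + rho) l - b l`, so that the relative prediction error never
#' exceeds `rho` and equals `rho` exactly at both extremes `y = l` and
#' `y = L`. Inclusion probabilities for probability-proportional-to-prediction
#' (3P) sampling are `pi_j = x_j / L_star`.
#'
#' @param pop A `"unit_population"` with values in `[l, L]`.
#' @param rho Maximum relative prediction error (`0 <= rho < 1`).
#' @param l,L Value range of the (truncated) population.
#' @param L_star Scaling constant of the 3P design; must give `pi_j <= 1`.
#' @return The population with `prediction` and `pi` columns added.
#' @examples
#' # at y = l = 4 the prediction is (1 + rho) l = 4.4
#' @export
add_predictions <- function(pop, rho = 0.10, l = 4, L = surface_L(),
                            L_star = 50) {
  stopifnot(inherits(pop, "unit_population"), rho >= 0, rho < 1, l < L)
  y <- pop$units$value
  if (is.null(y)) stop("assign values before predicting", call. = FALSE)
  if (any(y < l - 1e-12 | y > L + 1e-12)) {
    stop("unit values must lie in [l, L]; truncate first", call. = FALSE)
  }
  b <- 1 - rho * (L + l) / (L - l)
  a <- (1 + rho) * l - b * l
  x <- a + b * y
  pi <- x / L_star
  if (any(pi > 1)) {
    stop("L_star too small: some inclusion probabilities exceed 1",
         call. = FALSE)
  }
  if (any(pi <= 0)) {
    stop("non-positive inclusion probability; check rho, l, L_star",
         call. = FALSE)
  }
  pop$units$prediction <- x
  pop$units$pi <- pi
  pop$L_star <- L_star
  pop
}

#' Inclusion-probability floor of a truncated 3P design
#'
#' When the population is truncated at `l` and predictions are at least the
#' true values' lower bound, 3P inclusion probabilities `x_j / L_star` are
#' bounded below by `l / L_star`.
#'
#' @param l Truncation threshold.
#' @param L_star 3P scaling constant.
#' @return The floor `l / L_star`.
#' @examples
#' threep_floor(4, 50)   # 0.08
#' @export
threep_floor <- function(l, L_star) {
  stopifnot(l > 0, L_star > 0)
  l / L_star
}
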
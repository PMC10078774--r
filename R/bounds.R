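# Finite-sample error bounds for the NN interpolator.
#
# The design-based absolute error at a point p splits into a roughness term
# (the largest jump of the field within a delta-ball of p) and a design term
# (the field bound L times the probability that no sampled location falls in
# that ball). Both terms are computable: the oscillation by refinement over a
# local grid, the miss probability in closed form under uniform random and
# tessellation stratified sampling, or by Monte Carlo for any scheme.

#' Local oscillation of a field
#'
#' The largest jump `sup |f(q) - f(p)|` of a field over the closed
#' `delta`-ball of `p` intersected with the region, approximated on a regular
#' grid of the ball's bounding box, with resolution doubled until the value
#' stabilizes.
#'
#' @param f Field function `f(x, y)`, vectorized.
#' @param p Target location `c(x, y)`.
#' @param delta Ball radius, `> 0`.
#' @param region Study region clipping the ball.
#' @param resolution Initial grid side over the ball's bounding box.
#' @param tol Stop refining when a doubling changes the value by less than
#'   this.
#' @param max_resolution Hard cap on the refinement grid side.
#' @return The oscillation value (non-negative, non-decreasing in `delta`).
#' @export
oscillation <- function(f, p, delta, region = study_region(),
                        resolution = 101L, tol = 1e-4,
                        max_resolution = 3201L) {
  stopifnot(delta > 0)
  fp <- f(p[1], p[2])
  res <- as.integer(resolution)
  last <- -Inf
  repeat {
    gx <- seq(max(region$xmin, p[1] - delta),
              min(region$xmax, p[1] + delta), length.out = res)
    gy <- seq(max(region$ymin, p[2] - delta),
              min(region$ymax, p[2] + delta), length.out = res)
    qx <- rep(gx, times = length(gy))
    qy <- rep(gy, each = length(gx))
    keep <- (qx - p[1])^2 + (qy - p[2])^2 <= delta^2
    val <- max(abs(f(qx[keep], qy[keep]) - fp))
    if (abs(val - last) < tol || res >= max_resolution) return(val)
    last <- val
    res <- 2L * res - 1L
  }
}

# --- exact circle / rectangle intersection -------------------------------

# area of disk(center 0, radius r) intersected with the quadrant
# {X >= x, Y >= y}; standard piecewise closed form
disk_corner_area <- function(x, y, r) {
  if (x >= r || y >= r) return(0)
  x <- max(x, -r)
  F <- function(t) (t * sqrt(pmax(r^2 - t^2, 0)) + r^2 * asin(pmin(pmax(t / r, -1), 1))) / 2
  int_s <- function(a, b) if (b <= a) 0 else F(b) - F(a)   # integral of sqrt(r^2 - t^2)
  if (y >= 0) {
    ty <- sqrt(r^2 - y^2)
    a <- max(x, -ty)
    if (a >= ty) return(0)
    int_s(a, ty) - y * (ty - a)
  } else if (y > -r) {
    ty <- sqrt(r^2 - y^2)
    a1 <- max(x, -ty)
    part1 <- if (a1 < ty) int_s(a1, ty) - y * (ty - a1) else 0
    part2 <- 2 * int_s(max(x, ty), r)          # right cap, full chord
    part3 <- 2 * int_s(x, -ty)                  # left cap (x >= -r already)
    part1 + part2 + part3
  } else {
    2 * int_s(x, r)
  }
}

#' Area of a disk clipped to a rectangle
#'
#' Exact area of the intersection of the closed disk of radius `r` centered
#' at `(cx, cy)` with the axis-aligned rectangle, by inclusion-exclusion of
#' the standard disk-quadrant closed form.
#'
#' @param cx,cy Disk center.
#' @param r Radius.
#' @param xmin,xmax,ymin,ymax Rectangle bounds (or pass a [study_region()]
#'   via `region`).
#' @param region Optional region overriding the four bounds.
#' @return The intersection area.
#' @export
circle_rect_area <- function(cx, cy, r, xmin = 0, xmax = 1, ymin = 0,
                             ymax = 1, region = NULL) {
  if (!is.null(region)) {
    xmin <- region$xmin; xmax <- region$xmax
    ymin <- region$ymin; ymax <- region$ymax
  }
  stopifnot(r >= 0, xmax > xmin, ymax > ymin)
  if (r == 0) return(0)
  # translate so the disk is centered at the origin
  x1 <- xmin - cx; x2 <- xmax - cx
  y1 <- ymin - cy; y2 <- ymax - cy
  a <- disk_corner_area(x1, y1, r) - disk_corner_area(x2, y1, r) -
    disk_corner_area(x1, y2, r) + disk_corner_area(x2, y2, r)
  min(max(a, 0), pi * r^2)
}

# --- miss probabilities --------------------------------------------------

#' Miss probability under uniform random sampling
#'
#' Probability that none of `n` independent uniform locations falls within
#' the closed `delta`-ball of `p`: `(1 - area(ball \[intersect\] B) /
#' area(B))^n`, with the clipped ball area computed exactly.
#'
#' @param region Study region.
#' @param p Target location `c(x, y)`.
#' @param delta Ball radius.
#' @param n Sample size.
#' @return A probability, with attribute `method = "analytic"`.
#' @export
miss_prob_urs <- function(region, p, delta, n) {
  stopifnot(inherits(region, "study_region"), delta > 0, n >= 1)
  a <- circle_rect_area(p[1], p[2], delta, region = region)
  structure((1 - a / region$area)^n, method = "analytic")
}

#' Miss probability under tessellation stratified sampling
#'
#' With one independent uniform location per cell of the `k` x `k`
#' tessellation, the miss probability is the product over cells of
#' `1 - area(ball \[intersect\] cell) / area(cell)`. It hits exactly zero as
#' soon as the ball covers one whole cell, which happens for every `p` when
#' `delta >= sqrt(2)` cell sides: the spatial-balance guarantee behind
#' uniform consistency.
#'
#' @param region Study region.
#' @param p Target location.
#' @param delta Ball radius.
#' @param k Tessellation side (`n = k^2` locations).
#' @return A probability, with attribute `method = "analytic"`.
#' @export
miss_prob_tss <- function(region, p, delta, k) {
  stopifnot(inherits(region, "study_region"), delta > 0, k >= 1)
  co <- cell_origins(region, k)
  cell_area <- co$sx * co$sy
  pr <- 1
  for (i in seq_along(co$x0)) {
    x0 <- co$x0[i]; y0 <- co$y0[i]
    # a cell entirely inside the ball (all four corners within delta)
    # contributes an exactly-zero factor; testing corners avoids relying on
    # the clipped area agreeing with the cell area to the last bit
    corner_d2 <- pmax((x0 - p[1])^2, (x0 + co$sx - p[1])^2) +
      pmax((y0 - p[2])^2, (y0 + co$sy - p[2])^2)
    if (corner_d2 <= (delta * (1 + 1e-12))^2) {
      pr <- 0
      break
    }
    a <- circle_rect_area(p[1], p[2], delta, x0, x0 + co$sx, y0, y0 + co$sy)
    pr <- pr * (1 - a / cell_area)
    if (pr == 0) break
  }
  structure(max(pr, 0), method = "analytic")
}

#' Monte-Carlo miss probability for any scheme
#'
#' Estimates the probability that no sampled location falls within the
#' closed `delta`-ball of `p` by repeated sampling. The miss event uses the
#' strict inequality `distance > delta` for every sampled location, so
#' `delta = 0` makes a miss almost sure under continuous designs.
#'
#' @param spec A [scheme_spec()] for a continuous design (URS/TSS/SGS).
#' @param region Study region.
#' @param p Target location.
#' @param delta Ball radius (`>= 0`).
#' @param reps Number of Monte-Carlo replications.
#' @return The estimated probability, with attributes `method = "mc"` and
#'   `se` (binomial standard error).
#' @export
miss_prob_mc <- function(spec, region, p, delta, reps = 10000L) {
  stopifnot(inherits(spec, "scheme_spec"), reps >= 1, delta >= 0)
  misses <- 0L
  for (r in seq_len(reps)) {
    pts <- switch(spec$scheme,
                  URS = draw_urs(region, spec$n),
                  TSS = draw_tss(region, spec$k),
                  SGS = draw_sgs(region, spec$k),
                  stop("miss_prob_mc supports continuous designs",
                       call. = FALSE))
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    if (all(d2 > delta^2)) misses <- misses + 1L
  }
  est <- misses / reps
  structure(est, method = "mc", se = sqrt(est * (1 - est) / reps))
}

#' Pointwise bound on the expected interpolation error
#'
#' Upper bound `osc + L * miss` on the design expectation of the absolute
#' NN interpolation error at `p`: the local oscillation of the field over
#' the `delta`-ball plus the field bound times the probability that the
#' ball catches no sampled location. The miss probability is computed
#' analytically for URS and TSS and by Monte Carlo otherwise.
#'
#' @param field A [population_field()].
#' @param spec A [scheme_spec()] for a continuous design.
#' @param p Target location.
#' @param delta Ball radius, `> 0` (any value may be used; smaller balls
#'   shrink the roughness term but inflate the miss term).
#' @param reps Monte-Carlo replications when no closed form applies.
#' @return List with `oscillation`, `miss_prob`, `bound` and the inputs.
#' @export
nn_error_bound <- function(field, spec, p, delta, reps = 10000L) {
  stopifnot(inherits(field, "population_field"), delta > 0)
  osc <- oscillation(field$f, p, delta, field$region)
  miss <- switch(spec$scheme,
                 URS = miss_prob_urs(field$region, p, delta, spec$n),
                 TSS = miss_prob_tss(field$region, p, delta, spec$k),
                 miss_prob_mc(spec, field$region, p, delta, reps))
  list(p = p, delta = delta, oscillation = osc,
       miss_prob = as.numeric(miss),
       miss_method = attr(miss, "method"),
       bound = osc + field$L * as.numeric(miss))
}

#' Second-moment bound on the miss probability
#'
#' Bounds the probability that the count of sampled locations inside the
#' `delta`-ball is zero using only the per-location hit probabilities
#' `q_i = Pr(location i falls in the ball)` and the pairwise joint hit
#' probabilities: the bound is `1 / (sum(q) + s - 1)` truncated at its
#' positive part (infinite when the denominator is not positive), where `s`
#' is the supremum over pairs of `joint / (q_i q_h)`. Under independent
#' selections with equal `q` it reduces to `1 / (n q)`.
#'
#' @param q Vector of per-location hit probabilities, all `> 0`.
#' @param joint Matrix of pairwise joint hit probabilities (off-diagonal
#'   entries used); defaults to independence, `q_i * q_h`.
#' @return The bound (possibly `Inf` when vacuous).
#' @export
miss_count_bound <- function(q, joint = NULL) {
  stopifnot(all(q > 0))
  n <- length(q)
  if (n < 2L) {
    sup_ratio <- 1
  } else {
    if (is.null(joint)) joint <- outer(q, q)
    stopifnot(is.matrix(joint), all(dim(joint) == n))
    ratio <- joint / outer(q, q)
    diag(ratio) <- -Inf
    sup_ratio <- max(ratio)
  }
  denom <- sum(q) + sup_ratio - 1
  if (denom <= 0) Inf else 1 / denom
}

#' Error bound under a Lipschitz field at rate n^(-1/2)
#'
#' For a field that is Lipschitz at `p` with constant `beta`, taking the
#' ball radius `delta = t / sqrt(n)` turns the pointwise bound into
#' `beta t / sqrt(n) + L * miss`. Under designs that guarantee a sampled
#' location within `t / sqrt(n)` of every point (TSS and SGS with
#' `t >= sqrt(2)` on the unit square) the miss term vanishes, giving the
#' `n^(-1/2)` consistency rate.
#'
#' @param beta Lipschitz constant at `p`.
#' @param t Radius multiplier, `> 0`.
#' @param n Sample size.
#' @param L Field bound.
#' @param miss_prob Miss probability at radius `t / sqrt(n)` (from
#'   [miss_prob_urs()], [miss_prob_tss()] or [miss_prob_mc()]).
#' @return The bound value.
#' @export
lipschitz_error_bound <- function(beta, t, n, L, miss_prob) {
  stopifnot(beta >= 0, t > 0, n >= 1, miss_prob >= 0, miss_prob <= 1)
  beta * t / sqrt(n) + L * as.numeric(miss_prob)
}

#' Monte-Carlo pointwise error of the NN interpolator
#'
#' Estimates the design expectation of the absolute error and the RMSE of
#' the NN map at target points by repeated sampling.
#'
#' @param field A [population_field()].
#' @param spec A continuous-design [scheme_spec()].
#' @param p Target locations (matrix or single `c(x, y)`).
#' @param reps Replications.
#' @return List with per-point `mae` (mean absolute error), `rmse`, `se_mae`
#'   and `reps`.
#' @export
pointwise_error_mc <- function(field, spec, p, reps = 1000L) {
  p <- as_points(p)
  truth <- field$f(p[, 1], p[, 2])
  errs <- matrix(NA_real_, reps, nrow(p))
  for (r in seq_len(reps)) {
    s <- draw_sample(spec, field)
    errs[r, ] <- nn_values(s$points[, 1], s$points[, 2], s$values,
                           p[, 1], p[, 2]) - truth
  }
  list(mae = colMeans(abs(errs)),
       rmse = sqrt(colMeans(errs^2)),
       se_mae = apply(abs(errs), 2, stats::sd) / sqrt(reps),
       reps = reps)
}

#' Monte-Carlo mean integrated absolute error of the NN map
#'
#' Estimates the integral over the region of the expected absolute
#' interpolation error by averaging, over replicated samples, the quadrature
#' of `|fhat - f|` on a regular grid. Map-level accuracy is robust to
#' discontinuities of the field along measure-zero sets, which inflate the
#' pointwise error only on a vanishing fraction of the grid.
#'
#' @param field A [population_field()].
#' @param spec A continuous-design [scheme_spec()].
#' @param reps Replications.
#' @param grid_n Side of the integration grid (cell centers).
#' @return List with `miae`, its Monte-Carlo `se`, `reps` and `grid_n`.
#' @export
miae_mc <- function(field, spec, reps = 200L, grid_n = 50L) {
  grid <- grid_spec(field$region, n = grid_n)
  centers <- grid_centers(grid)
  truth <- field$f(centers$x, centers$y)
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- draw_sample(spec, field)
    fhat <- nn_values(s$points[, 1], s$points[, 2], s$values,
                      centers$x, centers$y)
    vals[r] <- mean(abs(fhat - truth)) * field$region$area
  }
  list(miae = mean(vals), se = stats::sd(vals) / sqrt(reps),
       reps = reps, grid_n = grid_n)
}
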
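# Canonical test surfaces on the unit square.
#
# Three scalar fields bounded by L = 10 are used throughout the simulation
# harness to emulate spatial populations:
#   1: a smooth Lipschitz trend,  (C1/2) (sin^2 p1 + cos^2 p2 + p1)
#   2: a smooth oscillatory field, C2 sin(3 p1) sin^2(3 p2)
#   3: a field with a jump along the internal edges of the upper-right
#      quadrant:  C3 p1 p2 when min(p1, p2) <= 1/2, else C3 (1 + p1) p2
# The constants C1, C2, C3 rescale each surface so that its maximum over the
# unit square equals L = 10.  They are not hard-coded: they are obtained by a
# grid search refined by box-constrained local maximization, so any change to
# a surface definition propagates to its constant automatically.

# unnormalized surface bodies; vectorized over p1, p2
surface_raw <- function(id) {
  switch(as.character(id),
    "1" = function(p1, p2) 0.5 * (sin(p1)^2 + cos(p2)^2 + p1),
    "2" = function(p1, p2) sin(3 * p1) * sin(3 * p2)^2,
    "3" = function(p1, p2) ifelse(pmin(p1, p2) <= 0.5,
                                  p1 * p2, (1 + p1) * p2),
    stop("surface id must be 1, 2 or 3", call. = FALSE)
  )
}

# cache for the scaling constants (computed once per session)
.surface_cache <- new.env(parent = emptyenv())

#' Upper bound of the canonical surfaces
#'
#' All three canonical surfaces take values in `[0, surface_L()]`.
#' @return The number 10.
#' @export
surface_L <- function() 10

#' Scaling constants of the canonical surfaces
#'
#' Computes the constants `C1`, `C2`, `C3` that rescale each unnormalized
#' surface so its maximum over the unit square equals `L = 10`. Each constant
#' is `10 / m` where `m` is the surface maximum found by a grid search over
#' the unit square refined by box-constrained local maximization
#' ([stats::optim()] with `L-BFGS-B`).
#'
#' @param grid_n Side of the search grid used for the initial maximization.
#' @return Named numeric vector `c(C1 = ..., C2 = ..., C3 = ...)`.
#' @examples
#' derive_constants()["C3"]   # 5: the jump branch peaks at 2 in (1, 1)
#' @export
derive_constants <- function(grid_n = 401L) {
  key <- paste0("C_", grid_n)
  if (!is.null(.surface_cache[[key]])) return(.surface_cache[[key]])
  g <- seq(0, 1, length.out = grid_n)
  gx <- rep(g, times = grid_n)
  gy <- rep(g, each = grid_n)
  out <- vapply(1:3, function(id) {
    f <- surface_raw(id)
    v <- f(gx, gy)
    i <- which.max(v)
    start <- pmin(pmax(c(gx[i], gy[i]), 1e-9), 1 - 1e-9)
    # refine; surface 3 is discontinuous but its maximum sits strictly inside
    # the smooth upper-right branch, so local maximization is safe
    opt <- stats::optim(start, function(q) -f(q[1], q[2]),
                        method = "L-BFGS-B", lower = 0, upper = 1)
    m <- max(v[i], -opt$value)
    surface_L() / m
  }, numeric(1))
  names(out) <- c("C1", "C2", "C3")
  .surface_cache[[key]] <- out
  out
}

#' Evaluate a canonical surface
#'
#' Evaluates one of the three canonical test surfaces at planar locations in
#' the unit square. Values lie in `[0, 10]`; each surface attains the maximum
#' 10. Surface 3 is discontinuous exactly on the internal edges of the
#' upper-right quadrant (the segments `p1 = 1/2, p2 > 1/2` and
#' `p2 = 1/2, p1 > 1/2`); surfaces 1 and 2 are smooth.
#'
#' @param id Surface identifier: 1, 2 or 3.
#' @param x,y Coordinates in `[0, 1]` (vectorized, recycled to common
#'   length). Locations outside the unit square are an error.
#' @return Numeric vector of surface values.
#' @examples
#' eval_surface(3, 0.25, 0.25)        # 0.3125
#' eval_surface(2, pi / 6, pi / 6)    # 10, the global maximum
#' @export
eval_surface <- function(id, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (anyNA(x) || anyNA(y) ||
      any(x < 0 | x > 1 | y < 0 | y > 1)) {
    stop("canonical surfaces are defined on the unit square only",
         call. = FALSE)
  }
  C <- derive_constants()[[paste0("C", id)]]
  C * surface_raw(id)(x, y)
}

#' A canonical surface as a population field
#'
#' Wraps a canonical surface (or any user function) as a continuous
#' population: a bounded density `f` on a study region, the object being
#' mapped in the continuous setting.
#'
#' @param surface A surface id (1, 2, 3) or a function `f(x, y)` vectorized
#'   over coordinates.
#' @param region Study region; canonical ids require the unit square.
#' @param L Upper bound of the field (10 for the canonical surfaces).
#' @return Object of class `"population_field"` with elements `f` (the
#'   density function), `region` and `L`.
#' @export
population_field <- function(surface, region = study_region(), L = surface_L()) {
  stopifnot(inherits(region, "study_region"))
  if (is.function(surface)) {
    f <- surface
    label <- "custom"
  } else {
    id <- as.integer(surface)
    stopifnot(id %in% 1:3)
    if (region$xmin != 0 || region$xmax != 1 ||
        region$ymin != 0 || region$ymax != 1) {
      stop("canonical surfaces live on the unit square", call. = FALSE)
    }
    f <- function(x, y) eval_surface(id, x, y)
    label <- paste0("surface ", id)
  }
  structure(list(f = f, region = region, L = L, label = label),
            class = "population_field")
}

#' @export
print.population_field <- function(x, ...) {
  cat(sprintf("continuous population field (%s), bound L = %g\n",
              x$label, x$L))
  invisible(x)
}
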
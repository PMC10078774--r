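# Probabilistic sampling schemes for locations, areas and units.

#' Sampling-scheme specification
#'
#' A small descriptor of a spatial sampling design, reusable both for the
#' original sample selection and for bootstrap resampling (which must redraw
#' with the identical design).
#'
#' Schemes:
#' * `"URS"`   — uniform random sampling of `n` independent locations.
#' * `"TSS"`   — tessellation stratified sampling: `k` x `k` equal quadrats,
#'   one uniform location per quadrat (`n = k^2`).
#' * `"SGS"`   — systematic grid sampling: one uniform within-cell offset
#'   replicated across all `k^2` quadrats.
#' * `"SRSWOR"` — simple random sampling without replacement of `n` areas or
#'   units.
#' * `"OPSS"`  — one-per-stratum stratified sampling: the population grid is
#'   tiled by blocks of contiguous quadrats and one quadrat is selected
#'   uniformly and independently in each block.
#' * `"SYS"`   — systematic sampling: one within-block position drawn once
#'   and replicated across all blocks.
#' * `"THREEP"` — probability-proportional-to-prediction Poisson sampling:
#'   each unit enters independently with probability `pi_j = x_j / L_star`.
#'
#' @param scheme Scheme name (see above).
#' @param n Sample size (URS, SRSWOR).
#' @param k Tessellation side (TSS, SGS); `n = k^2`.
#' @param block Block shape `c(rows, cols)` of contiguous quadrats
#'   (OPSS, SYS); default `c(2, 5)`.
#' @param L_star 3P scaling constant (THREEP; realized size is random).
#' @return Object of class `"scheme_spec"`.
#' @examples
#' scheme_spec("TSS", k = 4)
#' @export
scheme_spec <- function(scheme = c("URS", "TSS", "SGS", "SRSWOR", "OPSS",
                                   "SYS", "THREEP"),
                        n = NULL, k = NULL, block = c(2L, 5L), L_star = 50) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("URS", "SRSWOR")) {
    stopifnot(!is.null(n), n >= 1)
    n <- as.integer(n)
  }
  if (scheme %in% c("TSS", "SGS")) {
    stopifnot(!is.null(k), k >= 1)
    k <- as.integer(k)
    n <- k * k
  }
  if (scheme %in% c("OPSS", "SYS")) {
    block <- as.integer(block)
    stopifnot(length(block) == 2L, all(block >= 1L))
  }
  structure(list(scheme = scheme, n = n, k = k, block = block,
                 L_star = L_star),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  extra <- switch(x$scheme,
    TSS = , SGS = sprintf(", k = %d (n = %d)", x$k, x$n),
    URS = , SRSWOR = sprintf(", n = %d", x$n),
    OPSS = , SYS = sprintf(", block %d x %d", x$block[1], x$block[2]),
    THREEP = sprintf(", L* = %g", x$L_star))
  cat(sprintf("sampling scheme %s%s\n", x$scheme, extra))
  invisible(x)
}

#' Serialize / deserialize a scheme specification
#'
#' @param spec A [scheme_spec()].
#' @param json A JSON string produced by `scheme_to_json()`.
#' @return `scheme_to_json()` returns a JSON string; `scheme_from_json()`
#'   the reconstructed `"scheme_spec"`.
#' @export
scheme_to_json <- function(spec) {
  stopifnot(inherits(spec, "scheme_spec"))
  jsonlite::toJSON(spec[!vapply(spec, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname scheme_to_json
#' @export
scheme_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  scheme_spec(x$scheme, n = x$n, k = x$k,
              block = if (!is.null(x$block)) x$block else c(2L, 5L),
              L_star = if (!is.null(x$L_star)) x$L_star else 50)
}

#' Uniform random sampling of locations
#'
#' Draws `n` independent uniform locations on the region.
#'
#' @param region A [study_region()].
#' @param n Number of locations.
#' @return An `n` x 2 matrix of coordinates.
#' @export
draw_urs <- function(region, n) {
  stopifnot(inherits(region, "study_region"), n >= 1)
  cbind(x = region$xmin + stats::runif(n) * region$width,
        y = region$ymin + stats::runif(n) * region$height)
}

# lower-left corners of the k x k tessellation cells, column-major over
# (col, row); cell (r, c) covers [x0+(c-1)sx, x0+c*sx) x [y0+(r-1)sy, y0+r*sy)
cell_origins <- function(region, k) {
  sx <- region$width / k
  sy <- region$height / k
  list(x0 = region$xmin + (rep(seq_len(k), times = k) - 1) * sx,
       y0 = region$ymin + (rep(seq_len(k), each = k) - 1) * sy,
       sx = sx, sy = sy)
}

#' Tessellation stratified sampling of locations
#'
#' Partitions the region into a `k` x `k` grid of equal quadrats and selects
#' one uniform location per quadrat, independently across quadrats. This is
#' the classical spatially balanced design of large-scale forest surveys: by
#' construction every point of the region has a sampled location within
#' `sqrt(2)` cell sides.
#'
#' @param region A [study_region()].
#' @param k Tessellation side; the sample has `n = k^2` locations.
#' @return An `n` x 2 matrix of coordinates, one row per cell.
#' @export
draw_tss <- function(region, k) {
  stopifnot(inherits(region, "study_region"), k >= 1)
  co <- cell_origins(region, k)
  n <- k * k
  cbind(x = co$x0 + stats::runif(n) * co$sx,
        y = co$y0 + stats::runif(n) * co$sy)
}

#' Systematic grid sampling of locations
#'
#' Draws a single uniform offset in one cell of the `k` x `k` tessellation
#' and replicates it across all cells: an aligned systematic (lattice)
#' sample of `n = k^2` locations.
#'
#' @inheritParams draw_tss
#' @return An `n` x 2 matrix of coordinates.
#' @export
draw_sgs <- function(region, k) {
  stopifnot(inherits(region, "study_region"), k >= 1)
  co <- cell_origins(region, k)
  ox <- stats::runif(1) * co$sx
  oy <- stats::runif(1) * co$sy
  cbind(x = co$x0 + ox, y = co$y0 + oy)
}

#' Simple random sampling without replacement
#'
#' @param N Population size.
#' @param n Sample size, `1 <= n <= N`.
#' @return Integer vector of `n` distinct indices.
#' @export
draw_srswor <- function(N, n) {
  stopifnot(N >= 1, n >= 1)
  if (n > N) stop("sample size exceeds population size", call. = FALSE)
  sample.int(N, n)
}

# block decomposition of a g x g grid by br x bc blocks; returns per-block
# index matrices (row-major population indexing: j = (row - 1) * g + col)
block_indices <- function(g, block) {
  br <- block[1]; bc <- block[2]
  if (g %% br != 0L || g %% bc != 0L) {
    stop(sprintf("block %d x %d does not tile a %d x %d grid", br, bc, g, g),
         call. = FALSE)
  }
  rows <- seq_len(g %/% br)
  cols <- seq_len(g %/% bc)
  blocks <- expand.grid(brow = rows, bcol = cols)
  lapply(seq_len(nrow(blocks)), function(b) {
    r0 <- (blocks$brow[b] - 1L) * br
    c0 <- (blocks$bcol[b] - 1L) * bc
    as.vector(outer((r0 + seq_len(br) - 1L) * g, c0 + seq_len(bc), `+`))
  })
}

#' One-per-stratum stratified sampling of a grid population
#'
#' Tiles the `g` x `g` population grid with blocks of contiguous quadrats and
#' selects one quadrat uniformly and independently within each block.
#'
#' @param g Grid side of the area (or unit) population.
#' @param block Block shape `c(rows, cols)`; must tile the grid exactly.
#' @return Integer vector of selected population indices (row-major), one
#'   per block; `n = g^2 / prod(block)`.
#' @export
draw_opss <- function(g, block = c(2L, 5L)) {
  blocks <- block_indices(g, as.integer(block))
  vapply(blocks, function(ix) ix[sample.int(length(ix), 1L)], integer(1))
}

#' Systematic sampling of a grid population
#'
#' Draws one within-block position uniformly and replicates it across all
#' blocks of the tiling.
#'
#' @inheritParams draw_opss
#' @return Integer vector of selected indices, one per block.
#' @export
draw_sys_blocks <- function(g, block = c(2L, 5L)) {
  blocks <- block_indices(g, as.integer(block))
  pos <- sample.int(length(blocks[[1]]), 1L)
  vapply(blocks, `[`, integer(1), pos)
}

#' Probability-proportional-to-prediction (3P) sampling
#'
#' Includes each unit independently with its inclusion probability; the
#' realized sample size is random (Poisson sampling). An empty realized
#' sample leaves the interpolator undefined, so empty draws are redrawn and
#' reported with a warning.
#'
#' @param pi Vector of inclusion probabilities in `(0, 1]`.
#' @return Integer vector of included unit indices.
#' @export
draw_threep <- function(pi) {
  stopifnot(all(pi > 0), all(pi <= 1))
  redraws <- 0L
  repeat {
    take <- stats::runif(length(pi)) < pi
    if (any(take)) break
    redraws <- redraws + 1L
  }
  if (redraws > 0L) {
    warning(sprintf("empty 3P sample redrawn %d time(s)", redraws),
            call. = FALSE)
  }
  which(take)
}

#' Draw a sample from a population under a scheme
#'
#' High-level front end pairing a [scheme_spec()] with a population of the
#' matching setting and returning the observed sample: locations and values
#' (plus predictions, inclusion probabilities and prediction errors under the
#' 3P design).
#'
#' Setting compatibility: URS/TSS/SGS sample locations from a continuous
#' [population_field()]; SRSWOR/OPSS/SYS sample areas from an
#' [area_population()] (identified by their centroids) or units from a
#' `"unit_population"`; THREEP samples units with their attached `pi`.
#'
#' @param spec A [scheme_spec()].
#' @param population A `"population_field"`, `"area_population"` or
#'   `"unit_population"`.
#' @return Object of class `"nn_sample"`: list with `points` (n x 2 matrix),
#'   `values`, `setting`, `spec`, and for finite settings `indices` (and for
#'   3P also `predictions`, `pi`, `errors`).
#' @export
draw_sample <- function(spec, population) {
  stopifnot(inherits(spec, "scheme_spec"))
  if (inherits(population, "population_field")) {
    if (!spec$scheme %in% c("URS", "TSS", "SGS")) {
      stop(sprintf("%s cannot sample a continuous population", spec$scheme),
           call. = FALSE)
    }
    pts <- switch(spec$scheme,
                  URS = draw_urs(population$region, spec$n),
                  TSS = draw_tss(population$region, spec$k),
                  SGS = draw_sgs(population$region, spec$k))
    out <- list(points = pts, values = population$f(pts[, 1], pts[, 2]),
                setting = "continuous", spec = spec)
  } else if (inherits(population, "area_population")) {
    if (!spec$scheme %in% c("SRSWOR", "OPSS", "SYS")) {
      stop(sprintf("%s cannot sample an area population", spec$scheme),
           call. = FALSE)
    }
    N <- nrow(population$areas)
    idx <- switch(spec$scheme,
                  SRSWOR = draw_srswor(N, spec$n),
                  OPSS = draw_opss(population$g, spec$block),
                  SYS = draw_sys_blocks(population$g, spec$block))
    out <- list(points = cbind(x = population$areas$cx[idx],
                               y = population$areas$cy[idx]),
                values = population$areas$density[idx],
                indices = idx, setting = "areas", spec = spec)
  } else if (inherits(population, "unit_population")) {
    if (!spec$scheme %in% c("THREEP", "SRSWOR")) {
      stop(sprintf("%s cannot sample a unit population", spec$scheme),
           call. = FALSE)
    }
    u <- population$units
    if (spec$scheme == "THREEP") {
      if (is.null(u$pi)) stop("3P needs inclusion probabilities; add predictions first",
                              call. = FALSE)
      idx <- draw_threep(u$pi)
    } else {
      idx <- draw_srswor(nrow(u), spec$n)
    }
    out <- list(points = cbind(x = u$x[idx], y = u$y[idx]),
                values = u$value[idx], indices = idx,
                setting = "units", spec = spec)
    if (!is.null(u$prediction)) {
      out$predictions <- u$prediction[idx]
      out$pi <- u$pi[idx]
      out$errors <- u$value[idx] - u$prediction[idx]
    }
  } else {
    stop("unknown population type", call. = FALSE)
  }
  structure(out, class = "nn_sample")
}

#' @export
print.nn_sample <- function(x, ...) {
  cat(sprintf("sample of %d %s under %s\n", nrow(x$points),
              switch(x$setting, continuous = "locations", areas = "areas",
                     units = "units"),
              x$spec$scheme))
  invisible(x)
}

#' Build a sample object from locations and values
#'
#' Constructs an `"nn_sample"` directly from observed coordinates and values,
#' as when reading field data from a file rather than simulating.
#'
#' @param x,y Coordinates of the sampled locations.
#' @param values Observed values.
#' @param spec Optional [scheme_spec()] echo (needed for bootstrapping).
#' @param setting Population setting of the sample.
#' @return An `"nn_sample"`.
#' @export
as_nn_sample <- function(x, y, values, spec = NULL,
                         setting = c("continuous", "areas", "units")) {
  setting <- match.arg(setting)
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n, n >= 1)
  structure(list(points = cbind(x = as.numeric(x), y = as.numeric(y)),
                 values = as.numeric(values), setting = setting, spec = spec),
            class = "nn_sample")
}
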
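# Regular evaluation grids.

#' Regular evaluation grid over a region
#'
#' Describes a regular grid of square (or rectangular) cells covering a study
#' region, used as the evaluation support of continuous-setting maps and as
#' the tessellation of a survey region into quadrats. Cells are indexed
#' row-major from the lower-left corner; cell `(i, j)` covers the half-open
#' rectangle `[x0 + (j-1) sx, x0 + j sx) x [y0 + (i-1) sy, y0 + i sy)`.
#'
#' Exactly one of `n` (cells per side) or `cellsize` must be given; with
#' `cellsize` the region extent must be an exact multiple of it.
#'
#' @param region A [study_region()].
#' @param n Number of cells per side: a single value or `c(nx, ny)`.
#' @param cellsize Side of a square cell, in region units.
#' @return Object of class `"grid_spec"` with `ncols`, `nrows`, `cellsize`
#'   (x and y), and the lower-left corner.
#' @examples
#' # a square 4900-ha region (7000 m sides) at 200 m resolution: 1225 quadrats
#' g <- grid_spec(study_region(0, 7000, 0, 7000), cellsize = 200)
#' g$ncols * g$nrows
#' @export
grid_spec <- function(region = study_region(), n = NULL, cellsize = NULL) {
  stopifnot(inherits(region, "study_region"))
  if (is.null(n) == is.null(cellsize)) {
    stop("give exactly one of n or cellsize", call. = FALSE)
  }
  if (!is.null(n)) {
    n <- as.integer(rep_len(n, 2L))
    stopifnot(all(n >= 1L))
    ncols <- n[1]; nrows <- n[2]
    csx <- region$width / ncols
    csy <- region$height / nrows
  } else {
    stopifnot(cellsize > 0)
    ncols <- region$width / cellsize
    nrows <- region$height / cellsize
    if (abs(ncols - round(ncols)) > 1e-9 || abs(nrows - round(nrows)) > 1e-9) {
      stop("cellsize must tile the region exactly", call. = FALSE)
    }
    ncols <- as.integer(round(ncols)); nrows <- as.integer(round(nrows))
    csx <- csy <- cellsize
  }
  structure(list(ncols = ncols, nrows = nrows,
                 cellsize_x = csx, cellsize_y = csy,
                 xllcorner = region$xmin, yllcorner = region$ymin,
                 region = region),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d cells of %g x %g\n",
              x$ncols, x$nrows, x$cellsize_x, x$cellsize_y))
  invisible(x)
}

#' Cell centers of a regular grid
#'
#' @param grid A [grid_spec()].
#' @return Data frame with `x`, `y` cell-center coordinates, row-major from
#'   the lower-left cell.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cx <- grid$xllcorner + (seq_len(grid$ncols) - 0.5) * grid$cellsize_x
  cy <- grid$yllcorner + (seq_len(grid$nrows) - 0.5) * grid$cellsize_y
  data.frame(x = rep(cx, times = grid$nrows),
             y = rep(cy, each = grid$ncols))
}
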
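#' Rectangular study region
#'
#' Constructs an axis-aligned rectangular study region, the planar domain on
#' which populations live and from which locations are sampled. The default is
#' the unit square, the domain of the three canonical test surfaces.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds; width and height must be
#'   strictly positive.
#'
#' @return An object of class `"study_region"`: a list with the four bounds,
#'   `width`, `height` and `area` (the Lebesgue measure of the rectangle).
#' @examples
#' b <- study_region()          # unit square
#' b$area                       # 1
#' @export
study_region <- function(xmin = 0, xmax = 1, ymin = 0, ymax = 1) {
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin),
            is.numeric(ymax), length(xmin) == 1L, length(xmax) == 1L,
            length(ymin) == 1L, length(ymax) == 1L)
  if (!(xmax > xmin && ymax > ymin)) {
    stop("study region must have positive width and height", call. = FALSE)
  }
  structure(
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         width = xmax - xmin, height = ymax - ymin,
         area = (xmax - xmin) * (ymax - ymin)),
    class = "study_region"
  )
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("study region [%g, %g] x [%g, %g], area %g\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$area))
  invisible(x)
}

#' Test whether points lie inside a study region
#'
#' @param region A [study_region()].
#' @param x,y Coordinate vectors (recycled to common length).
#' @return Logical vector.
#' @export
in_region <- function(region, x, y) {
  stopifnot(inherits(region, "study_region"))
  x >= region$xmin & x <= region$xmax & y >= region$ymin & y <= region$ymax
}

#' Diameter of a study region
#'
#' Length of the rectangle diagonal: the largest distance between two points
#' of the region.
#'
#' @param region A [study_region()].
#' @return A single number.
#' @export
region_diameter <- function(region) {
  stopifnot(inherits(region, "study_region"))
  sqrt(region$width^2 + region$height^2)
}

# coerce a two-column matrix / data.frame / length-2 vector to an n x 2 matrix
as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c(1L, 2L)])
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have exactly two coordinates",
                              call. = FALSE)
    p <- matrix(p, ncol = 2L)
  }
  if (ncol(p) < 2L) stop("points need x and y columns", call. = FALSE)
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}
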
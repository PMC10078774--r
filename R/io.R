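# Point tables and raster export.

#' Read a table of sampled points from a delimited file
#'
#' Reads planar sampled locations with observed values (and optionally
#' predictions and inclusion probabilities) from a delimited text file and
#' validates it: required columns must be present and every cell numeric and
#' finite; offending rows are reported with their line numbers.
#'
#' @param path File path.
#' @param columns Named character vector mapping the roles `x`, `y`, `value`
#'   (and optionally `prediction`, `pi`) to column names in the file.
#' @param sep Field delimiter.
#' @return A data frame with standardized columns `x`, `y`, `value` (and
#'   `prediction`, `pi` when mapped), of class `"point_table"`.
#' @export
read_points_csv <- function(path,
                            columns = c(x = "x", y = "y", value = "value"),
                            sep = ",") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  need <- c("x", "y", "value")
  if (!all(need %in% names(columns))) {
    stop("columns must map at least x, y and value", call. = FALSE)
  }
  opt <- intersect(c("prediction", "pi"), names(columns))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("file contains a header but no data rows",
                            call. = FALSE)
  missing <- setdiff(unname(columns[c(need, opt)]), names(raw))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- vector("list", 0L)
  for (role in c(need, opt)) {
    col <- raw[[columns[[role]]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite '%s' at data line(s) %s",
                   columns[[role]],
                   paste(utils::head(bad, 5L) + 1L, collapse = ", ")),
           call. = FALSE)
    }
    out[[role]] <- num
  }
  out <- as.data.frame(out)
  class(out) <- c("point_table", "data.frame")
  out
}

#' Write a table of points to CSV
#'
#' @param points A data frame with at least `x`, `y` columns (a
#'   `"point_table"`, `"estimated_map"` or sample export).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a sample realization as a point table
#'
#' @param sample An `"nn_sample"`.
#' @return A `"point_table"` data frame (x, y, value, plus prediction/pi for
#'   3P samples).
#' @export
sample_points <- function(sample) {
  stopifnot(inherits(sample, "nn_sample"))
  out <- data.frame(x = sample$points[, 1], y = sample$points[, 2],
                    value = sample$values)
  if (!is.null(sample$predictions)) {
    out$prediction <- sample$predictions
    out$pi <- sample$pi
  }
  class(out) <- c("point_table", "data.frame")
  out
}

#' Write a gridded map to disk
#'
#' Writes an estimated map evaluated on a regular grid either as CSV
#' (`x,y,value` rows) or as an ESRI ASCII grid raster with the standard
#' header keywords (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) and rows ordered from the top of the region down.
#'
#' @param map An `"estimated_map"` built on a [grid_spec()] (required for
#'   `"esri_ascii"`), or any point data frame for `"csv"`.
#' @param path Output path.
#' @param format `"csv"` or `"esri_ascii"`.
#' @return The path, invisibly.
#' @export
write_grid <- function(map, path, format = c("csv", "esri_ascii")) {
  format <- match.arg(format)
  if (format == "csv") return(write_points_csv(map, path))
  grid <- attr(map, "grid")
  if (is.null(grid)) {
    stop("esri_ascii needs a map evaluated on a grid_spec", call. = FALSE)
  }
  if (abs(grid$cellsize_x - grid$cellsize_y) > 1e-12 * grid$cellsize_x) {
    stop("esri_ascii needs square cells", call. = FALSE)
  }
  m <- matrix(map$value, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$xllcorner),
               sprintf("yllcorner %.10g", grid$yllcorner),
               sprintf("cellsize %.10g", grid$cellsize_x),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(grid$nrows))) {   # top row first
    writeLines(paste(formatC(m[i, ], format = "g", digits = 15),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Path of a file written by [write_grid()] (or any conforming
#'   ESRI ASCII grid).
#' @return An `"estimated_map"` on the corresponding [grid_spec()], with
#'   cell-center coordinates.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != ncols * nrows) {
    stop("grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]   # back to bottom-up rows
  cs <- hdr$cellsize
  region <- study_region(hdr$xllcorner, hdr$xllcorner + ncols * cs,
                         hdr$yllcorner, hdr$yllcorner + nrows * cs)
  grid <- grid_spec(region, n = c(ncols, nrows))
  centers <- grid_centers(grid)
  structure(data.frame(x = centers$x, y = centers$y,
                       value = as.vector(t(m))),
            grid = grid, setting = "continuous",
            class = c("estimated_map", "data.frame"))
}
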
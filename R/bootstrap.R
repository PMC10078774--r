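# Pseudopopulation bootstrap estimation of the interpolator's RMSE.
#
# The estimated map is taken as a complete surrogate population; bootstrap
# samples are redrawn from it with exactly the design used for the original
# sample, each is NN-interpolated reading values from the estimated map, and
# the root mean squared deviation of the bootstrap maps from the estimated
# map estimates the RMSE of the interpolator.

#' Pseudopopulation behind an estimated map
#'
#' Converts an estimated map into a population object of the same setting,
#' usable as a complete sampling frame for bootstrap resampling:
#' * continuous — a [population_field()] equal to the Voronoi
#'   (nearest-original-sample) field of the original sample, evaluated
#'   exactly rather than through a display grid;
#' * areas — an [area_population()] whose densities are the mapped densities;
#' * units — a `"unit_population"` whose values are the mapped values
#'   (predictions and inclusion probabilities are carried over).
#'
#' @param map An `"estimated_map"` covering the full support.
#' @param tie_tol See [nn_interpolate()].
#' @return A population object of the matching class.
#' @export
build_pseudopopulation <- function(map, tie_tol = 1e-9) {
  stopifnot(inherits(map, "estimated_map"))
  setting <- attr(map, "setting")
  if (setting == "continuous") {
    s <- attr(map, "sample")
    if (!inherits(s, "nn_sample")) {
      stop("continuous map lacks its generating sample", call. = FALSE)
    }
    sx <- s$points[, 1]; sy <- s$points[, 2]; sv <- s$values
    region <- if (!is.null(attr(map, "grid"))) attr(map, "grid")$region
              else study_region(min(sx), max(max(sx), min(sx) + 1),
                                min(sy), max(max(sy), min(sy) + 1))
    population_field(function(x, y) nn_values(sx, sy, sv, x, y, tie_tol),
                     region = region, L = max(sv))
  } else if (setting == "areas") {
    pop <- attr(map, "population")
    if (is.null(pop) || nrow(map) != nrow(pop$areas)) {
      stop("area map must cover every area of its population", call. = FALSE)
    }
    pop$areas$density <- map$value
    pop$areas$total <- map$value * pop$cell_area
    pop
  } else {
    pop <- attr(map, "population")
    if (is.null(pop) || nrow(map) != nrow(pop$units)) {
      stop("unit map must cover every unit of its population", call. = FALSE)
    }
    pop$units$value <- map$value
    pop
  }
}

# draw M continuous-design samples at once; returns list(x, y) of length M*n
# vectors, replicate m occupying rows (m-1)*n + 1 ... m*n
draw_many_continuous <- function(spec, region, M) {
  n <- spec$n
  if (spec$scheme == "URS") {
    x <- region$xmin + stats::runif(M * n) * region$width
    y <- region$ymin + stats::runif(M * n) * region$height
  } else if (spec$scheme == "TSS") {
    co <- cell_origins(region, spec$k)
    x <- rep(co$x0, M) + stats::runif(M * n) * co$sx
    y <- rep(co$y0, M) + stats::runif(M * n) * co$sy
  } else if (spec$scheme == "SGS") {
    co <- cell_origins(region, spec$k)
    ox <- rep(stats::runif(M) * co$sx, each = n)
    oy <- rep(stats::runif(M) * co$sy, each = n)
    x <- rep(co$x0, M) + ox
    y <- rep(co$y0, M) + oy
  } else {
    stop("not a continuous design", call. = FALSE)
  }
  list(x = x, y = y, n = n)
}

#' Bootstrap RMSE of the NN interpolator
#'
#' Estimates the root mean squared error of the estimated map at support
#' points by the pseudopopulation bootstrap: `M` samples are redrawn from
#' the pseudopopulation of the map with the design of the original sample,
#' each is NN-interpolated, and the RMSE estimate at `p` is the root mean
#' squared deviation of the `M` bootstrap maps from the estimated map at
#' `p`.
#'
#' @param map An `"estimated_map"`. Continuous maps must carry their
#'   generating sample and a [scheme_spec()] (as produced by
#'   [draw_sample()] + [nn_interpolate()]); finite maps carry their
#'   population.
#' @param spec The sampling design; must be identical to the design of the
#'   original sample. Defaults to the design stored with the map.
#' @param M Number of bootstrap samples.
#' @param query Support points at which to estimate the RMSE (continuous
#'   setting): matrix of coordinates or [grid_spec()]; defaults to the map's
#'   own support. Ignored for finite settings, which always use the full
#'   support.
#' @param tie_tol See [nn_interpolate()].
#' @return Object of class `"bootstrap_report"`: a data frame with columns
#'   `x`, `y`, `fhat`, `rmse_star` and `mean_star` (the per-point mean of
#'   the bootstrap values), with `M` and the scheme as attributes.
#' @export
bootstrap_rmse <- function(map, spec = NULL, M = 1000L, query = NULL,
                           tie_tol = 1e-9) {
  stopifnot(inherits(map, "estimated_map"), M >= 1)
  setting <- attr(map, "setting")
  if (is.null(spec)) {
    s <- attr(map, "sample")
    spec <- if (inherits(s, "nn_sample")) s$spec else NULL
  }
  if (is.null(spec)) stop("no sampling design available for resampling",
                          call. = FALSE)
  if (setting == "continuous") {
    if (!spec$scheme %in% c("URS", "TSS", "SGS")) {
      stop("design does not match the continuous setting", call. = FALSE)
    }
    boot_continuous_rmse(map, spec, M, query, tie_tol)
  } else if (setting == "areas") {
    if (!spec$scheme %in% c("SRSWOR", "OPSS", "SYS")) {
      stop("design does not match the area setting", call. = FALSE)
    }
    boot_finite_rmse(map, spec, M, tie_tol)
  } else {
    boot_finite_rmse(map, spec, M, tie_tol)
  }
}

boot_continuous_rmse <- function(map, spec, M, query, tie_tol) {
  s <- attr(map, "sample")
  sx <- s$points[, 1]; sy <- s$points[, 2]; sv <- s$values
  region <- if (!is.null(attr(map, "grid"))) attr(map, "grid")$region
            else study_region()
  if (is.null(query)) {
    q <- list(x = map$x, y = map$y)
  } else {
    q <- query_points(query)
  }
  fhat <- nn_values(sx, sy, sv, q$x, q$y, tie_tol)
  bp <- draw_many_continuous(spec, region, M)
  # bootstrap observations come from the exact Voronoi field of the
  # original sample, not from a display grid
  pv <- nn_values(sx, sy, sv, bp$x, bp$y, tie_tol)
  n <- bp$n
  nq <- length(q$x)
  rmse <- numeric(nq)
  mstar <- numeric(nq)
  for (j in seq_len(nq)) {
    d <- sqrt((bp$x - q$x[j])^2 + (bp$y - q$y[j])^2)
    D <- matrix(d, nrow = n)                    # replicate per column
    dmin <- apply(D, 2L, min)                   # per-replicate minimum
    H <- D <= rep(dmin + tie_tol, each = n)
    PV <- matrix(pv, nrow = n)
    fstar <- colSums(PV * H) / colSums(H)
    rmse[j] <- sqrt(mean((fstar - fhat[j])^2))
    mstar[j] <- mean(fstar)
  }
  structure(data.frame(x = q$x, y = q$y, fhat = fhat,
                       rmse_star = rmse, mean_star = mstar),
            M = M, spec = spec, setting = "continuous",
            class = c("bootstrap_report", "data.frame"))
}

boot_finite_rmse <- function(map, spec, M, tie_tol) {
  pseudo <- build_pseudopopulation(map, tie_tol)
  setting <- attr(map, "setting")
  if (setting == "areas") {
    a <- pseudo$areas
    px <- a$cx; py <- a$cy; pvals <- a$density
  } else {
    u <- pseudo$units
    px <- u$x; py <- u$y; pvals <- u$value
  }
  N <- length(pvals)
  acc <- numeric(N); acc2 <- numeric(N)
  for (m in seq_len(M)) {
    idx <- switch(spec$scheme,
                  SRSWOR = draw_srswor(N, spec$n),
                  OPSS = draw_opss(pseudo$g, spec$block),
                  SYS = draw_sys_blocks(pseudo$g, spec$block),
                  THREEP = draw_threep(pseudo$units$pi))
    fstar <- nn_values(px[idx], py[idx], pvals[idx], px, py, tie_tol)
    acc <- acc + fstar
    acc2 <- acc2 + (fstar - pvals)^2
  }
  structure(data.frame(x = px, y = py, fhat = pvals,
                       rmse_star = sqrt(acc2 / M), mean_star = acc / M),
            M = M, spec = spec, setting = setting,
            class = c("bootstrap_report", "data.frame"))
}

#' Bootstrap RMSE under 3P sampling with residual interpolation
#'
#' Pseudopopulation bootstrap for the residual workflow of
#' probability-proportional-to-prediction sampling: the pseudopopulation
#' carries the reconstructed values `yhat`; each bootstrap replicate redraws
#' a 3P sample with the original (frame-level) inclusion probabilities,
#' interpolates the pseudo prediction errors `yhat - x`, rebuilds the
#' bootstrap map as `x + ehat*`, and the RMSE estimate per unit is the root
#' mean squared deviation from `yhat`.
#'
#' @param map An `"estimated_map"` of reconstructed values from
#'   [residual_interpolate()] (its population must carry `prediction` and
#'   `pi` for every unit).
#' @param M Number of bootstrap samples.
#' @param tie_tol See [nn_interpolate()].
#' @return A `"bootstrap_report"` over all units.
#' @export
threep_bootstrap_rmse <- function(map, M = 1000L, tie_tol = 1e-9) {
  stopifnot(inherits(map, "estimated_map"), M >= 1)
  pop <- attr(map, "population")
  if (is.null(pop) || is.null(pop$units$prediction) || is.null(pop$units$pi)) {
    stop("3P bootstrap needs predictions and inclusion probabilities for all units",
         call. = FALSE)
  }
  u <- pop$units
  yhat <- map$value
  pseudo_err <- yhat - u$prediction
  N <- nrow(u)
  acc <- numeric(N); acc2 <- numeric(N)
  for (m in seq_len(M)) {
    idx <- draw_threep(u$pi)
    ehat <- nn_values(u$x[idx], u$y[idx], pseudo_err[idx], u$x, u$y, tie_tol)
    ystar <- u$prediction + ehat
    acc <- acc + ystar
    acc2 <- acc2 + (ystar - yhat)^2
  }
  structure(data.frame(x = u$x, y = u$y, fhat = yhat,
                       rmse_star = sqrt(acc2 / M), mean_star = acc / M),
            M = M, spec = scheme_spec("THREEP", L_star = pop$L_star %||% 50),
            setting = "units",
            class = c("bootstrap_report", "data.frame"))
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap RMSE report: %d support points, M = %d, rmse* in [%g, %g]\n",
              nrow(x), attr(x, "M"), min(x$rmse_star), max(x$rmse_star)))
  invisible(x)
}
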
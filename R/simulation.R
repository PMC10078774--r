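# Monte-Carlo evaluation of the NN interpolator and its bootstrap RMSE
# estimator: per-support-point absolute bias, RMSE and the ratio of the
# expected bootstrap RMSE to the Monte-Carlo RMSE, with min/avg/max
# summaries over the support.

#' Monte-Carlo study configuration
#'
#' Bundles a population, a sampling design and Monte-Carlo sizes into one
#' reproducible configuration.
#'
#' @param setting `"continuous"`, `"areas"` or `"units"`.
#' @param surface Surface id (1, 2, 3) or a vectorized function `f(x, y)`.
#' @param spec A [scheme_spec()] compatible with the setting
#'   (URS/TSS/SGS for continuous, SRSWOR/OPSS/SYS for areas, THREEP for
#'   units).
#' @param R Number of sampling replications.
#' @param M Bootstrap samples per replication; `M = 0` disables the
#'   bootstrap.
#' @param grid_n Evaluation grid side for continuous maps.
#' @param g Area-population grid side (areas setting).
#' @param pattern,size Spatial pattern and population size (units setting).
#' @param l,rho,L_star Truncation threshold, maximum relative prediction
#'   error and 3P scaling constant (units setting).
#' @param seed Master seed; every replication derives its own seed from it,
#'   the configuration tag and the replication index, so any single
#'   replication can be reproduced in isolation.
#' @return Object of class `"mc_config"`.
#' @export
mc_config <- function(setting = c("continuous", "areas", "units"),
                      surface = 1, spec = scheme_spec("TSS", k = 4),
                      R = 500L, M = 0L, grid_n = 25L, g = 10L,
                      pattern = "random", size = 500L,
                      l = 4, rho = 0.10, L_star = 50, seed = 1L) {
  setting <- match.arg(setting)
  ok <- switch(setting,
               continuous = spec$scheme %in% c("URS", "TSS", "SGS"),
               areas = spec$scheme %in% c("SRSWOR", "OPSS", "SYS"),
               units = spec$scheme == "THREEP")
  if (!ok) {
    stop(sprintf("scheme %s is incompatible with the %s setting",
                 spec$scheme, setting), call. = FALSE)
  }
  stopifnot(R >= 1, M >= 0)
  structure(list(setting = setting, surface = surface, spec = spec,
                 R = as.integer(R), M = as.integer(M),
                 grid_n = as.integer(grid_n), g = as.integer(g),
                 pattern = pattern, size = as.integer(size),
                 l = l, rho = rho, L_star = L_star,
                 seed = as.integer(seed)),
            class = "mc_config")
}

# deterministic small hash of a configuration tag
tag_hash <- function(tag) {
  v <- utf8ToInt(tag)
  sum(v * seq_along(v)) %% 99991L
}

# per-replication seed: master + configuration + replication index
rep_seed <- function(master, tag, r) {
  (as.integer(master) %% 100003L) * 20011L + tag_hash(tag) * 101L + r
}

config_tag <- function(config) {
  paste(config$setting,
        if (is.function(config$surface)) "fn" else config$surface,
        config$spec$scheme, config$spec$n %||% "",
        config$g, config$pattern, config$size, sep = "_")
}

# build population, support and truth for a configuration
setup_population <- function(config) {
  if (config$setting == "continuous") {
    field <- population_field(config$surface)
    grid <- grid_spec(field$region, n = config$grid_n)
    centers <- grid_centers(grid)
    list(population = field, grid = grid,
         x = centers$x, y = centers$y,
         truth = field$f(centers$x, centers$y))
  } else if (config$setting == "areas") {
    pop <- area_population(config$surface, g = config$g)
    list(population = pop, x = pop$areas$cx, y = pop$areas$cy,
         truth = pop$areas$density)
  } else {
    set.seed(rep_seed(config$seed, paste0(config_tag(config), "_pop"), 0L))
    pops <- unit_pattern(config$pattern, sizes = config$size)
    pop <- assign_surface_values(pops[[1]], config$surface)
    pop <- truncate_units(pop, config$l)
    pop <- add_predictions(pop, rho = config$rho, l = config$l,
                           L = pop$L, L_star = config$L_star)
    list(population = pop, x = pop$units$x, y = pop$units$y,
         truth = pop$units$value)
  }
}

# one replication: sample, map, optional bootstrap rmse* at the support
run_one <- function(config, setup) {
  if (config$setting == "continuous") {
    s <- draw_sample(config$spec, setup$population)
    map <- nn_interpolate(s, setup$grid)
    rs <- if (config$M > 0)
      bootstrap_rmse(map, config$spec, M = config$M)$rmse_star
  } else if (config$setting == "areas") {
    s <- draw_sample(config$spec, setup$population)
    map <- nn_map_areas(s$indices, setup$population)
    rs <- if (config$M > 0)
      bootstrap_rmse(map, config$spec, M = config$M)$rmse_star
  } else {
    s <- draw_sample(config$spec, setup$population)
    map <- residual_interpolate(s$indices, setup$population)
    rs <- if (config$M > 0)
      threep_bootstrap_rmse(map, M = config$M)$rmse_star
  }
  list(err = map$value - setup$truth, rmse_star = rs)
}

#' Run the Monte-Carlo replications of a configuration
#'
#' Replicates sampling and interpolation `R` times (with an `M`-sample
#' pseudopopulation bootstrap per replication when `M > 0`), accumulating at
#' every support point the absolute bias `|mean error|`, the RMSE and, when
#' bootstrapped, the ratio of the mean bootstrap RMSE to the Monte-Carlo
#' RMSE. The evaluation support is the regular grid (continuous), the area
#' centroids or the unit locations; the units setting uses the 3P residual
#' workflow.
#'
#' @param config An [mc_config()].
#' @return Object of class `"mc_summary"`: list with `per_point` (data frame
#'   `x`, `y`, `truth`, `abs_bias`, `rmse`, `variance`, and when
#'   bootstrapped `mean_rmse_star`, `ratio`), `summary` (min/avg/max of each
#'   indicator over the support, ratios excluding undefined points), and
#'   `undefined_ratios` (count of support points with zero Monte-Carlo
#'   RMSE, where the ratio is undefined).
#' @export
run_replications <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  setup <- setup_population(config)
  tag <- config_tag(config)
  np <- length(setup$truth)
  sum_e <- numeric(np); sum_e2 <- numeric(np); sum_rs <- numeric(np)
  for (r in seq_len(config$R)) {
    set.seed(rep_seed(config$seed, tag, r))
    one <- run_one(config, setup)
    sum_e <- sum_e + one$err
    sum_e2 <- sum_e2 + one$err^2
    if (config$M > 0) sum_rs <- sum_rs + one$rmse_star
  }
  mean_e <- sum_e / config$R
  msqe <- sum_e2 / config$R
  per_point <- data.frame(x = setup$x, y = setup$y, truth = setup$truth,
                          abs_bias = abs(mean_e),
                          rmse = sqrt(msqe),
                          variance = pmax(msqe - mean_e^2, 0))
  undefined <- 0L
  if (config$M > 0) {
    per_point$mean_rmse_star <- sum_rs / config$R
    defined <- per_point$rmse > 0
    undefined <- sum(!defined)
    per_point$ratio <- ifelse(defined,
                              per_point$mean_rmse_star / per_point$rmse, NA)
  }
  indicators <- c("abs_bias", "rmse", if (config$M > 0) "ratio")
  summ <- do.call(rbind, lapply(indicators, function(ind) {
    v <- per_point[[ind]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      data.frame(indicator = ind, min = NA_real_, avg = NA_real_,
                 max = NA_real_)
    } else {
      data.frame(indicator = ind, min = min(v), avg = mean(v), max = max(v))
    }
  }))
  structure(list(per_point = per_point, summary = summ,
                 undefined_ratios = undefined, config = config),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo summary: %s setting, %s, R = %d, M = %d\n",
              cfg$setting, cfg$spec$scheme, cfg$R, cfg$M))
  print(x$summary, row.names = FALSE)
  if (x$undefined_ratios > 0) {
    cat(sprintf("(%d support points with zero RMSE excluded from ratios)\n",
                x$undefined_ratios))
  }
  invisible(x)
}

#' Bootstrap-calibration table of a configuration
#'
#' Convenience wrapper around [run_replications()] that requires the
#' bootstrap to be enabled, so the returned summary includes the per-point
#' ratio of the expected bootstrap RMSE to the Monte-Carlo RMSE.
#'
#' @param config An [mc_config()] with `M >= 1`.
#' @return An `"mc_summary"` including ratio rows.
#' @export
ratio_table <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  if (config$M < 1) stop("ratio_table needs a bootstrap (M >= 1)",
                         call. = FALSE)
  run_replications(config)
}

#' Write a Monte-Carlo summary as CSV
#'
#' Writes the min/avg/max summary rows (and optionally the per-point table)
#' in a flat CSV layout.
#'
#' @param summary An `"mc_summary"`.
#' @param path Output file.
#' @param per_point Also write the per-point table alongside (same path with
#'   suffix `_points`).
#' @return The path, invisibly.
#' @export
write_mc_summary <- function(summary, path, per_point = FALSE) {
  stopifnot(inherits(summary, "mc_summary"))
  utils::write.csv(summary$summary, path, row.names = FALSE, quote = FALSE)
  if (per_point) {
    pp <- sub("(\\.[^.]+)?$", "_points\\1", path)
    utils::write.csv(summary$per_point, pp, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Full factorial Monte-Carlo study
#'
#' Runs the full population x scheme x size factorial: three canonical
#' surfaces crossed with URS/TSS/SGS and a tessellation ladder (continuous),
#' SRSWOR/OPSS/SYS on growing area grids with a 10% sampling fraction
#' (areas), and 3P residual mapping of the four unit patterns. Two presets
#' are provided: `"desk"` (R = 500 replications, M = 100 bootstrap samples,
#' the two smallest sizes of each ladder, a 25 x 25 continuous evaluation
#' grid) runs in desk time; `"paper"` (R = 10000, M = 1000, all sizes,
#' 100 x 100 grid) is the cluster-scale design and emits a cost warning.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Master seed.
#' @param settings Subset of settings to run.
#' @param surfaces Subset of surfaces.
#' @param R,M Optional overrides of the preset sizes.
#' @return Named list of `"mc_summary"` objects, one per configuration; for
#'   the units setting each summary also carries the expected sampling
#'   fraction of its population in attribute `"sampling_fraction"`.
#' @export
full_study <- function(preset = c("desk", "paper"), seed = 1L,
                       settings = c("continuous", "areas", "units"),
                       surfaces = 1:3, R = NULL, M = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    warning("paper preset: R = 10000 x M = 1000 is a cluster-scale workload",
            call. = FALSE)
  }
  R <- R %||% if (preset == "desk") 500L else 10000L
  M <- M %||% if (preset == "desk") 100L else 1000L
  grid_n <- if (preset == "desk") 25L else 100L
  ks <- if (preset == "desk") c(4L, 6L) else c(4L, 6L, 8L, 10L)
  gs <- if (preset == "desk") c(10L, 20L) else c(10L, 20L, 30L, 40L)
  sizes <- if (preset == "desk") c(500L, 1000L) else c(500L, 1000L, 1500L)
  patterns <- c("regular", "random", "trended", "clustered")
  out <- list()
  for (sf in surfaces) {
    if ("continuous" %in% settings) {
      for (scheme in c("URS", "TSS", "SGS")) for (k in ks) {
        spec <- if (scheme == "URS") scheme_spec("URS", n = k^2)
                else scheme_spec(scheme, k = k)
        cfg <- mc_config("continuous", surface = sf, spec = spec, R = R,
                         M = M, grid_n = grid_n, seed = seed)
        out[[sprintf("continuous_s%d_%s_n%d", sf, scheme, k^2)]] <-
          run_replications(cfg)
      }
    }
    if ("areas" %in% settings) {
      for (scheme in c("SRSWOR", "OPSS", "SYS")) for (g in gs) {
        spec <- if (scheme == "SRSWOR") scheme_spec("SRSWOR", n = g^2 %/% 10L)
                else scheme_spec(scheme, block = c(2L, 5L))
        cfg <- mc_config("areas", surface = sf, spec = spec, R = R, M = M,
                         g = g, seed = seed)
        out[[sprintf("areas_s%d_%s_N%d", sf, scheme, g^2)]] <-
          run_replications(cfg)
      }
    }
    if ("units" %in% settings) {
      for (pat in patterns) for (n in sizes) {
        cfg <- mc_config("units", surface = sf,
                         spec = scheme_spec("THREEP"), R = R, M = M,
                         pattern = pat, size = n, seed = seed)
        res <- run_replications(cfg)
        pop <- setup_population(cfg)$population
        attr(res, "sampling_fraction") <- mean(pop$units$pi)
        out[[sprintf("units_s%d_%s_N%d", sf, pat, n)]] <- res
      }
    }
  }
  out
}

#' Monte-Carlo check of bootstrap conservativeness at a point
#'
#' Estimates, at one target location, the ratio of the expected bootstrap
#' RMSE to the true (Monte-Carlo) RMSE of the NN interpolator: `R` outer
#' replications each draw a sample, build the map, and run an `M`-sample
#' pseudopopulation bootstrap at the target point. For fields differentiable
#' at the point with nonzero gradient, under designs guaranteeing a sampled
#' location within a fixed radius (such as TSS), the ratio is bounded by 3.
#'
#' @param field A [population_field()].
#' @param spec A continuous-design [scheme_spec()].
#' @param p Target location `c(x, y)`.
#' @param R Outer replications.
#' @param M Bootstrap samples per replication.
#' @return List with `ratio`, `rmse_true`, `mean_rmse_star`, their
#'   Monte-Carlo standard errors and the sizes used.
#' @export
conservativeness_mc <- function(field, spec, p, R = 1000L, M = 200L) {
  stopifnot(inherits(field, "population_field"), R >= 1, M >= 1)
  truth <- field$f(p[1], p[2])
  err2 <- numeric(R)
  rstar <- numeric(R)
  q <- matrix(p, ncol = 2L)
  for (r in seq_len(R)) {
    s <- draw_sample(spec, field)
    map <- structure(data.frame(x = p[1], y = p[2], value = NA_real_),
                     sample = s, grid = grid_spec(field$region, n = 1L),
                     setting = "continuous",
                     class = c("estimated_map", "data.frame"))
    rep <- boot_continuous_rmse(map, spec, M, q, 1e-9)
    err2[r] <- (rep$fhat[1] - truth)^2
    rstar[r] <- rep$rmse_star[1]
  }
  rmse_true <- sqrt(mean(err2))
  list(ratio = mean(rstar) / rmse_true,
       rmse_true = rmse_true,
       mean_rmse_star = mean(rstar),
       se_rmse_star = stats::sd(rstar) / sqrt(R),
       R = R, M = M)
}
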
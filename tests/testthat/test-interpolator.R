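# NN interpolation: tie handling, oracle equivalence, range preservation.

test_that("degenerate and exactly tied configurations interpolate correctly", {
  s1 <- as_nn_sample(0.3, 0.7, 5)
  m <- nn_interpolate(s1, cbind(runif(10), runif(10)))
  expect_true(all(m$value == 5))

  # exact two-way tie at the midpoint
  s2 <- as_nn_sample(c(0, 1), c(0, 1), c(0, 8))
  expect_equal(nn_interpolate(s2, rbind(c(0.5, 0.5)))$value, 4)

  # a query at a sampled location returns the observation there
  expect_equal(nn_interpolate(s2, rbind(c(1, 1)))$value, 8)
})

test_that("NN map agrees exactly with the brute-force scan on random instances", {
  set.seed(30)
  for (case in 1:100) {
    n <- sample(1:12, 1)
    nq <- sample(1:50, 1)
    sx <- runif(n); sy <- runif(n); sv <- runif(n, 0, 10)
    qx <- runif(nq); qy <- runif(nq)
    s <- as_nn_sample(sx, sy, sv)
    got <- nn_interpolate(s, cbind(qx, qy))$value
    expect_identical(got, brute_nn(sx, sy, sv, qx, qy))
  }
})

test_that("NN is the large-alpha limit of IDW on tie-free instances", {
  set.seed(31)
  tried <- 0L
  while (tried < 40L) {
    n <- sample(2:10, 1)
    sx <- runif(n); sy <- runif(n); sv <- runif(n, 0, 10)
    qx <- runif(20); qy <- runif(20)
    d <- sqrt(outer(qx, sx, `-`)^2 + outer(qy, sy, `-`)^2)
    # require a clear relative gap between the two nearest distances, so
    # the alpha = 200 weight of every non-nearest point is negligible
    gap <- apply(d, 1, function(r) { r <- sort(r); r[2] / r[1] })
    if (min(gap) < 1.2) next
    tried <- tried + 1L
    s <- as_nn_sample(sx, sy, sv)
    q <- cbind(qx, qy)
    expect_equal(idw_interpolate(s, q, alpha = 200)$value,
                 nn_interpolate(s, q)$value, tolerance = 1e-6)
  }

  # alpha = 2, two equidistant points: plain average by symmetry
  s <- as_nn_sample(c(0, 1), c(0.5, 0.5), c(2, 6))
  expect_equal(idw_interpolate(s, rbind(c(0.5, 0.8)), alpha = 2)$value, 4)
})

test_that("interpolated values stay inside the observed range and hit samples exactly", {
  set.seed(32)
  field <- population_field(2)
  s <- draw_sample(scheme_spec("TSS", k = 5), field)
  g <- grid_spec(unit_sq, n = 40L)
  m <- nn_interpolate(s, g)
  expect_gte(min(m$value), min(s$values))
  expect_lte(max(m$value), max(s$values))
  at_samples <- nn_interpolate(s, s$points)
  expect_equal(at_samples$value, s$values)
})

test_that("dichotomous observations produce a dichotomous map", {
  set.seed(33)
  s <- draw_sample(scheme_spec("TSS", k = 6),
                   population_field(function(x, y) as.numeric(x + y > 1),
                                    L = 1))
  m <- nn_interpolate(s, grid_spec(unit_sq, n = 30L))
  expect_true(all(m$value %in% c(0, 1)))
})

test_that("area maps keep sampled densities and spread them to neighbors", {
  ap <- area_population(1, g = 10)
  set.seed(34)
  idx <- draw_srswor(100L, 10L)
  m <- nn_map_areas(idx, ap)
  expect_equal(m$value[idx], ap$areas$density[idx])

  # single sampled area floods the map
  m1 <- nn_map_areas(42L, ap)
  expect_true(all(m1$value == ap$areas$density[42]))

  # on the regular centroid lattice, an unsampled quadrat equidistant from
  # two sampled ones averages their densities: sample areas 1 and 3, query 2
  m2 <- nn_map_areas(c(1L, 3L), ap)
  expect_equal(m2$value[2], mean(ap$areas$density[c(1, 3)]))
})

test_that("unit maps average over multiple nearest neighbors on lattices", {
  # 3 x 3 lattice of units; center is equidistant from the 4 edge midpoints
  g <- expand.grid(x = c(0, .5, 1), y = c(0, .5, 1))
  pop <- structure(list(units = data.frame(x = g$x, y = g$y,
                                           value = seq_len(9)),
                        pattern = "regular", region = unit_sq, L = 10),
                   class = "unit_population")
  edge_mids <- which((g$x == .5) != (g$y == .5))
  m <- nn_map_units(edge_mids, pop)
  center <- which(g$x == .5 & g$y == .5)
  expect_equal(m$value[center], mean(pop$units$value[edge_mids]))
  expect_equal(m$value[edge_mids], pop$units$value[edge_mids])
})

test_that("residual interpolation is exact at sampled units and with perfect predictions", {
  set.seed(35)
  pop <- assign_surface_values(unit_pattern("random", sizes = 200L)[[1]], 3)
  pop <- truncate_units(pop, 4)
  pop <- add_predictions(pop, rho = 0.10)
  idx <- draw_threep(pop$units$pi)
  m <- residual_interpolate(idx, pop)
  expect_equal(m$value[idx], pop$units$value[idx])

  # reconstruction error is bounded by the spread of prediction errors:
  # the interpolated error lies in the sampled-error range, so the gap to
  # the true error cannot exceed the population error spread
  e_pop <- pop$units$value - pop$units$prediction
  expect_lte(max(abs(m$value - pop$units$value)),
             diff(range(e_pop)) + 1e-12)

  # perfect predictions: residuals vanish and the map equals the predictions
  perf <- pop
  perf$units$prediction <- perf$units$value
  m0 <- residual_interpolate(idx, perf)
  expect_equal(m0$value, perf$units$prediction)

  pop$units$prediction <- NULL
  expect_error(residual_interpolate(idx, pop), "predictions")
})
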
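# Finite-sample error bounds and miss probabilities.

surface3_f <- function(x, y) eval_surface(3, x, y)

test_that("oscillation is zero for constants, Lipschitz-bounded, and captures jumps", {
  expect_equal(oscillation(function(x, y) rep(3, length(x)), c(.4, .6), .2), 0)

  # beta-Lipschitz field f = beta * p1: oscillation over the ball is at most
  # beta * delta (grid approximation only undershoots)
  beta <- 4
  f <- function(x, y) beta * x
  for (delta in c(0.05, 0.2)) {
    osc <- oscillation(f, c(.5, .5), delta)
    expect_lte(osc, beta * delta + 1e-9)
    expect_gte(osc, beta * delta * 0.95)
  }

  # jump of surface 3 across the edge p1 = 1/2 at p2 = 0.75: C3 * p2 = 3.75
  expect_equal(oscillation(surface3_f, c(0.5, 0.75), 1e-3), 3.75,
               tolerance = 0.01)
})

test_that("circle-rectangle intersection area matches quadrature on varied configurations", {
  set.seed(40)
  cases <- rbind(
    c(0.5, 0.5, 0.1), c(0.0, 0.0, 0.3), c(1.0, 0.5, 0.4),
    c(0.9, 0.9, 0.5), c(0.5, 0.5, 2.0), c(-0.2, 0.5, 0.35),
    matrix(c(runif(6, -0.3, 1.3), runif(6, -0.3, 1.3),
             runif(6, 0.05, 0.8)), ncol = 3))
  for (i in seq_len(nrow(cases))) {
    a <- circle_rect_area(cases[i, 1], cases[i, 2], cases[i, 3])
    o <- quad_circle_rect(cases[i, 1], cases[i, 2], cases[i, 3], 0, 1, 0, 1)
    expect_equal(a, o, tolerance = 2e-3)
  }
  # interior ball: exact closed form
  expect_equal(circle_rect_area(0.5, 0.5, 0.1), pi * 0.01, tolerance = 1e-12)
})

test_that("analytic URS miss probabilities follow the independence closed form", {
  expect_equal(as.numeric(miss_prob_urs(unit_sq, c(.5, .5), 0.1, 1)),
               1 - 0.01 * pi, tolerance = 1e-12)
  expect_equal(as.numeric(miss_prob_urs(unit_sq, c(.5, .5), 0.1, 2)),
               (1 - 0.01 * pi)^2, tolerance = 1e-12)
  expect_equal(as.numeric(miss_prob_urs(unit_sq, c(.2, .8),
                                        region_diameter(unit_sq), 3)), 0)
})

test_that("TSS miss probability vanishes at the covering radius and reduces to URS at k = 1", {
  set.seed(41)
  for (i in 1:5) {
    p <- runif(2)
    k <- sample(2:8, 1)
    expect_equal(as.numeric(miss_prob_tss(unit_sq, p, sqrt(2) / k, k)), 0)
  }
  p <- c(0.37, 0.81)
  expect_equal(as.numeric(miss_prob_tss(unit_sq, p, 0.15, 1L)),
               as.numeric(miss_prob_urs(unit_sq, p, 0.15, 1L)),
               tolerance = 1e-12)
})

test_that("Monte-Carlo miss probabilities agree with the analytic forms within 3 SE", {
  set.seed(42)
  grid <- expand.grid(px = c(0.2, 0.5, 0.9), delta = c(0.08, 0.2))
  for (i in seq_len(nrow(grid))) {
    p <- c(grid$px[i], 0.4)
    delta <- grid$delta[i]
    ana_u <- as.numeric(miss_prob_urs(unit_sq, p, delta, 16L))
    mc_u <- miss_prob_mc(scheme_spec("URS", n = 16), unit_sq, p, delta,
                         reps = 4000L)
    expect_lt(abs(as.numeric(mc_u) - ana_u),
              3 * max(attr(mc_u, "se"), 1e-3))
    ana_t <- as.numeric(miss_prob_tss(unit_sq, p, delta, 4L))
    mc_t <- miss_prob_mc(scheme_spec("TSS", k = 4), unit_sq, p, delta,
                         reps = 4000L)
    expect_lt(abs(as.numeric(mc_t) - ana_t),
              3 * max(attr(mc_t, "se"), 1e-3))
  }

  # the miss event uses a strict inequality, so delta = 0 misses surely,
  # and SGS at the covering radius never misses
  expect_equal(as.numeric(miss_prob_mc(scheme_spec("URS", n = 5), unit_sq,
                                       c(.5, .5), 0, reps = 200L)), 1)
  set.seed(43)
  expect_equal(as.numeric(miss_prob_mc(scheme_spec("SGS", k = 5), unit_sq,
                                       c(.31, .62), sqrt(2) / 5,
                                       reps = 500L)), 0)
})

test_that("the pointwise error bound dominates the Monte-Carlo error across a test matrix", {
  set.seed(44)
  cases <- expand.grid(surface = c(1, 3), k = c(4, 10), delta = c(0.15, 0.3))
  for (i in seq_len(nrow(cases))) {
    field <- population_field(cases$surface[i])
    spec <- scheme_spec("TSS", k = cases$k[i])
    p <- c(0.5, 0.5)
    b <- nn_error_bound(field, spec, p, cases$delta[i])
    mc <- pointwise_error_mc(field, spec, p, reps = 800L)
    expect_lte(mc$mae, b$bound + 3 * mc$se_mae)
  }
  # constant field: the bound reduces to L * missprob and the error to 0
  cf <- population_field(function(x, y) rep(5, length(x)), L = 5)
  b0 <- nn_error_bound(cf, scheme_spec("URS", n = 4), c(.5, .5), 0.1)
  expect_equal(b0$oscillation, 0)
  expect_equal(b0$bound, 5 * b0$miss_prob)
})

test_that("second-moment miss bound: closed form under independence, dominates enumeration", {
  # independent equal selections: bound = 1 / (n q), always above (1 - q)^n
  for (n in 1:10) for (q in seq(0.1, 0.9, by = 0.1)) {
    b <- miss_count_bound(rep(q, n))
    expect_equal(b, 1 / (n * q), tolerance = 1e-12)
    expect_gte(b, (1 - q)^n)
  }
  # n = 2, q = 0.5: bound 1 against exhaustive Pr{no hits} = 0.25
  expect_equal(miss_count_bound(c(0.5, 0.5)), 1)

  # unequal independent probabilities, exhaustive enumeration oracle
  set.seed(45)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    q <- sample(seq(0.1, 0.9, 0.1), n, replace = TRUE)
    expect_gte(miss_count_bound(q), prod(1 - q))
  }

  # vacuous configuration: mutually exclusive hits drive the denominator
  # to zero and the bound collapses to +Inf
  joint <- matrix(0, 2, 2)
  expect_identical(miss_count_bound(c(0.5, 0.5), joint), Inf)
})

test_that("Lipschitz-rate bound: miss term vanishes under TSS at the covering radius", {
  k <- 6L; n <- k^2
  t <- sqrt(2)
  miss <- miss_prob_tss(unit_sq, c(.4, .7), t / sqrt(n), k)
  b <- lipschitz_error_bound(beta = 2, t = t, n = n, L = 10, miss_prob = miss)
  expect_equal(b, 2 * t / sqrt(n))
  expect_equal(lipschitz_error_bound(0, t, n, 10, 0.3), 3)
})

test_that("pointwise RMSE decays near the n^(-1/2) rate under TSS on a smooth surface", {
  set.seed(46)
  field <- population_field(1)
  ks <- c(4L, 6L, 8L, 10L)
  rmse <- vapply(ks, function(k) {
    pointwise_error_mc(field, scheme_spec("TSS", k = k), c(0.5, 0.5),
                       reps = 800L)$rmse
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(rmse) ~ log(ks^2)))[2]
  expect_gte(slope, -0.75)
  expect_lte(slope, -0.25)
})

test_that("MIAE decreases with the tessellation ladder on all three surfaces", {
  set.seed(47)
  for (sf in 1:3) {
    field <- population_field(sf)
    miae <- vapply(c(4L, 6L, 8L, 10L), function(k) {
      miae_mc(field, scheme_spec("TSS", k = k), reps = 120L,
              grid_n = 30L)$miae
    }, numeric(1))
    expect_true(all(diff(miae) < 0))
  }
  # constant field: MIAE identically zero
  cf <- population_field(function(x, y) rep(2, length(x)), L = 2)
  expect_equal(miae_mc(cf, scheme_spec("TSS", k = 4), reps = 5L,
                       grid_n = 10L)$miae, 0)
})
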
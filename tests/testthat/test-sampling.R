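# Sampling schemes: fixed-size contracts, determinism and distributions.

test_that("URS draws uniform points and is deterministic under a seed", {
  set.seed(5)
  p <- draw_urs(unit_sq, 100L)
  expect_equal(dim(p), c(100L, 2L))
  expect_true(all(in_region(unit_sq, p[, 1], p[, 2])))
  set.seed(5)
  expect_identical(draw_urs(unit_sq, 100L), p)

  # binomial oracle: fraction in the lower-left quadrant
  set.seed(6)
  q <- draw_urs(unit_sq, 10000L)
  frac <- mean(q[, 1] < 0.5 & q[, 2] < 0.5)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("TSS places exactly one point per tessellation cell", {
  set.seed(9)
  p <- draw_tss(unit_sq, 4L)
  expect_equal(nrow(p), 16L)
  cell <- floor(p[, 1] * 4) + 4 * floor(p[, 2] * 4)
  expect_equal(sort(cell), 0:15)
})

test_that("SGS is a translated lattice: shared offsets and exact spacing", {
  set.seed(10)
  p <- draw_sgs(unit_sq, 10L)
  offx <- p[, 1] %% 0.1
  offy <- p[, 2] %% 0.1
  expect_true(all(abs(offx - offx[1]) < 1e-12))
  expect_true(all(abs(offy - offy[1]) < 1e-12))
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  expect_equal(min(d), 0.1, tolerance = 1e-12)
})

test_that("TSS/SGS guarantee a sampled point within sqrt(2) cell sides of any location", {
  g <- grid_centers(grid_spec(unit_sq, n = 101L))
  for (k in c(4L, 7L)) {
    delta <- sqrt(2) / k
    for (seed in 1:5) {
      set.seed(seed)
      for (draw in list(draw_tss(unit_sq, k), draw_sgs(unit_sq, k))) {
        d2 <- outer(g$x, draw[, 1], `-`)^2 + outer(g$y, draw[, 2], `-`)^2
        expect_lte(max(sqrt(apply(d2, 1, min))), delta)
      }
    }
  }
})

test_that("SRSWOR returns distinct indices with the right inclusion rate", {
  set.seed(12)
  s <- draw_srswor(100L, 10L)
  expect_length(unique(s), 10L)
  expect_error(draw_srswor(5L, 6L), "exceeds")
  expect_setequal(draw_srswor(7L, 7L), 1:7)

  hits <- 0L
  reps <- 10000L
  for (r in seq_len(reps)) hits <- hits + (1L %in% draw_srswor(100L, 10L))
  expect_lt(abs(hits / reps - 0.1), 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("OPSS selects one quadrat inside each block; 1 x 1 blocks are a census", {
  set.seed(13)
  idx <- draw_opss(10L, c(2L, 5L))
  expect_length(idx, 10L)
  # block membership: row-major index -> (row, col) -> block coordinates
  row <- (idx - 1L) %/% 10L + 1L
  col <- (idx - 1L) %% 10L + 1L
  blocks <- paste((row - 1L) %/% 2L, (col - 1L) %/% 5L)
  expect_length(unique(blocks), 10L)
  expect_setequal(draw_opss(4L, c(1L, 1L)), 1:16)
  expect_error(draw_opss(10L, c(3L, 5L)), "tile")
})

test_that("SYS replicates a single within-block position across all blocks", {
  set.seed(14)
  idx <- draw_sys_blocks(10L, c(2L, 5L))
  expect_length(idx, 10L)
  row <- (idx - 1L) %/% 10L
  col <- (idx - 1L) %% 10L
  expect_length(unique(paste(row %% 2L, col %% 5L)), 1L)
  set.seed(14)
  expect_identical(draw_sys_blocks(10L, c(2L, 5L)), idx)
})

test_that("3P inclusion is Bernoulli per unit with Poisson-binomial size", {
  expect_setequal(draw_threep(rep(1, 20)), 1:20)

  set.seed(15)
  pi <- runif(50, 0.05, 0.6)
  sizes <- replicate(10000, length(draw_threep(pi)))
  se <- sqrt(sum(pi * (1 - pi)) / 10000)
  expect_lt(abs(mean(sizes) - sum(pi)), 3 * se)

  # an (almost surely) empty draw is retried with a warning
  set.seed(16)
  expect_warning(draw_threep(c(1e-4, 1e-4)), "redrawn")
})

test_that("draw_sample enforces scheme/setting compatibility and fixed sizes", {
  field <- population_field(1)
  expect_error(draw_sample(scheme_spec("SRSWOR", n = 5), field),
               "continuous")
  ap <- area_population(1, g = 10)
  expect_error(draw_sample(scheme_spec("TSS", k = 4), ap), "area")

  for (spec in list(scheme_spec("URS", n = 9), scheme_spec("TSS", k = 3),
                    scheme_spec("SGS", k = 3))) {
    set.seed(17)
    s <- draw_sample(spec, field)
    expect_equal(nrow(s$points), 9L)
    expect_equal(s$values, field$f(s$points[, 1], s$points[, 2]))
  }

  set.seed(18)
  s <- draw_sample(scheme_spec("OPSS"), ap)
  expect_equal(length(s$indices), 10L)
  expect_equal(s$values, ap$areas$density[s$indices])
})

test_that("scheme specifications survive a JSON round trip", {
  for (spec in list(scheme_spec("TSS", k = 6), scheme_spec("URS", n = 30),
                    scheme_spec("SYS", block = c(2L, 5L)),
                    scheme_spec("THREEP", L_star = 50))) {
    back <- scheme_from_json(scheme_to_json(spec))
    expect_equal(back, spec)
  }
})
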
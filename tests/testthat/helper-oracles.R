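# Independent oracles used across the suite.

# brute-force tie-averaging NN interpolation: plain double loop, no shared
# code with the package's vectorized path
brute_nn <- function(sx, sy, sv, qx, qy, tie_tol = 1e-9) {
  vapply(seq_along(qx), function(j) {
    d <- numeric(length(sv))
    for (i in seq_along(sv)) {
      d[i] <- sqrt((sx[i] - qx[j])^2 + (sy[i] - qy[j])^2)
    }
    mean(sv[d <= min(d) + tie_tol])
  }, numeric(1))
}

# disk / rectangle intersection area by dense midpoint quadrature
quad_circle_rect <- function(cx, cy, r, xmin, xmax, ymin, ymax, n = 1500L) {
  gx <- seq(xmin, xmax, length.out = n + 1L)
  gx <- (gx[-1] + gx[-(n + 1L)]) / 2
  gy <- seq(ymin, ymax, length.out = n + 1L)
  gy <- (gy[-1] + gy[-(n + 1L)]) / 2
  inside <- outer(gx, gy, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
  mean(inside) * (xmax - xmin) * (ymax - ymin)
}

unit_sq <- study_region()
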
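# Brute-force least-squares line fit by iterative grid search, independent
# of stats::lm. Works on centered x (the centered intercept and slope are
# uncorrelated, so the SSE valley is axis-aligned and the zooming grid
# converges), then maps the intercept back: y = a + b x = ac + b (x - xbar)
# implies a = ac - b xbar.
grid_search_ols <- function(x, y, n_grid = 41L, n_zoom = 40L) {
  xbar <- mean(x)
  xc <- x - xbar
  slopes <- outer(y, y, "-") / outer(xc, xc, "-")
  slopes <- slopes[is.finite(slopes)]
  b_lo <- min(slopes) - 1; b_hi <- max(slopes) + 1
  a_lo <- min(y) - 1; a_hi <- max(y) + 1
  best <- c(NA_real_, NA_real_)
  for (it in seq_len(n_zoom)) {
    a_grid <- seq(a_lo, a_hi, length.out = n_grid)
    b_grid <- seq(b_lo, b_hi, length.out = n_grid)
    sse <- outer(a_grid, b_grid, Vectorize(function(a, b)
      sum((y - a - b * xc)^2)))
    idx <- which(sse == min(sse), arr.ind = TRUE)[1L, ]
    best <- c(a_grid[idx[1L]], b_grid[idx[2L]])
    a_step <- a_grid[2L] - a_grid[1L]; b_step <- b_grid[2L] - b_grid[1L]
    a_lo <- best[1L] - 2 * a_step; a_hi <- best[1L] + 2 * a_step
    b_lo <- best[2L] - 2 * b_step; b_hi <- best[2L] + 2 * b_step
  }
  list(intercept = best[1L] - best[2L] * xbar, slope = best[2L])
}

# Convenience: a noise-free static-quenching series with known kb, n.
static_series <- function(kb = 2.07e4, n = 1, f0 = 1000, temperature = 298,
                          conc = seq(0, 27.5, length.out = 11), ...) {
  generate_titration(ground_truth("static", kb = kb, n = n, ...),
                     conc_grid = conc, f0 = f0, temperature = temperature)
}
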
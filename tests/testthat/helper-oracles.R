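# Independent numerical oracles used across tests.

# Direct numerical convolution of a Gaussian (center c0, sd sg, area A)
# with a one-sided half-Gaussian of width sh, by trapezoidal quadrature on
# a fine grid.  Brute-force alternative to the closed form in gmg_value().
conv_gmg <- function(c0, sg, sh, A, x, step = 0.005) {
  if (sh == 0) return(A * stats::dnorm(x, c0, sg))
  t <- seq(0, 12 * sh, by = step)
  w <- 2 / (sqrt(2 * pi) * sh) * exp(-t^2 / (2 * sh^2))
  vapply(x, function(xx) {
    g <- A / (sqrt(2 * pi) * sg) * exp(-(xx - t - c0)^2 / (2 * sg^2))
    v <- w * g
    step * (sum(v) - (v[1] + v[length(v)]) / 2)
  }, numeric(1))
}

# Build a noiseless af_spectrum as an exact sum of GMG bands.
band_sum_spectrum <- function(bands, grid = seq(390, 630, by = 1),
                              excitation = 366, sample_id = "synthetic",
                              group = "other") {
  y <- rowSums(vapply(bands, function(b) gmg_value(b, grid),
                      numeric(length(grid))))
  af_spectrum(grid, y, excitation = excitation, sample_id = sample_id,
              group = group)
}

# Brute-force grid-search + Nelder-Mead polish oracle for few-band
# problems.  Amplitudes enter the model linearly, so for any trial set of
# shapes they are profiled out by linear least squares; only the peak
# positions are searched.  Independent of the package's LM fitting path.
grid_oracle_amplitudes <- function(wl, y, peaks, fwhms, rhos, span = 6) {
  design <- function(pk) {
    sapply(seq_along(pk), function(k)
      gmg_value(solve_band(pk[k], fwhms[k], rhos[k], 1), wl))
  }
  profiled_sse <- function(pk) {
    X <- design(pk)
    a <- qr.coef(qr(X), y)
    sum((y - X %*% a)^2)
  }
  # coarse grid over peak offsets
  offs <- seq(-span, span, by = 2)
  best <- NULL
  grid <- as.matrix(expand.grid(rep(list(offs), length(peaks))))
  for (i in seq_len(nrow(grid))) {
    pk <- peaks + grid[i, ]
    sse <- profiled_sse(pk)
    if (is.null(best) || sse < best$sse) best <- list(pk = pk, sse = sse)
  }
  pol <- stats::optim(best$pk, profiled_sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  X <- design(pol$par)
  a <- qr.coef(qr(X), y)
  list(amplitudes = as.numeric(a), peaks = pol$par, sse = pol$value)
}
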
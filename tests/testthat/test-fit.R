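# Spectral fitting: self-consistency on constructed inputs, determinism,
# bound respect, diagnostics, and the grid-search oracle cross-check.

# a small well-separated 3-band problem used in several tests
three_band_problem <- function() {
  peaks <- c(428, 490, 560)
  fwhms <- c(73, 112, 60)
  rhos <- c(0.3, 0.3, 0.3)
  amps <- c(3000, 5000, 800)
  bands <- mapply(solve_band, peaks, fwhms, rhos, amps, SIMPLIFY = FALSE)
  list(peaks = peaks, fwhms = fwhms, rhos = rhos, amps = amps,
       spectrum = band_sum_spectrum(bands, grid = seq(390, 630, 0.5)))
}

test_that("noiseless spectra built from library bands are recovered within 1%", {
  comps <- af_components(366, "control")
  truth_amp <- c(retinol = 4000, arachidonic_acid = 2500, oleic_acid = 1500,
                 linoleic_acid = 2800, proteins = 300, undefined_440 = 900)
  bands <- lapply(names(truth_amp), function(nm) {
    r <- comps[comps$name == nm, ]
    solve_band(r$peak_lambda, r$fwhm, r$rho, truth_amp[[nm]])
  })
  raw <- band_sum_spectrum(bands)
  s <- normalize_spectrum(raw)
  f <- fit_af_spectrum(s, comps, stage = "reference", restarts = 2, seed = 1)
  # truth areas over the window, on the normalized scale of the spectrum
  fine <- seq(390, 600, by = 0.25)
  scale <- 100 / max(raw$intensity)
  truth_area <- vapply(bands, function(b) {
    v <- gmg_value(b, fine) * scale
    sum(diff(fine) * (v[-length(v)] + v[-1]) / 2)
  }, numeric(1))
  expect_equal(unname(f$component_areas[names(truth_amp)]),
               unname(truth_area), tolerance = 0.01)
  expect_gt(f$r_squared, 0.9999)
})

test_that("a pure retinol spectrum attributes almost nothing elsewhere", {
  b <- solve_band(490, 112, 0.3, 5000)
  s <- normalize_spectrum(band_sum_spectrum(list(b)))
  f <- fit_af_spectrum(s, af_components(366, "control"), stage = "reference",
                       restarts = 2, seed = 1)
  pct <- percent_contributions(f)
  others <- pct[setdiff(c("arachidonic_acid", "oleic_acid", "linoleic_acid"),
                        character(0))]
  expect_true(all(others < 2))
  expect_gt(pct[["retinol"]], 90)
})

test_that("fits are deterministic given spectrum and seed", {
  pr <- default_profiles(366)$sham
  s <- normalize_spectrum(generate_spectrum(pr, "s1", seed = 9)$spectrum)
  f1 <- fit_af_spectrum(s, stage = "reference", restarts = 3, seed = 4)
  f2 <- fit_af_spectrum(s, stage = "reference", restarts = 3, seed = 4)
  expect_identical(f1$pars, f2$pars)
  expect_identical(f1$sse, f2$sse)
})

test_that("fitted parameters respect their declared bounds", {
  pr <- default_profiles(310)$sham
  s <- normalize_spectrum(generate_spectrum(pr, "s1", seed = 2)$spectrum)
  comps <- af_components(310)
  f <- fit_af_spectrum(s, comps, stage = "reference", restarts = 2, seed = 1)
  for (k in seq_len(nrow(f$pars))) {
    r <- comps[comps$name == f$pars$name[k], ]
    expect_gte(f$pars$peak_lambda[k], r$peak_lo)
    expect_lte(f$pars$peak_lambda[k], r$peak_hi)
    expect_gte(f$pars$fwhm[k], r$fwhm_lo)
    expect_lte(f$pars$fwhm[k], r$fwhm_hi)
    expect_gte(f$pars$rho[k], r$rho_lo)
    expect_lte(f$pars$rho[k], r$rho_hi)
    if (r$role == "negative") expect_lte(f$pars$amplitude[k], 0)
    else expect_gte(f$pars$amplitude[k], 0)
  }
})

test_that("noise can only degrade the fit relative to the noiseless case", {
  pr0 <- default_profiles(366)$sham
  pr0$noise_sd <- 0
  s0 <- normalize_spectrum(generate_spectrum(pr0, "s", seed = 31)$spectrum)
  f0 <- fit_af_spectrum(s0, stage = "reference", restarts = 2, seed = 1)
  for (rep_seed in 31:34) {
    pr <- default_profiles(366)$sham
    s <- normalize_spectrum(generate_spectrum(pr, "s", seed = rep_seed)$spectrum)
    f <- fit_af_spectrum(s, stage = "reference", restarts = 2, seed = 1)
    expect_lt(f$r_squared, f0$r_squared)
  }
})

test_that("component area bookkeeping is consistent with the model curve", {
  pr <- default_profiles(310)$ir_60_60
  s <- normalize_spectrum(generate_spectrum(pr, "s1", seed = 6)$spectrum)
  f <- fit_af_spectrum(s, stage = "reference", restarts = 2, seed = 1)
  fine <- seq(f$window[1], f$window[2], by = 0.25)
  model <- rowSums(vapply(f$bands, function(b) gmg_value(b, fine),
                          numeric(length(fine))))
  model_area <- sum(diff(fine) * (model[-length(model)] + model[-1]) / 2)
  expect_equal(sum(f$component_areas), model_area, tolerance = 1e-6)
})

test_that("under-determined and ill-posed inputs raise errors", {
  s <- normalize_spectrum(af_spectrum(seq(440, 460, 1), dnorm(seq(440, 460, 1),
                                                              450, 5), 310))
  expect_error(fit_af_spectrum(s, af_components(310), window = c(440, 460)),
               "under-determined")
  raw <- af_spectrum(390:600, rep(1, 211), 310)
  expect_error(fit_af_spectrum(normalize_spectrum(raw)), NA)
  expect_error(fit_af_spectrum(raw), "normalized")
  pr <- default_profiles(366)$sham
  sn <- normalize_spectrum(generate_spectrum(pr, "s", seed = 1)$spectrum)
  expect_error(fit_af_spectrum(sn, stage = "comparative"), "reference")
  ref <- structure(list(pars = NULL, excitation = 310), class = "af_fit")
  expect_error(fit_af_spectrum(sn, stage = "comparative", reference = ref),
               "excitation")
})

test_that("LM solution matches the brute-force grid-search oracle", {
  prob <- three_band_problem()
  s <- normalize_spectrum(prob$spectrum, window = c(390, 630))
  scale <- 100 / max(prob$spectrum$intensity)

  comps <- af_components(366, "ir")
  comps <- comps[comps$name %in% c("linoleic_acid", "retinol", "flavin_560"), ]
  f <- fit_af_spectrum(s, comps, stage = "reference", window = c(390, 630),
                       restarts = 2, seed = 1)

  idx <- s$wavelength >= 390 & s$wavelength <= 630
  oracle <- grid_oracle_amplitudes(s$wavelength[idx], s$intensity[idx],
                                   peaks = prob$peaks, fwhms = prob$fwhms,
                                   rhos = prob$rhos)
  fitted_amp <- f$pars$amplitude[match(c("linoleic_acid", "retinol",
                                         "flavin_560"), f$pars$name)]
  expect_equal(fitted_amp, oracle$amplitudes, tolerance = 0.005)
  # both routes recover the constructed truth
  expect_equal(oracle$amplitudes, prob$amps * scale, tolerance = 0.005)
})

test_that("goodness-of-fit diagnostics follow the r-squared definition", {
  pr <- default_profiles(366)$sham
  s <- normalize_spectrum(generate_spectrum(pr, "s", seed = 21)$spectrum)
  f <- fit_af_spectrum(s, stage = "reference", restarts = 2, seed = 1)
  g <- goodness_of_fit(f)
  expect_equal(g$r_squared, 1 - f$sse / sum((f$data - mean(f$data))^2))
  expect_true(g$pass)

  # a perfect fit: r-squared exactly 1
  perfect <- f
  perfect$residuals <- rep(0, length(f$residuals))
  perfect$sse <- 0
  perfect$r_squared <- 1
  expect_true(goodness_of_fit(perfect)$pass)
  expect_equal(goodness_of_fit(perfect)$r_squared, 1)

  # a model identical to the data mean: r-squared exactly 0
  flat <- f
  flat$residuals <- f$data - mean(f$data)
  flat$sse <- sum(flat$residuals^2)
  flat$r_squared <- 0
  expect_false(goodness_of_fit(flat)$pass)
})
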
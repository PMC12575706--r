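test_that("peak statistics recover constructed band shapes", {
  # triangular band: half-width at half height = 20 nm
  tri <- triangle_spectrum(center = 540, width_at_base = 80, height = 0.8)
  ps <- peak_stats(tri)
  expect_equal(ps$lambda_max, 540)
  expect_equal(ps$fwhm, 40, tolerance = 1e-6)
  expect_equal(ps$baseline, 0, tolerance = 1e-9)

  # Gaussian band: FWHM = 2 sqrt(2 ln 2) sigma = 23.548 nm at sigma 10
  g <- gaussian_spectrum(center = 540, fwhm = 2 * sqrt(2 * log(2)) * 10)
  expect_equal(peak_stats(g)$fwhm, 23.548, tolerance = 1e-2)

  # flat spectrum: no peak, baseline preserved
  flat <- spectrum(visible_grid(), rep(0.057, 401))
  psf <- peak_stats(flat)
  expect_true(is.na(psf$lambda_max))
  expect_true(is.na(psf$fwhm))
  expect_equal(psf$baseline, 0.057)
})

test_that("FWHM is measured above the off-band baseline", {
  ps <- peak_stats(gaussian_spectrum(fwhm = 30, height = 0.5,
                                     baseline = 0.06))
  expect_equal(ps$fwhm, 30, tolerance = 0.5)
  expect_equal(ps$baseline, 0.06, tolerance = 1e-3)
  expect_equal(ps$peak_reflectance, 0.56, tolerance = 1e-3)
})

test_that("flat spectra map to the illuminant white point", {
  for (ill in c("E", "D65")) {
    ch <- spectrum_to_chromaticity(spectrum(visible_grid(), rep(0.3, 401)),
                                   ill)
    expect_equal(ch$saturation, 0, tolerance = 1e-12)
    expect_equal(ch$x + ch$y + ch$z, 1, tolerance = 1e-12)
  }
  # equal-energy white point is the centre of the diagram
  chE <- spectrum_to_chromaticity(spectrum(visible_grid(), rep(1, 401)), "E")
  expect_equal(chE$x, 1 / 3, tolerance = 2e-3)
  expect_equal(chE$y, 1 / 3, tolerance = 2e-3)
})

test_that("a narrow band at 540 nm lands on the spectral locus there", {
  wl <- visible_grid(by = 5)
  v <- numeric(length(wl))
  v[wl == 540] <- 1
  ch <- spectrum_to_chromaticity(spectrum(wl, v), "E")
  expect_equal(ch$x, 0.2296, tolerance = 2e-3)
  expect_equal(ch$y, 0.7543, tolerance = 2e-3)
})

test_that("chromaticity is scale-invariant and inside the unit simplex", {
  set.seed(31)
  for (i in 1:20) {
    fw <- runif(1, 15, 150)
    ctr <- runif(1, 430, 680)
    base <- runif(1, 0, 0.2)
    sp <- gaussian_spectrum(center = ctr, fwhm = fw, height = runif(1, .2, .8),
                            baseline = base)
    ch <- spectrum_to_chromaticity(sp)
    expect_true(all(c(ch$x, ch$y, ch$z) >= 0))
    expect_equal(ch$x + ch$y + ch$z, 1, tolerance = 1e-12)
    scaled <- spectrum(sp$wavelength_nm, sp$reflectance * 0.37)
    ch2 <- spectrum_to_chromaticity(scaled)
    expect_equal(c(ch$x, ch$y), c(ch2$x, ch2$y), tolerance = 1e-12)
  }
})

test_that("white noise strictly desaturates any colored spectrum", {
  set.seed(17)
  for (i in 1:10) {
    sp <- gaussian_spectrum(center = runif(1, 440, 660),
                            fwhm = runif(1, 20, 80), height = 0.7)
    noisy <- spectrum(sp$wavelength_nm, sp$reflectance * 0.8 + 0.1)
    expect_lt(spectrum_to_chromaticity(noisy)$saturation,
              spectrum_to_chromaticity(sp)$saturation)
  }
})

test_that("narrowing a band at fixed peak wavelength raises saturation", {
  for (ctr in c(460, 540, 640)) {
    narrow <- spectrum_to_chromaticity(gaussian_spectrum(ctr, fwhm = 20))
    broad <- spectrum_to_chromaticity(gaussian_spectrum(ctr, fwhm = 120))
    expect_gt(narrow$saturation, broad$saturation)
  }
})

test_that("saturation ranking is deterministic and physically ordered", {
  ammolite_like <- gaussian_spectrum(540, fwhm = 30, height = 0.8,
                                     baseline = 0)
  abalone_like <- gaussian_spectrum(540, fwhm = 30, height = 0.8,
                                    baseline = 0.05)
  rk <- compare_saturation(list(abalone_like, ammolite_like))
  expect_equal(rk$input[1], 2)   # the noise-free band ranks first

  # identical spectra: tie broken by input order
  rk2 <- compare_saturation(list(ammolite_like, ammolite_like))
  expect_equal(rk2$input, c(1, 2))
  expect_error(compare_saturation(list(ammolite_like)), "two")
})

test_that("an all-zero spectrum has no defined chromaticity", {
  expect_error(spectrum_to_chromaticity(spectrum(visible_grid(),
                                                 rep(0, 401))),
               "undefined")
})
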
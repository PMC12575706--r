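# Constructed spectra used across tests.

# Symmetric triangular band on a flat baseline: peak `height` at `center`,
# reaching the baseline at center +/- width_at_base/2.
triangle_spectrum <- function(center = 540, width_at_base = 80,
                              height = 1, baseline = 0,
                              wl = visible_grid()) {
  v <- baseline + height * pmax(0, 1 - abs(wl - center) / (width_at_base / 2))
  spectrum(wl, pmin(v, 1))
}

# Gaussian band of a given FWHM on a flat baseline.
gaussian_spectrum <- function(center = 540, fwhm = 30, height = 1,
                              baseline = 0, wl = visible_grid()) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spectrum(wl, pmin(baseline + height * exp(-(wl - center)^2 / (2 * sigma^2)), 1))
}

# Ordered (zero-disorder) Ammolite-like stack.
ordered_stack <- function(d1 = 160, d2 = 4, n_periods = 300, n2 = 1.00) {
  sample_stack(stack_spec(d1_mean = d1, d2_mean = d2, n_periods = n_periods,
                          refr = refractive_model(n2 = n2)))
}
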
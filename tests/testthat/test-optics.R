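test_that("Fresnel coefficients reproduce hand-computed interface values", {
  f <- fresnel_interface(1.00, 1.63, 0, "s")
  expect_equal(f$R, (0.63 / 2.63)^2, tolerance = 1e-12)
  # index-matched interface reflects nothing
  expect_equal(Mod(fresnel_interface(1.5, 1.5, 37, "s")$r), 0)
  expect_equal(Mod(fresnel_interface(1.5, 1.5, 37, "p")$r), 0)
  # p-polarized reflection vanishes at the Brewster angle
  brewster <- atan(1.63) * 180 / pi
  expect_lt(Mod(fresnel_interface(1.00, 1.63, brewster, "p")$r), 1e-12)
})

test_that("Fresnel energy balance holds for both polarizations", {
  for (pol in c("s", "p")) {
    for (th in c(0, 20, 45, 70)) {
      f <- fresnel_interface(1.00, 1.63, th, pol)
      expect_equal(f$R + f$T, 1, tolerance = 1e-12)
    }
  }
})

test_that("an empty stack reduces to the bare ambient/substrate interface", {
  st <- layer_stack(numeric(0), numeric(0), n_ambient = 1.00,
                    n_substrate = 1.63)
  sp <- tmm_reflectance(st)
  expect_equal(sp$reflectance, rep((0.63 / 2.63)^2, length(sp$reflectance)),
               tolerance = 1e-12)
})

test_that("transfer matrix agrees with the Airy single-film closed form", {
  wl <- visible_grid()
  for (case in list(c(4, 1.00), c(11, 1.43), c(125, 1.00), c(60, 1.20))) {
    st <- layer_stack(case[2], case[1], n_ambient = 1.63, n_substrate = 1.63)
    tmm <- tmm_reflectance(st, wl)$reflectance
    airy <- single_gap_reflectance(case[1], 1.63, case[2], wl)
    expect_lt(max(abs(tmm - airy)), 1e-10)
  }
})

test_that("energy is conserved through lossless multilayer stacks", {
  st <- sample_stack(stack_spec(d1_mean = 150, d1_sd = 15, d2_mean = 4,
                                d2_sd = 2, n_periods = 200, seed = 3))
  for (th in c(0, 30)) {
    for (pol in c("s", "p")) {
      g <- incidence_geometry(th, pol)
      R <- tmm_reflectance(st, geom = g)$reflectance
      T <- tmm_transmittance(st, geom = g)$reflectance
      expect_lt(max(abs(R + T - 1)), 1e-8)
    }
  }
})

test_that("reflectance is reciprocal under stack reversal", {
  spec <- stack_spec(d1_mean = 150, d1_sd = 15, d2_mean = 4, d2_sd = 2,
                     n_periods = 50, seed = 9,
                     refr = refractive_model(n_ambient = 1.63,
                                             n_substrate = 1.63))
  st <- sample_stack(spec)
  rev_st <- layer_stack(rev(st$index), rev(st$thickness),
                        n_ambient = 1.63, n_substrate = 1.63)
  expect_equal(tmm_reflectance(st)$reflectance,
               tmm_reflectance(rev_st)$reflectance, tolerance = 1e-12)
})

test_that("an index-matched stack collapses to a flat interface spectrum", {
  st <- sample_stack(stack_spec(d1_mean = 160, d1_sd = 10, d2_mean = 4,
                                n_periods = 100, seed = 2,
                                refr = refractive_model(n2 = 1.63)))
  R <- tmm_reflectance(st)$reflectance
  expect_lt(max(R) - min(R), 1e-10)
})

test_that("the ordered-stack peak sits at the Bragg-Snell prediction", {
  st <- ordered_stack(160, 4, 300)
  ps <- peak_stats(tmm_reflectance(st))
  lam <- bragg_wavelength(164, effective_index(160, 4))
  expect_lt(abs(ps$lambda_max - lam) / lam, 0.02)
})

test_that("peak reflectance grows with period count up to saturation", {
  peaks <- vapply(c(5, 15, 40, 120), function(N)
    max(tmm_reflectance(ordered_stack(160, 4, N))$reflectance), numeric(1))
  expect_true(all(diff(peaks) > -1e-9))
  expect_gt(peaks[4], 0.95)
})

test_that("ensemble averaging is seeded, exact at zero SD, and convergent", {
  spec0 <- stack_spec(d1_mean = 160, d2_mean = 4, n_periods = 100)
  det <- tmm_reflectance(sample_stack(spec0))
  ens <- ensemble_reflectance(spec0, n_realizations = 7)
  expect_equal(ens$reflectance, det$reflectance)

  spec <- stack_spec(d1_mean = 157, d1_sd = 8, d2_mean = 4, n_periods = 100,
                     seed = 21)
  e1 <- ensemble_reflectance(spec, 30)
  e2 <- ensemble_reflectance(spec, 30)
  expect_identical(e1$reflectance, e2$reflectance)

  # disorder broadens the band
  fw0 <- peak_stats(det)$fwhm
  fw <- peak_stats(ensemble_reflectance(
    stack_spec(d1_mean = 160, d1_sd = 15, d2_mean = 4, n_periods = 100,
               seed = 4), 50))$fwhm
  expect_gt(fw, fw0)

  # doubling realizations moves the mean by less than the MC error bound
  e50 <- ensemble_reflectance(spec, 50)
  e200 <- ensemble_reflectance(spec, 200)
  bound <- 6 * max(attr(e50, "mc_se"))
  expect_lt(max(abs(e50$reflectance - e200$reflectance)), bound)
})

test_that("the reflection band blue-shifts with incidence angle", {
  st <- ordered_stack(160, 4, 300)
  sps <- angle_scan(st, thetas = c(0, 15, 30, 45))
  lams <- vapply(sps, function(s) peak_stats(s)$lambda_max, numeric(1))
  expect_true(all(diff(lams) < 0))
  # and tracks the Bragg-Snell relation
  ne <- effective_index(160, 4)
  for (i in seq_along(lams)) {
    pred <- bragg_wavelength(164, ne, theta = c(0, 15, 30, 45)[i])
    expect_lt(abs(lams[i] - pred) / pred, 0.03)
  }
  # s and p are degenerate at normal incidence
  g0s <- tmm_reflectance(st, geom = incidence_geometry(0, "s"))
  g0p <- tmm_reflectance(st, geom = incidence_geometry(0, "p"))
  expect_equal(g0s$reflectance, g0p$reflectance, tolerance = 1e-12)
})

test_that("spectrum and geometry constructors validate their inputs", {
  expect_error(spectrum(c(400, 400, 500), c(0, 0, 0)), "increasing")
  expect_error(spectrum(400, numeric(0)), "equal length")
  expect_error(incidence_geometry(95), "theta")
  expect_error(incidence_geometry(5, "circular"))
})
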
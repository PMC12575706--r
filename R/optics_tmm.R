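#' Reflectance spectrum container
#'
#' A thin data-frame subclass holding a strictly increasing wavelength grid
#' (nm) and reflectance (or transmittance) fractions.  The default working
#' grid everywhere in the package is 380-780 nm at 1 nm steps.
#'
#' @param wavelength_nm Strictly increasing numeric vector, nm.
#' @param reflectance Values in `[0, 1]` (lossless media).
#' @return An object of class `spectrum` (also a data frame).
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  if (length(wavelength_nm) != length(reflectance))
    stop("wavelength and reflectance must have equal length")
  if (length(wavelength_nm) == 0) stop("empty wavelength grid")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(reflectance)))
    stop("non-finite reflectance values")
  structure(data.frame(wavelength_nm = as.numeric(wavelength_nm),
                       reflectance = as.numeric(reflectance)),
            class = c("spectrum", "data.frame"))
}

#' Default visible wavelength grid
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
visible_grid <- function(from = 380, to = 780, by = 1) seq(from, to, by = by)

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %.0f-%.0f nm, R in [%.4g, %.4g]\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Incidence geometry
#'
#' @param theta Angle of incidence from the surface normal, degrees, in
#'   `[0, 90)`.
#' @param polarization `"s"`, `"p"` or `"unpolarized"` (the incoherent mean
#'   of the two).
#' @return An object of class `incidence_geometry`.
#' @export
incidence_geometry <- function(theta = 0,
                               polarization = c("unpolarized", "s", "p")) {
  polarization <- match.arg(polarization)
  if (!is.numeric(theta) || theta < 0 || theta >= 90)
    stop("'theta' must be in [0, 90) degrees")
  structure(list(theta = theta, polarization = polarization),
            class = "incidence_geometry")
}

# cos(theta_j) in a medium of index n_j for light incident from index n0 at
# theta0 (degrees), by Snell's law.  All media here have n >= 1 and light
# enters from air, so the angle is always propagating (real).
snell_cos <- function(n, n0, theta0_deg) {
  s <- n0 * sin(theta0_deg * pi / 180) / n
  sqrt(1 - s^2)
}

#' Fresnel amplitude coefficients of a single interface
#'
#' Reflection and transmission amplitudes for a planar interface between
#' lossless media `n_a` (incidence side) and `n_b`, at incidence angle
#' `theta` degrees.  Conventions: for s the amplitudes are
#' `r = (na*ca - nb*cb)/(na*ca + nb*cb)`; for p,
#' `r = (nb*ca - na*cb)/(nb*ca + na*cb)` (r = 0 at the Brewster angle).
#' Energy is conserved: `|r|^2 + (nb*cb)/(na*ca) |t|^2 = 1`.
#'
#' @param n_a,n_b Refractive indices (>= 1) on the incidence and exit side.
#' @param theta Incidence angle, degrees.
#' @param polarization `"s"` or `"p"`.
#' @return List with complex `r` and `t` and the intensity coefficients
#'   `R` and `T`.
#' @examples
#' fresnel_interface(1.00, 1.63)$R   # 0.0574 at the air/aragonite interface
#' @export
fresnel_interface <- function(n_a, n_b, theta = 0,
                              polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  if (n_a < 1 || n_b < 1) stop("indices must be >= 1")
  ca <- snell_cos(n_a, n_a, theta)      # = cos(theta) in medium a
  cb <- snell_cos(n_b, n_a, theta)
  if (polarization == "s") {
    r <- (n_a * ca - n_b * cb) / (n_a * ca + n_b * cb)
    t <- 2 * n_a * ca / (n_a * ca + n_b * cb)
  } else {
    r <- (n_b * ca - n_a * cb) / (n_b * ca + n_a * cb)
    t <- 2 * n_a * ca / (n_b * ca + n_a * cb)
  }
  list(r = as.complex(r), t = as.complex(t),
       R = Mod(r)^2, T = (n_b * cb) / (n_a * ca) * Mod(t)^2)
}

# Characteristic-matrix reflectance/transmittance for one polarization,
# vectorized over the wavelength grid.  Optical admittances (in units of
# the free-space admittance): eta = n*cos(theta) for s, n/cos(theta) for p.
# The matrix product is carried as the field vector (B, C) = M (1, eta_sub)
# so each layer is two fused multiply-adds over the lambda vector.
tmm_one_pol <- function(stack, wavelengths, theta, pol) {
  n0 <- stack$n_ambient
  ns <- stack$n_substrate
  c0 <- snell_cos(n0, n0, theta)
  cs <- snell_cos(ns, n0, theta)
  eta <- function(n, cth) if (pol == "s") n * cth else n / cth
  eta0 <- eta(n0, c0)
  etas <- eta(ns, cs)
  B <- rep(1 + 0i, length(wavelengths))
  C <- rep(etas + 0i, length(wavelengths))
  nl <- length(stack$index)
  if (nl > 0) {
    # traverse from the layer adjacent to the substrate up to the surface
    for (j in rev(seq_len(nl))) {
      nj <- stack$index[j]
      cj <- snell_cos(nj, n0, theta)
      ej <- eta(nj, cj)
      delta <- 2 * pi * nj * stack$thickness[j] * cj / wavelengths
      cd <- cos(delta)
      sd <- sin(delta)
      Bn <- cd * B + (1i * sd / ej) * C
      Cn <- (1i * ej * sd) * B + cd * C
      B <- Bn
      C <- Cn
    }
  }
  denom <- eta0 * B + C
  if (any(!is.finite(Mod(denom))) || any(Mod(denom) == 0))
    stop(sprintf(
      "transfer-matrix product is non-finite (stack of %d layers, theta = %g)",
      nl, theta))
  r <- (eta0 * B - C) / denom
  R <- Mod(r)^2
  T <- 4 * eta0 * etas / Mod(denom)^2
  list(R = R, T = T)
}

#' Transfer-matrix reflectance of a planar layer stack
#'
#' Exact coherent reflectance of a one-dimensional stack of lossless planar
#' layers via the characteristic-matrix method, per wavelength.  For
#' unpolarized light the s and p intensities are averaged.  For lossless
#' media `R + T = 1` to numerical precision.  This 1D solver stands in for
#' grid-based electromagnetic simulation of laterally uniform stacks, for
#' which the two are physically equivalent, but is exact and fast.
#'
#' @param stack A [layer_stack()].
#' @param wavelengths Wavelength grid, nm (default [visible_grid()]).
#' @param geom An [incidence_geometry()].
#' @return A [spectrum()] of reflectance.
#' @examples
#' st <- sample_stack(stack_spec(d1_mean = 160, d2_mean = 4, n_periods = 50))
#' sp <- tmm_reflectance(st)
#' sp$wavelength_nm[which.max(sp$reflectance)]  # green stop band ~531 nm
#' @export
tmm_reflectance <- function(stack, wavelengths = visible_grid(),
                            geom = incidence_geometry()) {
  if (!inherits(stack, "layer_stack")) stop("'stack' must be a layer_stack")
  if (length(wavelengths) == 0) stop("empty wavelength grid")
  R <- switch(geom$polarization,
              s = tmm_one_pol(stack, wavelengths, geom$theta, "s")$R,
              p = tmm_one_pol(stack, wavelengths, geom$theta, "p")$R,
              unpolarized = if (geom$theta == 0) {
                tmm_one_pol(stack, wavelengths, 0, "s")$R  # s = p at normal
              } else {
                (tmm_one_pol(stack, wavelengths, geom$theta, "s")$R +
                   tmm_one_pol(stack, wavelengths, geom$theta, "p")$R) / 2
              })
  spectrum(wavelengths, pmin(pmax(R, 0), 1))
}

#' Transmittance companion to [tmm_reflectance()]
#'
#' @inheritParams tmm_reflectance
#' @return A [spectrum()] whose values are transmittance.
#' @export
tmm_transmittance <- function(stack, wavelengths = visible_grid(),
                              geom = incidence_geometry()) {
  T <- switch(geom$polarization,
              s = tmm_one_pol(stack, wavelengths, geom$theta, "s")$T,
              p = tmm_one_pol(stack, wavelengths, geom$theta, "p")$T,
              unpolarized = if (geom$theta == 0) {
                tmm_one_pol(stack, wavelengths, 0, "s")$T
              } else {
                (tmm_one_pol(stack, wavelengths, geom$theta, "s")$T +
                   tmm_one_pol(stack, wavelengths, geom$theta, "p")$T) / 2
              })
  spectrum(wavelengths, pmin(pmax(T, 0), 1))
}

#' Disorder-averaged reflectance of a stochastic stack family
#'
#' Draws `n_realizations` stacks from the spec (realization i uses seed
#' `spec$seed + i - 1`), solves each exactly, and returns the arithmetic
#' mean of the intensity spectra.  Intensity (not amplitude) averaging
#' models distinct lateral patches of the nacre adding incoherently at the
#' detector.  With all SDs zero every realization is identical and the
#' result equals the deterministic spectrum.
#'
#' @param spec A [stack_spec()].
#' @param n_realizations Number of independent stacks to average (>= 1).
#' @param wavelengths Wavelength grid, nm.
#' @param geom An [incidence_geometry()].
#' @return A [spectrum()]; the per-wavelength Monte-Carlo standard error is
#'   attached as attribute `"mc_se"` (zero when `n_realizations = 1` or the
#'   spec is deterministic).
#' @export
ensemble_reflectance <- function(spec, n_realizations = 100,
                                 wavelengths = visible_grid(),
                                 geom = incidence_geometry()) {
  if (n_realizations < 1) stop("'n_realizations' must be >= 1")
  deterministic <- spec$d1_sd == 0 && spec$d2_sd == 0
  if (deterministic) {
    out <- tmm_reflectance(sample_stack(spec), wavelengths, geom)
    attr(out, "mc_se") <- rep(0, length(wavelengths))
    return(out)
  }
  acc <- acc2 <- rep(0, length(wavelengths))
  for (i in seq_len(n_realizations)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    Ri <- tmm_reflectance(sample_stack(spec_i), wavelengths, geom)$reflectance
    acc <- acc + Ri
    acc2 <- acc2 + Ri^2
  }
  m <- acc / n_realizations
  se <- if (n_realizations > 1)
    sqrt(pmax(acc2 / n_realizations - m^2, 0) / (n_realizations - 1))
  else rep(0, length(wavelengths))
  out <- spectrum(wavelengths, m)
  attr(out, "mc_se") <- se
  out
}

#' Reflectance at a set of incidence angles
#'
#' One spectrum per angle, for studying iridescence: the stop band of a
#' periodic stack blue-shifts as the viewing angle tilts away from the
#' normal, following the Bragg-Snell relation.
#'
#' @param stack A [layer_stack()].
#' @param wavelengths Wavelength grid, nm.
#' @param thetas Angles in degrees, each in `[0, 85]`.
#' @param polarization Passed to [incidence_geometry()].
#' @return A named list of [spectrum()] objects (`"theta=0"`, ...).
#' @export
angle_scan <- function(stack, wavelengths = visible_grid(),
                       thetas = c(0, 15, 30, 45),
                       polarization = "unpolarized") {
  if (any(thetas < 0 | thetas > 85)) stop("angles must be in [0, 85] degrees")
  out <- lapply(thetas, function(th)
    tmm_reflectance(stack, wavelengths,
                    incidence_geometry(th, polarization)))
  names(out) <- sprintf("theta=%g", thetas)
  out
}
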
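#' Peak statistics of a reflectance spectrum
#'
#' Summarizes a spectrum the way nacre reflectance bands are described:
#' the peak wavelength (global maximum), the full width at half maximum of
#' the band above its baseline, the peak reflectance, and the off-band
#' baseline — the "white noise" level that washes color out.
#'
#' The half-maximum level is `baseline + (peak - baseline) / 2`; the FWHM
#' spans the outermost half-maximum crossings, located by linear
#' interpolation (clamped to the grid edge when the band is still above
#' half maximum there, so the value is then a lower bound).  The baseline
#' is the median reflectance outside `lambda_max +/- 1.5 * FWHM`, iterated
#' once from an initial whole-spectrum median so that the window is stable
#' against band asymmetry.  A flat spectrum has no peak
#' (`lambda_max = NA`); a band rising less than `min_contrast` above the
#' baseline — e.g. the residual slow oscillation of a one-period stack —
#' is not a resolvable interference band and has `fwhm = NA`.
#'
#' @param sp A [spectrum()].
#' @param flat_tol Spectra with total range below this are declared flat.
#' @param min_contrast Minimum peak height above baseline (reflectance
#'   units) for a band to count as resolved; default 0.03, on the order of
#'   the broadband measurement noise of reflectance spectra.
#' @return An object of class `peak_stats`: list with `lambda_max`,
#'   `fwhm`, `peak_reflectance`, `baseline`.
#' @examples
#' st <- sample_stack(stack_spec(d1_mean = 160, d2_mean = 4, n_periods = 100))
#' peak_stats(tmm_reflectance(st))
#' @export
peak_stats <- function(sp, flat_tol = 1e-9, min_contrast = 0.03) {
  stopifnot(inherits(sp, "spectrum"))
  wl <- sp$wavelength_nm
  v <- sp$reflectance
  if (max(v) - min(v) < flat_tol) {
    return(structure(list(lambda_max = NA_real_, fwhm = NA_real_,
                          peak_reflectance = max(v),
                          baseline = stats::median(v)),
                     class = "peak_stats"))
  }
  i_max <- which.max(v)
  lambda_max <- wl[i_max]
  peak <- v[i_max]

  # Width between the outermost half-maximum crossings.  Using the
  # outermost (not the peak-nearest) crossings makes the measure the
  # envelope width of the band, which stays meaningful for the rippled
  # plateau spectra of chirped-period stacks where interference fringes
  # dip below half maximum inside the band.  A band still above half
  # maximum at a grid edge is clamped there, so the value is then a lower
  # bound on the true width.
  measure_fwhm <- function(baseline) {
    half <- baseline + (peak - baseline) / 2
    above <- which(v >= half)
    lo <- min(above)
    hi <- max(above)
    left <- if (lo == 1L) wl[1]
    else wl[lo - 1] +
      (half - v[lo - 1]) * (wl[lo] - wl[lo - 1]) / (v[lo] - v[lo - 1])
    right <- if (hi == length(v)) wl[length(v)]
    else wl[hi] +
      (v[hi] - half) * (wl[hi + 1] - wl[hi]) / (v[hi] - v[hi + 1])
    right - left
  }

  fwhm0 <- measure_fwhm(stats::median(v))
  baseline <- stats::median(v)
  if (is.finite(fwhm0)) {
    outside <- abs(wl - lambda_max) > 1.5 * fwhm0
    if (sum(outside) >= 5) baseline <- stats::median(v[outside])
  }
  fwhm <- measure_fwhm(baseline)
  resolvable <- peak - baseline >= min_contrast
  structure(list(lambda_max = lambda_max,
                 fwhm = if (resolvable && is.finite(fwhm) && fwhm > 0)
                   fwhm else NA_real_,
                 peak_reflectance = peak, baseline = baseline),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf(
    "peak_stats: lambda_max = %s nm, FWHM = %s nm, peak = %.4f, baseline = %.4f\n",
    format(x$lambda_max), format(x$fwhm), x$peak_reflectance, x$baseline))
  invisible(x)
}

#' CIE 1931 chromaticity and saturation of a reflectance spectrum
#'
#' Integrates reflectance x illuminant x color-matching functions over the
#' wavelength grid to get tristimulus X, Y, Z, normalizes to chromaticity
#' `(x, y, z)` with `x + y + z = 1`, and reports saturation as the
#' Euclidean distance of `(x, y)` from the white point of the same
#' illuminant computed on the same grid (so a flat spectrum has saturation
#' exactly 0).  Chromaticity is invariant under positive scaling of the
#' spectrum; adding a flat background pulls it toward the white point.
#'
#' @param sp A [spectrum()] on a visible-range grid.
#' @param illuminant `"E"` (equal energy, default) or `"D65"`.
#' @return An object of class `chromaticity`: list with `x`, `y`, `z`,
#'   `saturation`, `XYZ` and `white_point`.
#' @examples
#' flat <- spectrum(visible_grid(), rep(0.3, 401))
#' spectrum_to_chromaticity(flat)$saturation   # 0
#' @export
spectrum_to_chromaticity <- function(sp, illuminant = c("E", "D65")) {
  stopifnot(inherits(sp, "spectrum"))
  illuminant <- match.arg(illuminant)
  wl <- sp$wavelength_nm
  cmf <- cie1931_cmf(wl)
  spd <- illuminant_spd(illuminant, wl)
  tristim <- function(refl) {
    w <- spd * refl
    c(X = trapz(wl, w * cmf$xbar), Y = trapz(wl, w * cmf$ybar),
      Z = trapz(wl, w * cmf$zbar))
  }
  XYZ <- tristim(sp$reflectance)
  if (sum(XYZ) <= 0)
    stop("all-zero spectrum: chromaticity undefined")
  xyz <- XYZ / sum(XYZ)
  XYZw <- tristim(rep(1, length(wl)))
  white <- XYZw[1:2] / sum(XYZw)
  sat <- sqrt((xyz[1] - white[1])^2 + (xyz[2] - white[2])^2)
  structure(list(x = unname(xyz[1]), y = unname(xyz[2]), z = unname(xyz[3]),
                 saturation = unname(sat), XYZ = XYZ,
                 white_point = unname(white)),
            class = "chromaticity")
}

#' @export
print.chromaticity <- function(x, ...) {
  cat(sprintf("chromaticity: (x, y) = (%.4f, %.4f), saturation = %.4f\n",
              x$x, x$y, x$saturation))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Rank spectra by color saturation
#'
#' Orders spectra from most to least saturated under a common illuminant.
#' Ties are broken by peak wavelength (ascending), then input order, so
#' the ranking is deterministic.
#'
#' @param spectra A list of [spectrum()] objects (length >= 2).
#' @param illuminant Passed to [spectrum_to_chromaticity()].
#' @return Data frame with one row per input spectrum, most saturated
#'   first: `input`, `lambda_max`, `x`, `y`, `saturation`, `rank`.
#' @export
compare_saturation <- function(spectra, illuminant = c("E", "D65")) {
  illuminant <- match.arg(illuminant)
  if (length(spectra) < 2) stop("need at least two spectra to rank")
  rows <- lapply(seq_along(spectra), function(i) {
    ch <- spectrum_to_chromaticity(spectra[[i]], illuminant)
    ps <- peak_stats(spectra[[i]])
    data.frame(input = i, lambda_max = ps$lambda_max, x = ch$x, y = ch$y,
               saturation = ch$saturation)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$saturation,
               ifelse(is.na(out$lambda_max), Inf, out$lambda_max),
               out$input)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
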
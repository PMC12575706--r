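# Experiment runners: structure -> spectra -> band statistics -> color,
# one tidy data frame per experiment, fully reproducible from (config, seed).

summarize_ensemble <- function(spec, reps, wavelengths, illuminant = "E") {
  sp <- ensemble_reflectance(spec, n_realizations = reps,
                             wavelengths = wavelengths)
  ps <- peak_stats(sp)
  ch <- spectrum_to_chromaticity(sp, illuminant)
  list(spectrum = sp, lambda_max = ps$lambda_max, fwhm = ps$fwhm,
       peak = ps$peak_reflectance, baseline = ps$baseline,
       saturation = ch$saturation,
       mc_se = mean(attr(sp, "mc_se")))
}

#' Plate-thickness scan: color vs d1, band broadening vs disorder
#'
#' For each plate thickness, solves the disorder-free stack and the
#' disordered ensemble (plate-thickness SD as observed on real blue /
#' green / red Ammolite) and tabulates peak wavelength, FWHM and
#' saturation.  Reproduces the two textbook facts of nacre coloration:
#' the reflection peak moves to longer wavelengths as d1 grows, and
#' thickness disorder broadens the band.
#'
#' @param d1 Plate thicknesses to scan, nm.
#' @param d1_sd Matching plate-thickness SDs, nm (recycled).
#' @param d2 Gap width, nm (air gap by default).
#' @param n_periods Periods per stack.
#' @param reps Realizations per disordered ensemble.
#' @param seed Base RNG seed.
#' @param wavelengths Wavelength grid, nm.
#' @return Data frame with one row per (d1, sd) condition:
#'   `d1`, `sd`, `lambda_max`, `fwhm`, `peak`, `baseline`, `saturation`.
#' @export
run_d1_scan <- function(d1 = c(137, 157, 194), d1_sd = c(18, 8, 15),
                        d2 = 4, n_periods = 300, reps = 100, seed = 1L,
                        wavelengths = visible_grid()) {
  d1_sd <- rep_len(d1_sd, length(d1))
  rows <- list()
  for (i in seq_along(d1)) {
    for (sd in unique(c(0, d1_sd[i]))) {
      spec <- stack_spec(d1_mean = d1[i], d1_sd = sd, d2_mean = d2,
                         n_periods = n_periods, seed = seed + 1000L * i)
      s <- summarize_ensemble(spec, if (sd == 0) 1 else reps, wavelengths)
      rows[[length(rows) + 1]] <-
        data.frame(d1 = d1[i], sd = sd, lambda_max = s$lambda_max,
                   fwhm = s$fwhm, peak = s$peak, baseline = s$baseline,
                   saturation = s$saturation)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gap-width scan: the nanogap sweet spot
#'
#' Holds the plate statistics at the disordered reference condition
#' (d1 = 150 nm, SD 15 nm) and scans the gap width for air-filled gaps
#' (Ammolite-like) and organic-filled gaps (abalone/nautilus-like).  The
#' expected pattern: shrinking an air gap below ~4 nm starves the per-gap
#' reflection and the band weakens; widening it toward 20 nm raises
#' broadband "white noise" that desaturates the color; ~4 nm maximizes
#' saturation.  Raising the gap index to 1.43 cuts the index contrast and
#' the peak reflectance with it.
#'
#' @param d2 Gap widths to scan, nm.
#' @param n2 Gap refractive indices to scan.
#' @param d1,d1_sd Plate thickness mean and SD, nm.
#' @param n_periods,reps,seed,wavelengths As in [run_d1_scan()].
#' @return Data frame with one row per (n2, d2):
#'   `n2`, `d2`, `lambda_max`, `fwhm`, `peak`, `baseline`, `saturation`.
#' @export
run_d2_scan <- function(d2 = c(1, 4, 11, 20), n2 = c(1.00, 1.43),
                        d1 = 150, d1_sd = 15, n_periods = 300, reps = 100,
                        seed = 1L, wavelengths = visible_grid()) {
  rows <- list()
  for (k in seq_along(n2)) {
    for (i in seq_along(d2)) {
      spec <- stack_spec(d1_mean = d1, d1_sd = d1_sd, d2_mean = d2[i],
                         n_periods = n_periods,
                         refr = refractive_model(n2 = n2[k]),
                         seed = seed + 1000L * i + 100000L * k)
      s <- summarize_ensemble(spec, reps, wavelengths)
      rows[[length(rows) + 1]] <-
        data.frame(n2 = n2[k], d2 = d2[i], lambda_max = s$lambda_max,
                   fwhm = s$fwhm, peak = s$peak, baseline = s$baseline,
                   saturation = s$saturation)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Period-homogeneity scan: constant vs drifting lamination period
#'
#' Compares stacks whose lamination period is constant with depth
#' (Ammolite-like) against stacks whose mean plate thickness drifts
#' linearly (abalone / Madagascar-like), at matched mean period.  Drift
#' spreads the local Bragg condition over depth, so the reflection band
#' broadens and saturation drops as the drift rate grows.
#'
#' @param drift_rates Drift of mean plate thickness, nm per period.
#' @param d1_mean Mean plate thickness at mid-stack, nm (each drifting
#'   profile is centred on this value so mean period is matched).
#' @param d2 Gap width, nm.
#' @param n_periods Periods per stack.
#' @param wavelengths Wavelength grid, nm.
#' @return Data frame: `drift_rate`, `profile`, `lambda_max`, `fwhm`,
#'   `saturation`.
#' @export
run_homogeneity_scan <- function(drift_rates = c(0, 0.05, 0.1),
                                 d1_mean = 160, d2 = 4, n_periods = 300,
                                 wavelengths = visible_grid()) {
  rows <- list()
  for (rate in drift_rates) {
    start <- d1_mean - rate * (n_periods - 1) / 2
    spec <- if (rate == 0)
      stack_spec(d1_mean = d1_mean, d2_mean = d2, n_periods = n_periods)
    else
      stack_spec(d1_mean = start, d2_mean = d2, n_periods = n_periods,
                 profile = "linear_drift", drift_rate = rate)
    sp <- tmm_reflectance(sample_stack(spec), wavelengths)
    ps <- peak_stats(sp)
    ch <- spectrum_to_chromaticity(sp)
    rows[[length(rows) + 1]] <-
      data.frame(drift_rate = rate,
                 profile = if (rate == 0) "constant" else "linear_drift",
                 lambda_max = ps$lambda_max, fwhm = ps$fwhm,
                 saturation = ch$saturation)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reflection-order scan: peak wavelength vs lamination period
#'
#' For a grid of lamination periods, computes the Bragg-Snell peak for the
#' order that lands in the visible window and cross-checks it against the
#' transfer-matrix peak of the corresponding ordered stack.  Ammolite-scale
#' periods reflect at m = 1; the thicker abalone periods at m = 2.
#'
#' @param d1 Plate thicknesses to scan, nm.
#' @param d2 Gap width, nm.
#' @param n2 Gap index.
#' @param n_periods Periods per stack.
#' @return Data frame: `d1`, `d`, `n_eff`, `m`, `lambda_bragg`,
#'   `lambda_tmm`.
#' @export
run_order_scan <- function(d1 = seq(140, 310, by = 10), d2 = 4, n2 = 1.00,
                           n_periods = 300) {
  wl <- visible_grid()
  rows <- lapply(d1, function(p) {
    d <- p + d2
    ne <- effective_index(p, d2, n2 = n2)
    m <- choose_order(d, ne)
    lam_b <- if (is.na(m)) NA_real_ else bragg_wavelength(d, ne, m = m)
    sp <- tmm_reflectance(
      sample_stack(stack_spec(d1_mean = p, d2_mean = d2, n_periods = n_periods,
                              refr = refractive_model(n2 = n2))), wl)
    data.frame(d1 = p, d = d, n_eff = ne, m = m, lambda_bragg = lam_b,
               lambda_tmm = peak_stats(sp)$lambda_max)
  })
  do.call(rbind, rows)
}

#' Iridescence scan: peak wavelength vs viewing angle
#'
#' @param thetas Angles, degrees.
#' @param d1,d2 Plate and gap thickness, nm.
#' @param n_periods Periods per stack.
#' @return Data frame: `theta`, `lambda_max`, `lambda_bragg`.
#' @export
run_angle_scan <- function(thetas = c(0, 15, 30, 45), d1 = 160, d2 = 4,
                           n_periods = 300) {
  st <- sample_stack(stack_spec(d1_mean = d1, d2_mean = d2,
                                n_periods = n_periods))
  ne <- effective_index(d1, d2)
  sps <- angle_scan(st, thetas = thetas)
  rows <- lapply(seq_along(thetas), function(i)
    data.frame(theta = thetas[i],
               lambda_max = peak_stats(sps[[i]])$lambda_max,
               lambda_bragg = bragg_wavelength(d1 + d2, ne,
                                               theta = thetas[i])))
  do.call(rbind, rows)
}

#' Write the canonical nacre stack specs (and small spectra) to disk
#'
#' Emits one YAML `stack_spec` per canonical sample — blue/green/red
#' Ammolite (air nanogaps, homogeneous period), blue/green abalone
#' (organic sheets), a nautilus-like wide-gap stack and a Madagascar-like
#' stack with collapsed gaps and a drifting period — plus a small
#' precomputed reflectance spectrum CSV (5 nm grid) for each Ammolite
#' color.  Deterministic: the same seed writes identical files.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Base seed stored in the specs.
#' @return Character vector of paths written, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  air <- refractive_model(n2 = 1.00)
  org <- refractive_model(n2 = 1.43)
  specs <- list(
    ammolite_red   = stack_spec(190, 15, 4, 2, 300, refr = air, seed = seed),
    ammolite_green = stack_spec(160, 8, 4, 2, 300, refr = air,
                                seed = seed + 1L),
    ammolite_blue  = stack_spec(140, 18, 4, 2, 300, refr = air,
                                seed = seed + 2L),
    abalone_blue   = stack_spec(250, 15, 11, 3, 300, refr = org,
                                seed = seed + 3L),
    abalone_green  = stack_spec(300, 15, 11, 3, 300, refr = org,
                                seed = seed + 4L),
    nautilus_like  = stack_spec(350, 20, 20, 5, 300, refr = org,
                                seed = seed + 5L),
    madagascar_like = stack_spec(150, 15, 1, 0.5, 300,
                                 profile = "linear_drift", drift_rate = 0.1,
                                 refr = air, seed = seed + 6L))
  paths <- character(0)
  for (nm in names(specs)) {
    p <- file.path(outdir, paste0(nm, ".yaml"))
    write_stack_spec(specs[[nm]], p)
    paths <- c(paths, p)
  }
  wl <- visible_grid(by = 5)
  for (nm in c("ammolite_red", "ammolite_green", "ammolite_blue")) {
    sp <- ensemble_reflectance(specs[[nm]], n_realizations = 20,
                               wavelengths = wl)
    p <- file.path(outdir, paste0(nm, "_spectrum.csv"))
    write_spectrum(sp, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
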
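#' Read and write spectra as two-column CSV
#'
#' The interchange format for spectra: a header line
#' `wavelength_nm,reflectance` followed by one row per wavelength.
#'
#' @param sp A [spectrum()].
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns a [spectrum()].
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  utils::write.csv(as.data.frame(sp), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "reflectance")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have a 'wavelength_nm,reflectance' header")
  spectrum(df$wavelength_nm, df$reflectance)
}

#' Read and write explicit layer stacks as CSV
#'
#' Two columns: `index` (refractive index) and `thickness_nm`, one row per
#' layer from the surface down.  Ambient and substrate indices travel in
#' comment-free extra columns on the first row would be fragile, so they
#' are stored as ordinary columns repeated down the file.
#'
#' @param stack A [layer_stack()].
#' @param path File path.
#' @export
write_layer_stack <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  df <- data.frame(index = stack$index, thickness_nm = stack$thickness,
                   n_ambient = stack$n_ambient,
                   n_substrate = stack$n_substrate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layer_stack
#' @export
read_layer_stack <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("index", "thickness_nm") %in% names(df)))
    stop("layer-stack CSV must have 'index' and 'thickness_nm' columns")
  layer_stack(df$index, df$thickness_nm,
              n_ambient = if ("n_ambient" %in% names(df))
                df$n_ambient[1] else 1.00,
              n_substrate = if ("n_substrate" %in% names(df))
                df$n_substrate[1] else 1.63)
}

#' Serialize a stack spec to YAML and back
#'
#' @param spec A [stack_spec()].
#' @param path File path (`.yaml`).
#' @export
write_stack_spec <- function(spec, path) {
  stopifnot(inherits(spec, "stack_spec"))
  lst <- unclass(spec)
  lst$refr <- unclass(lst$refr)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_stack_spec
#' @export
read_stack_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  refr <- do.call(refractive_model, lst$refr)
  stack_spec(d1_mean = lst$d1_mean, d1_sd = lst$d1_sd,
             d2_mean = lst$d2_mean, d2_sd = lst$d2_sd,
             n_periods = lst$n_periods, profile = lst$profile,
             drift_rate = if (is.null(lst$drift_rate)) 0 else lst$drift_rate,
             d1_profile = lst$d1_profile, refr = refr, seed = lst$seed)
}

#' Write spectral/color summary statistics as JSON
#'
#' Bundles [peak_stats()] and [spectrum_to_chromaticity()] of a spectrum
#' into one flat JSON object: `lambda_max`, `fwhm`, `peak`, `baseline`,
#' `x`, `y`, `z`, `saturation`.
#'
#' @param sp A [spectrum()].
#' @param path Output path; `NULL` returns the list without writing.
#' @param illuminant Passed to [spectrum_to_chromaticity()].
#' @return The summary list, invisibly when written.
#' @export
write_spectrum_stats <- function(sp, path = NULL, illuminant = "E") {
  ps <- peak_stats(sp)
  ch <- spectrum_to_chromaticity(sp, illuminant)
  out <- list(lambda_max = ps$lambda_max, fwhm = ps$fwhm,
              peak = ps$peak_reflectance, baseline = ps$baseline,
              x = ch$x, y = ch$y, z = ch$z, saturation = ch$saturation)
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out)
}
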
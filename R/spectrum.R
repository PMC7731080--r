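#' Impedance spectrum
#'
#' A frequency grid with impedance magnitudes — the object that is measured,
#' simulated and fitted throughout the package. Frequencies must be strictly
#' increasing and positive; magnitudes positive. Units are carried as tags
#' (`"hz"`/`"khz"`, `"ohm"`/`"kohm"`) so that conversions are always explicit.
#'
#' @param frequency Numeric vector of frequencies, strictly increasing, > 0.
#' @param z_mod Numeric vector of impedance magnitudes, > 0, same length.
#' @param f_unit Frequency unit tag: `"hz"` or `"khz"`.
#' @param z_unit Magnitude unit tag: `"ohm"` or `"kohm"`.
#' @param meta Optional named list of metadata (e.g. `glucose_mmol_l`,
#'   `label`, `noise_sd`, `seed`).
#' @return An object of class `eis_spectrum`.
#' @examples
#' s <- eis_spectrum(c(50, 60, 70), c(97.9, 78.7, 66.9),
#'                   f_unit = "khz", z_unit = "kohm")
#' as.data.frame(s)
#' @export
eis_spectrum <- function(frequency, z_mod, f_unit = c("hz", "khz"),
                         z_unit = c("ohm", "kohm"), meta = list()) {
  f_unit <- match.arg(f_unit)
  z_unit <- match.arg(z_unit)
  if (!is.numeric(frequency) || !is.numeric(z_mod))
    stop_validation("frequency and z_mod must be numeric")
  if (length(frequency) != length(z_mod) || length(frequency) < 1L)
    stop_validation("frequency and z_mod must have equal length >= 1")
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop_validation("frequencies must be positive and finite")
  if (is.unsorted(frequency, strictly = TRUE))
    stop_validation("frequencies must be strictly increasing")
  if (any(!is.finite(z_mod)) || any(z_mod <= 0))
    stop_validation("impedance magnitudes must be positive and finite")
  if (!is.list(meta))
    stop_validation("meta must be a list")
  structure(list(frequency = as.numeric(frequency),
                 z_mod = as.numeric(z_mod),
                 f_unit = f_unit, z_unit = z_unit, meta = meta),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d points, %.4g-%.4g %s, |Z| in %s\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$f_unit, x$z_unit))
  if (!is.null(x$meta$glucose_mmol_l))
    cat(sprintf("  glucose: %g mmol/L\n", x$meta$glucose_mmol_l))
  if (!is.null(x$meta$label)) cat(sprintf("  label: %s\n", x$meta$label))
  print(utils::head(as.data.frame(x), 6))
  if (length(x$frequency) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.eis_spectrum <- function(x, ...) {
  df <- data.frame(frequency = x$frequency, z_mod = x$z_mod)
  names(df) <- c(paste0("frequency_", x$f_unit), paste0("z_mod_", x$z_unit))
  df
}

#' @export
length.eis_spectrum <- function(x) length(x$frequency)

#' Normalization scales for dimensionless spectra
#'
#' Scale factors used to render a spectrum dimensionless: magnitudes are
#' divided by `Z_norm` and frequencies by `f_norm` (`k_norm`, `kprime_norm`
#' apply to the volume fractions in the same convention). The numeric values
#' are user-supplied; the model itself fixes none of them.
#'
#' @param Z_norm Impedance scale, in the spectrum's magnitude unit.
#' @param k_norm,kprime_norm Volume-fraction scales, dimensionless.
#' @param f_norm Frequency scale, in the spectrum's frequency unit.
#' @return An object of class `normalization_scales`.
#' @export
normalization_scales <- function(Z_norm = 1, k_norm = 1, kprime_norm = 1,
                                 f_norm = 1) {
  v <- c(Z_norm, k_norm, kprime_norm, f_norm)
  if (any(!is.finite(v)) || any(v <= 0))
    stop_validation("all normalization scales must be strictly positive")
  structure(list(Z_norm = Z_norm, k_norm = k_norm,
                 kprime_norm = kprime_norm, f_norm = f_norm),
            class = "normalization_scales")
}

#' Normalize / denormalize a spectrum
#'
#' Element-wise division of frequencies by `f_norm` and magnitudes by
#' `Z_norm` (multiplication for the inverse). The round trip
#' `denormalize_spectrum(normalize_spectrum(s, sc), sc)` is the identity up
#' to floating-point precision. Unit tags are preserved: the caller decides
#' what the normalized axes mean.
#'
#' @param spectrum An [eis_spectrum()].
#' @param scales A [normalization_scales()].
#' @return A new `eis_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, scales) {
  stopifnot(inherits(spectrum, "eis_spectrum"),
            inherits(scales, "normalization_scales"))
  eis_spectrum(spectrum$frequency / scales$f_norm,
               spectrum$z_mod / scales$Z_norm,
               f_unit = spectrum$f_unit, z_unit = spectrum$z_unit,
               meta = spectrum$meta)
}

#' @rdname normalize_spectrum
#' @export
denormalize_spectrum <- function(spectrum, scales) {
  stopifnot(inherits(spectrum, "eis_spectrum"),
            inherits(scales, "normalization_scales"))
  eis_spectrum(spectrum$frequency * scales$f_norm,
               spectrum$z_mod * scales$Z_norm,
               f_unit = spectrum$f_unit, z_unit = spectrum$z_unit,
               meta = spectrum$meta)
}
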
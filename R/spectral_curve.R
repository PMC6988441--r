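#' Default wavelength grid
#'
#' Integration grid used throughout the package: 400--700 nm inclusive at
#' 1 nm steps. All spectral integrals use the rectangle rule on this grid.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_grid <- function() 400:700

#' Construct a spectral curve
#'
#' A tabulated function of wavelength: a reflectance (or radiance factor),
#' an illuminant, or a receptor sensitivity. Reflectances normally lie in
#' [0, 1] but radiance factors of fluorescent materials may exceed 1 (up
#' to 1.5); illuminants and sensitivities are unitless relative curves.
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths.
#' @param values non-negative finite numeric vector, same length.
#' @param name optional label carried through for provenance.
#' @return An object of class `spectral_curve`.
#' @export
spectral_curve <- function(wavelengths_nm, values, name = NULL) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have equal length")
  if (length(wavelengths_nm) < 2L)
    stop("a spectral curve needs at least two samples")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and >= 0")
  structure(list(wl = wavelengths_nm, value = values, name = name),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve%s: %d samples, %g-%g nm, range [%.4g, %.4g]>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$wl), min(x$wl), max(x$wl), min(x$value), max(x$value)))
  invisible(x)
}

#' Resample a spectral curve onto a wavelength grid
#'
#' Linear interpolation onto `grid`. Curves already tabulated on `grid`
#' are returned unchanged (lossless). Extrapolation beyond the tabulated
#' support is refused except for a 5 nm guard band, inside which the end
#' value is held constant.
#'
#' @param curve a [spectral_curve()].
#' @param grid target wavelengths (default [default_grid()]).
#' @return A `spectral_curve` on `grid`.
#' @export
resample_spectrum <- function(curve, grid = default_grid()) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (length(curve$wl) == length(grid) && all(curve$wl == grid)) return(curve)
  lo <- min(curve$wl); hi <- max(curve$wl)
  if (min(grid) < lo - 5 || max(grid) > hi + 5)
    stop(sprintf(
      "grid [%g, %g] nm extends more than 5 nm beyond curve support [%g, %g] nm",
      min(grid), max(grid), lo, hi))
  v <- stats::approx(curve$wl, curve$value, xout = grid, rule = 2)$y
  spectral_curve(grid, v, name = curve$name)
}

#' Read a spectrum from a two-column CSV
#'
#' Expects a header row and columns `wavelength_nm,value` (comma separated,
#' '.' decimal). The curve is resampled onto `grid` by linear
#' interpolation; see [resample_spectrum()] for the extrapolation rule.
#'
#' @param path CSV file path.
#' @param grid target grid, or `NULL` to keep the tabulated wavelengths.
#' @return A `spectral_curve`.
#' @export
read_spectrum_csv <- function(path, grid = default_grid()) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("CSV must have columns 'wavelength_nm' and 'value'")
  cur <- spectral_curve(d$wavelength_nm, d$value,
                        name = sub("\\.csv$", "", basename(path)))
  if (is.null(grid)) cur else resample_spectrum(cur, grid)
}

#' Write a spectrum to CSV
#'
#' @param curve a `spectral_curve`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(curve, path) {
  stopifnot(inherits(curve, "spectral_curve"))
  utils::write.csv(data.frame(wavelength_nm = curve$wl, value = curve$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: values of a curve on the default grid, with a length check.
.on_grid <- function(curve, grid = default_grid()) {
  resample_spectrum(curve, grid)$value
}
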
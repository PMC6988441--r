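# Built-in material reflectance registry.
#
# No reflectance spectra are published for the racecourse materials, so the
# registry ships documented parametric stand-ins: a Gaussian chlorophyll
# bump for turf, a rising logistic for birch wood, steep logistic long-pass
# curves for orange paint and yellow card, Gaussian short-wave bumps for
# the blues, flat curves for the EVA whites/blacks and the PTFE standards,
# and a gently blued ramp standing in for sky radiance. Shapes and levels
# are chosen to be realistic for the named materials; they are synthetic
# stand-ins, not measurements.

.gauss <- function(wl, mu, sd) exp(-0.5 * ((wl - mu) / sd)^2)
.logistic <- function(wl, mid, k) 1 / (1 + exp(-(wl - mid) / k))

.material_funs <- list(
  turf         = function(wl) 0.04 + 0.22 * .gauss(wl, 550, 45),
  birch        = function(wl) 0.08 + 0.22 * .logistic(wl, 600, 60),
  orange_paint = function(wl) 0.04 + 0.75 * .logistic(wl, 585, 18),
  white_eva    = function(wl) rep(0.85, length(wl)),
  black_eva    = function(wl) rep(0.04, length(wl)),
  fluoro_yellow_matt = function(wl) 0.05 + 0.80 * .logistic(wl, 515, 15),
  light_blue   = function(wl) 0.08 + 0.50 * .gauss(wl, 465, 45),
  dark_blue    = function(wl) 0.03 + 0.22 * .gauss(wl, 455, 38),
  ptfe_white   = function(wl) rep(0.931, length(wl)),
  ptfe_black   = function(wl) rep(0.0449, length(wl)),
  sky          = function(wl) 0.95 - 0.0022 * (wl - 400)
)

#' Names of the built-in material spectra
#' @return Character vector of registry names.
#' @export
material_names <- function() names(.material_funs)

#' Look up a built-in material reflectance spectrum
#'
#' @param name registry name (see [material_names()]).
#' @param grid wavelength grid.
#' @param gloss if `TRUE`, an additive illuminant-coloured specular
#'   fraction is modelled by [glossy_radiance_factor()] at render time;
#'   here the flag is only recorded in the curve name.
#' @return A `spectral_curve`.
#' @export
material_spectrum <- function(name, grid = default_grid(), gloss = FALSE) {
  f <- .material_funs[[name]]
  if (is.null(f))
    stop("unknown material '", name, "'; registry: ",
         paste(material_names(), collapse = ", "))
  spectral_curve(grid, f(grid),
                 name = if (gloss) paste0(name, "_gloss") else name)
}

#' Dump the material registry to CSV files
#'
#' Writes one `<name>.csv` per registry entry (columns
#' `wavelength_nm,value`) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param grid wavelength grid.
#' @return Invisibly, the written paths.
#' @export
dump_material_spectra <- function(dir, grid = default_grid()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(material_names(), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_spectrum_csv(material_spectrum(nm, grid), p)
    p
  }, character(1))
  invisible(paths)
}

#' Effective radiance factor of the fluorescent yellow card
#'
#' Fluorescence is modelled as an illuminant-dependent radiance factor
#' rather than a full excitation--emission matrix: short-wave illuminant
#' power (below 480 nm) pumps a Gaussian emission band centred at 530 nm,
#' so bluer light yields a larger boost. The total factor is capped at
#' 1.5. With no illuminant power below 480 nm the base reflectance is
#' returned unchanged.
#'
#' @param base the fluorescent material's base reflectance curve.
#' @param illuminant scene illuminant (`spectral_curve`).
#' @param grid wavelength grid.
#' @return A `spectral_curve` of effective radiance factors for rendering.
#' @export
fluorescent_radiance_factor <- function(base, illuminant,
                                        grid = default_grid()) {
  R <- .on_grid(base, grid)
  I <- .on_grid(illuminant, grid)
  pump <- sum(I[grid < 480]) / sum(I)
  boost <- 2.2 * pump * .gauss(grid, 530, 25)
  spectral_curve(grid, pmin(R + boost, 1.5),
                 name = paste0(base$name, "_fluor"))
}

#' Glossy radiance factor
#'
#' Gloss (a covering of glossy vinyl) is modelled as an additive
#' illuminant-coloured specular fraction: a constant fraction of the
#' illuminant is reflected regardless of the body colour, which raises
#' luminance and desaturates the chromatic signal.
#'
#' @param base body reflectance curve.
#' @param specular specular fraction (default 0.08).
#' @param grid wavelength grid.
#' @return A `spectral_curve` of effective radiance factors.
#' @export
glossy_radiance_factor <- function(base, specular = 0.08,
                                   grid = default_grid()) {
  R <- .on_grid(base, grid)
  spectral_curve(grid, pmin(R + specular, 1.5),
                 name = paste0(base$name, "_gloss"))
}
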
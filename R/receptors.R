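#' Visual-pigment sensitivity template
#'
#' A1 visual-pigment absorbance template (Govardovskii et al. 2000 form:
#' alpha band plus the small beta band), parameterized only by the peak
#' wavelength and normalized to a maximum of 1. Ocular-media transmission
#' is not modelled separately; the template stands for the whole-eye
#' sensitivity.
#'
#' @param lambda_max_nm peak wavelength, must lie in [380, 700] and within
#'   the grid support.
#' @param grid wavelength grid (default [default_grid()]).
#' @return A `spectral_curve` with maximum 1 peaking at `lambda_max_nm`
#'   (within one grid step).
#' @export
pigment_template <- function(lambda_max_nm, grid = default_grid()) {
  if (!is.numeric(lambda_max_nm) || length(lambda_max_nm) != 1L ||
      lambda_max_nm < 380 || lambda_max_nm > 700)
    stop("lambda_max_nm must be a single wavelength in [380, 700] nm")
  x <- lambda_max_nm / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max_nm
  bwd <- -40.5 + 0.195 * lambda_max_nm
  beta <- 0.26 * exp(-((grid - lmb) / bwd)^2)
  s <- alpha + beta
  spectral_curve(grid, s / max(s),
                 name = sprintf("pigment_%gnm", lambda_max_nm))
}

#' Construct a receptor
#'
#' @param name channel label, e.g. "SW" or "LW".
#' @param lambda_max_nm peak sensitivity wavelength.
#' @param abundance relative cone density (used for receptor noise).
#' @param sensitivity optional `spectral_curve`; defaults to
#'   [pigment_template()] at `lambda_max_nm`. Must peak at `lambda_max_nm`
#'   within one grid step and have maximum 1.
#' @param grid wavelength grid.
#' @return An object of class `receptor`.
#' @export
receptor <- function(name, lambda_max_nm, abundance,
                     sensitivity = NULL, grid = default_grid()) {
  if (is.null(sensitivity)) sensitivity <- pigment_template(lambda_max_nm, grid)
  sensitivity <- resample_spectrum(sensitivity, grid)
  step <- max(diff(grid))
  pk <- sensitivity$wl[which.max(sensitivity$value)]
  if (abs(pk - lambda_max_nm) > step)
    stop(sprintf("sensitivity peaks at %g nm, not at lambda_max %g nm",
                 pk, lambda_max_nm))
  if (abs(max(sensitivity$value) - 1) > 1e-9)
    stop("sensitivity must be normalized to a maximum of 1")
  if (!is.numeric(abundance) || abundance <= 0)
    stop("abundance must be > 0")
  structure(list(name = name, lambda_max_nm = lambda_max_nm,
                 abundance = abundance, sensitivity = sensitivity),
            class = "receptor")
}

#' Construct a visual system
#'
#' An ordered receptor set plus the noise parameters of the
#' receptor-noise-limited model. The Weber fraction anchors the noise of
#' the most abundant receptor; the per-receptor noise is
#' `e_i = omega * sqrt(eta_max / eta_i)` (see [receptor_noise()]).
#'
#' @param receptors list of [receptor()] objects (>= 2 for colour JNDs).
#' @param weber_fraction omega for the most abundant receptor, in (0, 1).
#' @param luminance_receptor name(s) of the channel(s) used for achromatic
#'   contrast; if several are named their catches are summed. `NULL`
#'   (default) selects the most abundant receptor.
#' @param luminance_weber Weber fraction of the achromatic channel.
#' @return An object of class `visual_system`.
#' @export
visual_system <- function(receptors, weber_fraction = 0.05,
                          luminance_receptor = NULL,
                          luminance_weber = 0.05) {
  if (!all(vapply(receptors, inherits, TRUE, "receptor")))
    stop("receptors must be a list of receptor objects")
  if (weber_fraction <= 0 || weber_fraction >= 1)
    stop("weber_fraction must lie in (0, 1)")
  nm <- vapply(receptors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("receptor names must be unique")
  if (is.null(luminance_receptor)) {
    eta <- vapply(receptors, `[[`, numeric(1), "abundance")
    luminance_receptor <- nm[which.max(eta)]
  }
  if (!all(luminance_receptor %in% nm))
    stop("luminance_receptor not among receptor names: ",
         paste(setdiff(luminance_receptor, nm), collapse = ", "))
  names(receptors) <- nm
  structure(list(receptors = receptors, weber_fraction = weber_fraction,
                 luminance_receptor = luminance_receptor,
                 luminance_weber = luminance_weber),
            class = "visual_system")
}

#' The default horse visual system
#'
#' Dichromat with a shortwave cone peaking at 428 nm and a
#' medium/longwave cone at 539 nm, LW:SW cone abundance 40:5, Weber
#' fraction 0.05 anchored to the abundant LW cone, and an LW achromatic
#' channel with Weber fraction 0.05.
#'
#' @param grid wavelength grid.
#' @param luminance_receptor achromatic channel, "LW" (default) or
#'   `c("SW", "LW")` for a summed-cone channel.
#' @return A `visual_system`.
#' @export
horse_visual_system <- function(grid = default_grid(),
                                luminance_receptor = "LW") {
  visual_system(
    list(receptor("SW", 428, abundance = 5, grid = grid),
         receptor("LW", 539, abundance = 40, grid = grid)),
    weber_fraction = 0.05,
    luminance_receptor = luminance_receptor,
    luminance_weber = 0.05)
}

#' Cone quantum catches of a reflectance under an illuminant
#'
#' Rectangle-rule integral `Q_i = sum R(l) I(l) S_i(l) dl` per receptor.
#' With `adapt = TRUE` (von Kries adaptation, the default) each catch is
#' divided by the catch of a perfect reflector (R == 1) under the same
#' illuminant, so a perfect reflector has catch 1 in every channel and
#' catches are invariant to uniform illuminant scaling.
#'
#' @param reflectance,illuminant `spectral_curve`s (resampled to `grid`).
#' @param system a [visual_system()].
#' @param adapt apply von Kries adaptation?
#' @param grid wavelength grid.
#' @return Named numeric vector of catches, class `cone_catch`, with
#'   attribute `adapted`.
#' @export
cone_catch <- function(reflectance, illuminant, system, adapt = TRUE,
                       grid = default_grid()) {
  stopifnot(inherits(system, "visual_system"))
  R <- .on_grid(reflectance, grid)
  I <- .on_grid(illuminant, grid)
  if (all(I == 0)) stop("illuminant is identically zero")
  dl <- c(diff(grid), utils::tail(diff(grid), 1))
  q <- vapply(system$receptors, function(rec) {
    S <- .on_grid(rec$sensitivity, grid)
    denom <- sum(I * S * dl)
    if (denom <= 0)
      stop(sprintf("receptor %s has zero overlap with the illuminant", rec$name))
    num <- sum(R * I * S * dl)
    if (adapt) num / denom else num
  }, numeric(1))
  structure(q, class = "cone_catch", adapted = adapt)
}
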
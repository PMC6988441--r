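#' The eight light and weather classes
#'
#' Scenes are stratified by time of day (Daytime, Evening) crossed with
#' weather (Sunny, Sunny_CloudCover, Overcast, Shade), giving eight
#' classes. Each class carries the parameters of its parametric daylight
#' illuminant -- amplitude, spectral tilt, curvature -- plus a fence-region
#' shading factor. The shading factor models fences that stand in shadow
#' (sun behind the fence) while the foreground, background, and the
#' calibration standards remain in ambient light; it multiplies the
#' illumination of fence-mounted regions only. Because calibrated images
#' are equalized to in-frame standards (a von Kries normalization), a
#' uniform whole-scene amplitude change cancels exactly; shading relative
#' to the standards is what alters measured luminance.
#'
#' @return Data frame with one row per class: `label`, `time_of_day`,
#'   `weather`, `amplitude`, `tilt`, `curvature`, `fence_shade`.
#' @export
light_conditions <- function() {
  d <- data.frame(
    label = c("Sunny_Daytime", "Sunny_CloudCover_Daytime", "Overcast_Daytime",
              "Shade_Daytime", "Sunny_Evening", "Sunny_CloudCover_Evening",
              "Overcast_Evening", "Shade_Evening"),
    amplitude = c(1.00, 0.85, 0.60, 0.45, 0.70, 0.60, 0.40, 0.30),
    tilt      = c(0.00, -0.10, 0.00, -0.55, 0.45, 0.30, 0.15, -0.35),
    curvature = c(0, 0, 0, 0, 0, 0, 0, 0),
    fence_shade = c(1, 1, 1, 0.6, 1, 1, 1, 0.6),
    stringsAsFactors = FALSE)
  d$time_of_day <- ifelse(grepl("Evening$", d$label), "Evening", "Daytime")
  d$weather <- sub("_(Daytime|Evening)$", "", d$label)
  d
}

# Internal: parameter row for one class, with a helpful error.
.condition_row <- function(condition) {
  lc <- light_conditions()
  i <- match(condition, lc$label)
  if (is.na(i))
    stop("unknown light condition '", condition, "'; valid labels: ",
         paste(lc$label, collapse = ", "))
  lc[i, ]
}

#' Parametric daylight-family illuminant for a light class
#'
#' A smooth three-parameter curve
#' `I(l) = amplitude * (1 + tilt * s + curvature * (s^2 - 1/3))` with
#' `s = (l - 550) / 150`, floored at a small positive value. Negative tilt
#' skews power toward short wavelengths (blue shade light), positive tilt
#' toward long wavelengths (warm evening light); sunny daytime is neutral
#' and overcast is neutral at lower amplitude. An optional seeded jitter
#' perturbs the parameters to emulate within-class variation.
#'
#' @param condition one of the eight labels in [light_conditions()].
#' @param grid wavelength grid.
#' @param jitter_sd relative s.d. of multiplicative parameter jitter
#'   (default 0 = the documented class illuminant).
#' @param seed integer seed used when `jitter_sd > 0`.
#' @return A `spectral_curve`.
#' @export
make_illuminant <- function(condition, grid = default_grid(),
                            jitter_sd = 0, seed = NULL) {
  p <- .condition_row(condition)
  amp <- p$amplitude; tilt <- p$tilt; curv <- p$curvature
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- amp * exp(stats::rnorm(1, 0, jitter_sd))
    tilt <- tilt + stats::rnorm(1, 0, jitter_sd * 0.2)
  }
  s <- (grid - 550) / 150
  v <- amp * (1 + tilt * s + curv * (s^2 - 1 / 3))
  spectral_curve(grid, pmax(v, 1e-6), name = condition)
}
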
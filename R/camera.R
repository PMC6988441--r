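#' Construct a camera model
#'
#' A simulated RAW-style camera: per-channel spectral sensitivities, a
#' monotone power-law response (`counts = max_count * linear^(1/gamma)`),
#' additive Gaussian read noise in counts, and an integer bit depth.
#'
#' @param channel_sensitivities named list of `spectral_curve`s, one per
#'   channel (non-negative).
#' @param gamma response exponent (> 0); `gamma = 1` is a linear camera.
#' @param noise_sd additive Gaussian s.d. in counts.
#' @param bit_depth stored integer range is `[0, 2^bit_depth - 1]`.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(channel_sensitivities, gamma = 2.2, noise_sd = 0,
                         bit_depth = 16) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (is.null(names(channel_sensitivities)))
    names(channel_sensitivities) <- paste0("ch", seq_along(channel_sensitivities))
  for (cs in channel_sensitivities) {
    stopifnot(inherits(cs, "spectral_curve"))
    if (any(cs$value < 0)) stop("channel sensitivities must be non-negative")
  }
  structure(list(channel_sensitivities = channel_sensitivities,
                 gamma = gamma, noise_sd = noise_sd, bit_depth = bit_depth,
                 max_count = 2^bit_depth - 1),
            class = "camera_model")
}

#' The default test-bench camera
#'
#' Spectral sensitivities of real camera dyes are unpublished, so the
#' package ships a synthetic test-bench camera. Its three channels are
#' broad unimodal pigment-template curves (peaks near 428, 539 and 600
#' nm) mixed by a fixed invertible matrix, so each channel looks like an
#' ordinary blue/green/red dye curve while the horse SW and LW
#' sensitivities lie exactly in the linear span of the channel set. That
#' span property makes the camera-to-cone mapping well-posed (no
#' metamerism with respect to horse vision), mirroring the near-exact
#' accuracy reported for calibrated multispectral workflows; see the
#' methods vignette for the rationale and its limits.
#'
#' @param gamma response exponent (default 2.2).
#' @param noise_sd read noise in counts (default 0).
#' @param grid wavelength grid.
#' @return A `camera_model` with channels `B`, `G`, `R`.
#' @export
default_camera <- function(gamma = 2.2, noise_sd = 0, grid = default_grid()) {
  basis <- cbind(pigment_template(428, grid)$value,
                 pigment_template(539, grid)$value,
                 pigment_template(600, grid)$value)
  mix <- rbind(c(1.00, 0.12, 0.02),
               c(0.05, 1.00, 0.08),
               c(0.00, 0.06, 1.00))
  ch <- basis %*% t(mix)
  ch <- sweep(ch, 2, apply(ch, 2, max), `/`)
  camera_model(list(B = spectral_curve(grid, ch[, 1], "cam_B"),
                    G = spectral_curve(grid, ch[, 2], "cam_G"),
                    R = spectral_curve(grid, ch[, 3], "cam_R")),
               gamma = gamma, noise_sd = noise_sd)
}

#' Camera response: linear radiance to stored counts
#'
#' Applies the power-law nonlinearity and quantizes to the camera's bit
#' depth; values outside [0, 1] are clipped. If `camera$noise_sd > 0`,
#' seeded Gaussian noise is added in count space before quantization.
#'
#' @param linear array/matrix of linear values in [0, 1] (fraction of
#'   full-scale radiance).
#' @param camera a [camera_model()].
#' @param seed optional integer seed for the noise draw.
#' @return Integer-valued array of stored counts, same shape.
#' @export
camera_response <- function(linear, camera, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  x <- pmin(pmax(linear, 0), 1)
  counts <- camera$max_count * x^(1 / camera$gamma)
  if (camera$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    counts <- counts + stats::rnorm(length(counts), 0, camera$noise_sd)
  }
  out <- round(pmin(pmax(counts, 0), camera$max_count))
  dim(out) <- dim(linear)
  out
}

#' Linearize stored counts
#'
#' Inverts the camera response so values are again proportional to
#' radiance: `linear = (counts / max_count)^gamma`. Saturated pixels
#' (counts at or above 99.5 % of full scale) are flagged; it is an error
#' for more than half of a standard region to saturate (checked in
#' [equalize_to_standards()]).
#'
#' @param counts stored-count array (any shape; channels in the last
#'   dimension for multichannel images).
#' @param camera a [camera_model()].
#' @return The linear array with attribute `saturated` (logical array of
#'   the same shape) and `saturated_fraction`.
#' @export
linearize <- function(counts, camera) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(counts < 0) || any(counts > camera$max_count))
    stop("counts outside the camera bit depth")
  sat <- counts >= 0.995 * camera$max_count
  lin <- (counts / camera$max_count)^camera$gamma
  dim(lin) <- dim(counts); dim(sat) <- dim(counts)
  attr(lin, "saturated") <- sat
  attr(lin, "saturated_fraction") <- mean(sat)
  lin
}

#' Construct a standard set
#'
#' The two in-frame diffuse PTFE reflectance standards and their regions.
#'
#' @param white_reflectance,black_reflectance known reflectances as
#'   fractions (defaults 0.931 and 0.0449).
#' @param white_region,black_region logical matrices (TRUE inside the
#'   patch), non-empty and disjoint.
#' @return An object of class `standard_set`.
#' @export
standard_set <- function(white_region, black_region,
                         white_reflectance = 0.931,
                         black_reflectance = 0.0449) {
  if (!(black_reflectance >= 0 && black_reflectance < white_reflectance &&
        white_reflectance <= 1))
    stop("need 0 <= black_reflectance < white_reflectance <= 1")
  if (!any(white_region) || !any(black_region))
    stop("standard regions must be non-empty")
  if (any(white_region & black_region))
    stop("standard regions must be disjoint")
  structure(list(white_reflectance = white_reflectance,
                 black_reflectance = black_reflectance,
                 white_region = white_region, black_region = black_region),
            class = "standard_set")
}

# Internal: per-channel mean over a logical mask for an [r, c, ch] array.
.region_channel_means <- function(img, mask, exclude = NULL) {
  nc <- dim(img)[3]
  vapply(seq_len(nc), function(k) {
    v <- img[, , k][mask]
    if (!is.null(exclude)) v <- v[!exclude[, , k][mask]]
    if (!length(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
}

#' Equalize a linear image to the in-frame standards
#'
#' Per channel, the affine map taking the mean linear values of the black
#' and white standard regions to the standards' known reflectances is
#' applied to every pixel, yielding reflectance-equivalent planes
#' (values may exceed 1 for glare or fluorescence). The affine two-point
#' form (dark offset plus gain) uses both standards; it makes the result
#' invariant to global exposure scaling.
#'
#' @param linear linear image, array `[rows, cols, channels]`, as from
#'   [linearize()] (its `saturated` attribute, if present, is honoured).
#' @param standards a [standard_set()].
#' @param provenance optional list (camera id, light condition, ...)
#'   stored on the result.
#' @return A `calibrated_image`: array `[rows, cols, channels]` of
#'   reflectance-equivalent values with attributes `provenance` and
#'   `saturated`.
#' @export
equalize_to_standards <- function(linear, standards, provenance = list()) {
  stopifnot(inherits(standards, "standard_set"))
  d <- dim(linear)
  if (length(d) != 3) stop("linear image must be [rows, cols, channels]")
  for (rg in c("white_region", "black_region")) {
    m <- standards[[rg]]
    if (!all(dim(m) == d[1:2]))
      stop(rg, " does not match the image dimensions")
  }
  sat <- attr(linear, "saturated")
  if (!is.null(sat)) {
    for (rg in c("white_region", "black_region")) {
      m <- standards[[rg]]
      frac <- mean(sat[array(m, dim = d)])
      if (is.finite(frac) && frac > 0.5)
        stop("more than 50% of the ", rg, " is saturated")
    }
  }
  mw <- .region_channel_means(linear, standards$white_region)
  mb <- .region_channel_means(linear, standards$black_region)
  if (any(mw <= mb))
    stop("degenerate standards: white region mean must exceed black per channel")
  out <- array(0, d)
  gain <- (standards$white_reflectance - standards$black_reflectance) / (mw - mb)
  for (k in seq_len(d[3])) {
    out[, , k] <- standards$black_reflectance + (linear[, , k] - mb[k]) * gain[k]
  }
  dimnames(out) <- dimnames(linear)
  structure(out, class = "calibrated_image",
            provenance = provenance, saturated = sat)
}

#' Measure a region of a calibrated image
#'
#' Per-channel mean and s.d. over the unmasked, unsaturated pixels.
#'
#' @param calibrated a `calibrated_image` (or any `[r, c, ch]` array).
#' @param mask logical matrix, TRUE inside the region.
#' @return Data frame with one row per channel: `channel`, `mean`, `sd`,
#'   `n_pixels`.
#' @export
measure_region <- function(calibrated, mask) {
  d <- dim(calibrated)
  if (!any(mask)) stop("region mask is empty")
  if (!all(dim(mask) == d[1:2])) stop("mask does not match image dimensions")
  sat <- attr(calibrated, "saturated")
  ch_names <- dimnames(calibrated)[[3]]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(d[3]))
  rows <- lapply(seq_len(d[3]), function(k) {
    v <- calibrated[, , k][mask]
    if (!is.null(sat)) v <- v[!sat[, , k][mask]]
    if (!length(v)) stop("region is empty after excluding saturated pixels")
    data.frame(channel = ch_names[k], mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_pixels = length(v))
  })
  do.call(rbind, rows)
}
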
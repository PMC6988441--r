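# Camera-to-cone-catch mapping.
#
# Calibrated images hold camera-weighted reflectance per channel; horse
# vision needs receptor-weighted (SW, LW) quantum catches. The mapping is
# a per-receptor polynomial regression of direct spectral catches on the
# camera channel values, trained on a library of smooth random
# reflectance spectra rendered under one illuminant class.

#' Generate a library of smooth random reflectance spectra
#'
#' Each spectrum is a constant plus one dominant wide Gaussian bump and
#' up to three secondary bumps (random centre, width 60--130 nm, signed
#' amplitude), passed through a logistic squash so values lie strictly
#' inside (0, 1) with no clipping plateaus. Draws whose lag-10-nm
#' autocorrelation falls below 0.95 (rare near-cancelling bump
#' combinations) are redrawn, so every sample honours the documented
#' smoothness of the library. Deterministic given the seed. Stands in
#' for a measured natural-spectra library as mapping training material.
#'
#' @param n number of spectra (>= 50).
#' @param seed integer seed.
#' @param grid wavelength grid.
#' @return List of `spectral_curve`s.
#' @export
generate_training_spectra <- function(n, seed, grid = default_grid()) {
  if (n < 50) stop("n must be >= 50")
  set.seed(seed)
  lag <- 10
  draw <- function() {
    raw <- rep(stats::runif(1, 0, 0.8), length(grid))
    raw <- raw + sign(stats::runif(1, -1, 1)) * stats::runif(1, 0.25, 0.7) *
      .gauss(grid, stats::runif(1, 430, 670), stats::runif(1, 70, 130))
    for (j in seq_len(sample(0:3, 1))) {
      raw <- raw + stats::runif(1, -0.4, 0.5) *
        .gauss(grid, stats::runif(1, 380, 720), stats::runif(1, 60, 130))
    }
    1 / (1 + exp(-(raw - 0.5) * 3.5))
  }
  lapply(seq_len(n), function(i) {
    repeat {
      v <- draw()
      m <- length(v) - lag
      ac <- suppressWarnings(stats::cor(v[seq_len(m)], v[lag + seq_len(m)]))
      if (is.na(ac) || ac > 0.95) break
    }
    spectral_curve(grid, v, name = sprintf("train_%03d", i))
  })
}

# Internal: polynomial design row(s) for camera values.
# x: matrix [n, n_channels]. degree 1 = intercept + linear; degree 2 adds
# squares and pairwise interactions.
.poly_design <- function(x, degree) {
  x <- as.matrix(x)
  nc <- ncol(x)
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("c", seq_len(nc))
  for (k in seq_len(nc)) cols[[nms[k]]] <- x[, k]
  if (degree >= 2) {
    for (k in seq_len(nc)) cols[[paste0(nms[k], "^2")]] <- x[, k]^2
    if (nc >= 2) {
      for (k in seq_len(nc - 1)) for (l in (k + 1):nc) {
        cols[[paste0(nms[k], ":", nms[l])]] <- x[, k] * x[, l]
      }
    }
  }
  do.call(cbind, cols)
}

# Internal: camera-weighted adapted reflectance values for one spectrum.
.camera_values <- function(reflectance, illuminant, camera,
                           grid = default_grid()) {
  R <- .on_grid(reflectance, grid)
  I <- .on_grid(illuminant, grid)
  vapply(camera$channel_sensitivities, function(cs) {
    C <- .on_grid(cs, grid)
    sum(R * I * C) / sum(I * C)
  }, numeric(1))
}

#' Fit the camera-to-cone-catch mapping
#'
#' Per-receptor least-squares regression of direct spectral (adapted)
#' cone catches on polynomial terms of the camera channel values, both
#' computed for the training spectra under one illuminant. A random 20 %
#' of the spectra is held out to report out-of-sample R-squared.
#'
#' @param spectra training set, e.g. [generate_training_spectra()].
#' @param camera a [camera_model()].
#' @param system a [visual_system()].
#' @param illuminant the illuminant class the mapping is trained for.
#' @param degree polynomial degree, 1 or 2 (default 2: linear + squares +
#'   pairwise interactions).
#' @param seed seed for the held-out split.
#' @param grid wavelength grid.
#' @return An object of class `cone_mapping`: coefficient matrix
#'   (terms x receptors), term names, illuminant label, and per-receptor
#'   diagnostics (training and held-out R-squared, n).
#' @export
fit_mapping <- function(spectra, camera, system, illuminant, degree = 2,
                        seed = 1, grid = default_grid()) {
  stopifnot(inherits(camera, "camera_model"), inherits(system, "visual_system"))
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  X <- t(vapply(spectra, .camera_values, numeric(length(camera$channel_sensitivities)),
                illuminant = illuminant, camera = camera, grid = grid))
  colnames(X) <- names(camera$channel_sensitivities)
  D <- .poly_design(X, degree)
  if (nrow(D) < 10 * ncol(D))
    stop("need at least 10x more spectra than coefficients; ",
         "supply more (or more varied) training spectra")
  Y <- t(vapply(spectra, function(sp)
    unclass(cone_catch(sp, illuminant, system, adapt = TRUE, grid = grid)),
    numeric(length(system$receptors))))
  set.seed(seed)
  n <- nrow(D)
  hold <- sort(sample(n, max(1, round(0.2 * n))))
  qrD <- qr(D[-hold, , drop = FALSE])
  if (qrD$rank < ncol(D))
    stop("rank-deficient design: supply more varied training spectra")
  coef <- qr.coef(qrD, Y[-hold, , drop = FALSE])
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  fit_tr <- D[-hold, , drop = FALSE] %*% coef
  fit_ho <- D[hold, , drop = FALSE] %*% coef
  diag_df <- data.frame(
    receptor = colnames(Y),
    r2_train = vapply(seq_len(ncol(Y)), function(j) r2(Y[-hold, j], fit_tr[, j]), 1),
    r2_holdout = vapply(seq_len(ncol(Y)), function(j) r2(Y[hold, j], fit_ho[, j]), 1),
    n_train = n - length(hold), n_holdout = length(hold))
  structure(list(coefficients = coef, terms = colnames(D), degree = degree,
                 channels = colnames(X),
                 illuminant = illuminant$name, diagnostics = diag_df),
            class = "cone_mapping")
}

#' @export
print.cone_mapping <- function(x, ...) {
  cat(sprintf("<cone_mapping: degree %d, %d terms, illuminant %s>\n",
              x$degree, length(x$terms),
              if (is.null(x$illuminant)) "?" else x$illuminant))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Apply a cone mapping to a calibrated image
#'
#' Evaluates the fitted polynomial per pixel, yielding one plane per
#' receptor. Negative predictions are floored at a small positive epsilon
#' (catches are log-transformed downstream); the floored count is
#' recorded in the `n_floored` attribute. A mapping whose training
#' illuminant differs from the image's provenance raises a warning (or an
#' error with `mismatch = "error"`).
#'
#' @param calibrated a `calibrated_image` from [equalize_to_standards()].
#' @param mapping a `cone_mapping`.
#' @param floor_epsilon positive floor for predicted catches.
#' @param mismatch "warn" (default) or "error" on illuminant-label
#'   mismatch.
#' @return Array `[rows, cols, receptors]` of predicted cone catches,
#'   class `cone_image`.
#' @export
apply_mapping <- function(calibrated, mapping, floor_epsilon = 1e-6,
                          mismatch = c("warn", "error")) {
  mismatch <- match.arg(mismatch)
  d <- dim(calibrated)
  if (length(d) != 3 || d[3] != length(mapping$channels))
    stop("image channel count does not match the mapping")
  prov <- attr(calibrated, "provenance")
  if (!is.null(prov$light_condition) && !is.null(mapping$illuminant) &&
      prov$light_condition != mapping$illuminant) {
    msg <- sprintf("image light condition '%s' differs from mapping illuminant '%s'",
                   prov$light_condition, mapping$illuminant)
    if (mismatch == "error") stop(msg) else warning(msg)
  }
  X <- matrix(unclass(calibrated), nrow = prod(d[1:2]), ncol = d[3])
  colnames(X) <- mapping$channels
  pred <- .poly_design(X, mapping$degree) %*% mapping$coefficients
  n_floored <- sum(pred < floor_epsilon)
  pred <- pmax(pred, floor_epsilon)
  out <- array(pred, dim = c(d[1], d[2], ncol(pred)),
               dimnames = list(NULL, NULL, colnames(mapping$coefficients)))
  structure(out, class = "cone_image", provenance = prov,
            n_floored = n_floored)
}

#' Serialize a cone mapping to JSON
#' @param mapping a `cone_mapping`.
#' @param path output file.
#' @export
write_mapping_json <- function(mapping, path) {
  obj <- list(degree = mapping$degree, terms = mapping$terms,
              channels = mapping$channels, illuminant = mapping$illuminant,
              receptors = colnames(mapping$coefficients),
              coefficients = as.numeric(mapping$coefficients),
              diagnostics = mapping$diagnostics)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cone mapping from JSON
#' @param path file written by [write_mapping_json()].
#' @return A `cone_mapping`.
#' @export
read_mapping_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- matrix(obj$coefficients, ncol = length(obj$receptors),
                 dimnames = list(obj$terms, obj$receptors))
  structure(list(coefficients = coef, terms = obj$terms, degree = obj$degree,
                 channels = obj$channels, illuminant = obj$illuminant,
                 diagnostics = as.data.frame(obj$diagnostics)),
            class = "cone_mapping")
}
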
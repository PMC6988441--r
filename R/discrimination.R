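#' Per-receptor noise of the receptor-noise-limited model
#'
#' The Weber fraction omega anchors the noise of the most abundant
#' receptor; noise scales with the inverse square root of relative cone
#' abundance, `e_i = omega * sqrt(eta_max / eta_i)`. For the horse
#' defaults (omega 0.05, LW:SW abundance 40:5) this gives e_LW = 0.05 and
#' e_SW = 0.05 * sqrt(8).
#'
#' @param system a [visual_system()].
#' @return Named numeric vector of noise values `e_i`.
#' @export
receptor_noise <- function(system) {
  stopifnot(inherits(system, "visual_system"))
  eta <- vapply(system$receptors, `[[`, numeric(1), "abundance")
  system$weber_fraction * sqrt(max(eta) / eta)
}

# Internal: validate a pair of catch vectors against the system.
.check_catches <- function(a, b, system) {
  nm <- names(system$receptors)
  a <- unclass(a)[nm]; b <- unclass(b)[nm]
  for (x in list(a = a, b = b)) {
    bad <- nm[!is.finite(x) | x <= 0]
    if (length(bad))
      stop("non-positive or missing cone catch for receptor ",
           paste(bad, collapse = ", "))
  }
  list(a = a, b = b)
}

#' Chromatic contrast (colour JND)
#'
#' Log-linear receptor-noise-limited discriminability between two cone
#' catch vectors. With `Df_i = ln(Q_i^a) - ln(Q_i^b)`, the dichromat
#' statistic is `|Df_LW - Df_SW| / sqrt(e_LW^2 + e_SW^2)`; for n > 2
#' receptors the standard quadratic form is used:
#' `DS^2 = sum_{i<j} prod_{k != i,j} e_k^2 (Df_i - Df_j)^2 /
#'   sum_i prod_{k != i} e_k^2`.
#' The statistic is symmetric and invariant to a common scaling of both
#' stimuli (intensity cancels in the log differences).
#'
#' @param a,b cone catch vectors (named by receptor, all > 0).
#' @param system a [visual_system()].
#' @return Non-negative colour JND.
#' @export
colour_jnd <- function(a, b, system) {
  q <- .check_catches(a, b, system)
  df <- log(q$a) - log(q$b)
  e <- receptor_noise(system)
  n <- length(e)
  if (n < 2) stop("colour JND requires at least two receptors")
  e2 <- e^2
  num <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- num + prod(e2[-c(i, j)]) * (df[i] - df[j])^2
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e2[-i]), numeric(1)))
  unname(sqrt(num / den))
}

#' Achromatic contrast (luminance JND)
#'
#' `DL = |ln(Q_lum^a / Q_lum^b)| / omega_lum`, where the achromatic
#' channel is the system's luminance receptor (LW by default; if several
#' receptors are named their catches are summed before taking the log).
#'
#' @inheritParams colour_jnd
#' @return Non-negative luminance JND.
#' @export
luminance_jnd <- function(a, b, system) {
  q <- .check_catches(a, b, system)
  lum <- system$luminance_receptor
  la <- sum(q$a[lum]); lb <- sum(q$b[lum])
  unname(abs(log(la / lb)) / system$luminance_weber)
}

#' Contrast band of a JND value
#'
#' Values under 1 equate to low contrast, 1--3 to poor contrast, and
#' above 3 to increasingly good contrast. The boundaries 1 and 3 fall in
#' the "poor" band.
#'
#' @param jnd non-negative JND value (vectorized).
#' @return Factor with levels `low`, `poor`, `good`.
#' @export
classify_contrast <- function(jnd) {
  if (any(!is.finite(jnd)) || any(jnd < 0))
    stop("jnd must be finite and >= 0")
  band <- cut(jnd, breaks = c(-Inf, 1, 3, Inf),
              labels = c("low", "poor", "good"), right = FALSE)
  # boundary handling: exactly 3 belongs to "poor" (1 already does)
  band[jnd == 3] <- "poor"
  band
}

#' Colour and luminance JNDs for one stimulus pair
#'
#' Convenience wrapper returning both discrimination statistics and their
#' contrast bands.
#'
#' @inheritParams colour_jnd
#' @return A list of class `jnd_result`: `colour_jnd`, `luminance_jnd`,
#'   `band_colour`, `band_luminance`, and the input catches.
#' @export
jnd_result <- function(a, b, system) {
  cj <- colour_jnd(a, b, system)
  lj <- luminance_jnd(a, b, system)
  structure(list(colour_jnd = cj, luminance_jnd = lj,
                 band_colour = as.character(classify_contrast(cj)),
                 band_luminance = as.character(classify_contrast(lj)),
                 inputs = list(a = a, b = b)),
            class = "jnd_result")
}

#' @export
print.jnd_result <- function(x, ...) {
  cat(sprintf("colour JND %.3f (%s), luminance JND %.3f (%s)\n",
              x$colour_jnd, x$band_colour, x$luminance_jnd, x$band_luminance))
  invisible(x)
}
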
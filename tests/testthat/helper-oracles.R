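# Independent oracles, deliberately written as naive loops so they share
# no code path with the package internals.

# Brute-force rectangle-rule cone catch (adapted): loops over wavelengths.
oracle_catch <- function(R, I, S, adapt = TRUE) {
  num <- 0; den <- 0
  for (i in seq_along(R)) {
    num <- num + R[i] * I[i] * S[i]
    den <- den + I[i] * S[i]
  }
  if (adapt) num / den else num
}

# Brute-force receptor-noise-limited chromatic distance for n = 2:
# the quadratic form written out longhand.
oracle_rnl_dichromat <- function(qa, qb, e) {
  df1 <- log(qa[1]) - log(qb[1])
  df2 <- log(qa[2]) - log(qb[2])
  unname(sqrt((df1 - df2)^2 / (e[1]^2 + e[2]^2)))
}

# Trichromat closed form, for checking the general quadratic form.
oracle_rnl_trichromat <- function(qa, qb, e) {
  df <- log(qa) - log(qb)
  num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
    e[3]^2 * (df[1] - df[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  unname(sqrt(num / den))
}

# Band-integral ratio of an illuminant: short (<=500 nm) over long
# (>= 600 nm) power.
oracle_blue_red_ratio <- function(curve) {
  sum(curve$value[curve$wl <= 500]) / sum(curve$value[curve$wl >= 600])
}

# Flat spectral curve helper.
flat_curve <- function(v, grid = default_grid(), name = NULL) {
  spectral_curve(grid, rep(v, length(grid)), name = name)
}

# Per-channel region means of a calibrated or cone image.
region_means <- function(img, mask) measure_region(img, mask)$mean
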
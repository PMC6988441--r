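make_uniform_image <- function(vals, nrow = 20, ncol = 30) {
  # vals: per-channel linear values
  arr <- array(0, c(nrow, ncol, length(vals)))
  for (k in seq_along(vals)) arr[, , k] <- vals[k]
  arr
}

test_that("linearize inverts the camera response", {
  cam <- default_camera(gamma = 2.2)
  x <- array(seq(0.01, 0.95, length.out = 60), c(4, 5, 3))
  counts <- camera_response(x, cam)
  lin <- linearize(counts, cam)
  expect_lt(max(abs(lin - x) / x), 1e-3)  # quantization-limited at 16 bit
  cam1 <- default_camera(gamma = 1)
  counts1 <- camera_response(x, cam1)
  expect_equal(as.numeric(linearize(counts1, cam1)),
               as.numeric(counts1 / cam1$max_count), tolerance = 1e-12)
  expect_error(linearize(counts + 2^16, cam), "bit depth")
})

test_that("noisy ramp is recovered with unit slope after linearization", {
  cam <- default_camera(gamma = 2.2, noise_sd = 150)
  truth <- array(rep(seq(0.05, 0.9, length.out = 500), each = 20), c(20, 500, 1))
  counts <- camera_response(truth, cam, seed = 5)
  lin <- linearize(counts, cam)
  slope <- coef(lm(as.numeric(lin) ~ as.numeric(truth)))[2]
  expect_lt(abs(slope - 1), 0.01)
})

test_that("saturated pixels are flagged", {
  cam <- default_camera()
  counts <- camera_response(array(c(0.2, 1, 1, 0.4), c(2, 2, 1)), cam)
  lin <- linearize(counts, cam)
  expect_equal(sum(attr(lin, "saturated")), 2)
  expect_equal(attr(lin, "saturated_fraction"), 0.5)
})

test_that("equalization pins the standard regions to their reflectances", {
  cam <- default_camera(gamma = 2.2)
  img <- make_uniform_image(rep(0.5 * 0.9, 3), 40, 40)
  wmask <- matrix(FALSE, 40, 40); wmask[1:10, 1:10] <- TRUE
  bmask <- matrix(FALSE, 40, 40); bmask[1:10, 21:30] <- TRUE
  # paint the standards: linear value proportional to reflectance
  for (k in 1:3) {
    pl <- img[, , k]
    pl[wmask] <- 0.931 * 0.9; pl[bmask] <- 0.0449 * 0.9
    img[, , k] <- pl
  }
  lin <- linearize(camera_response(img, cam), cam)
  std <- standard_set(wmask, bmask)
  cal <- equalize_to_standards(lin, std)
  expect_equal(unname(region_means(cal, wmask)), rep(0.931, 3), tolerance = 1e-9)
  expect_equal(unname(region_means(cal, bmask)), rep(0.0449, 3), tolerance = 1e-9)
  # the 0.5-reflectance body pixels are recovered (quantization-limited)
  body <- !(wmask | bmask)
  expect_equal(unname(region_means(cal, body)), rep(0.5, 3), tolerance = 1e-3)
})

test_that("equalization is invariant to global exposure scaling", {
  wmask <- matrix(FALSE, 10, 20); wmask[1:5, 1:5] <- TRUE
  bmask <- matrix(FALSE, 10, 20); bmask[6:10, 1:5] <- TRUE
  lin <- array(runif(10 * 20 * 3, 0.1, 0.6), c(10, 20, 3))
  for (k in 1:3) {
    pl <- lin[, , k]; pl[wmask] <- 0.7; pl[bmask] <- 0.05; lin[, , k] <- pl
  }
  std <- standard_set(wmask, bmask)
  c1 <- equalize_to_standards(lin, std)
  c2 <- equalize_to_standards(lin * 3.7, std)
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-12)
})

test_that("degenerate or mismatched standards are refused", {
  wmask <- matrix(FALSE, 5, 5); wmask[1, 1] <- TRUE
  bmask <- matrix(FALSE, 5, 5); bmask[2, 2] <- TRUE
  lin <- array(0.5, c(5, 5, 3))
  expect_error(equalize_to_standards(lin, standard_set(wmask, bmask)),
               "degenerate")
  expect_error(standard_set(wmask, wmask), "disjoint")
  expect_error(standard_set(matrix(FALSE, 5, 5), bmask), "non-empty")
  big <- matrix(TRUE, 6, 6)
  expect_error(equalize_to_standards(lin, standard_set(big, big * FALSE)),
               "non-empty|dimensions")
})

test_that("measure_region returns means, sds and counts", {
  img <- array(0.2, c(10, 10, 2))
  img[, 6:10, 1] <- 0.6
  mask_uni <- matrix(FALSE, 10, 10); mask_uni[, 1:5] <- TRUE
  m <- measure_region(img, mask_uni)
  expect_equal(m$mean, c(0.2, 0.2))
  expect_equal(m$sd, c(0, 0))
  expect_equal(m$n_pixels, c(50, 50))
  mask_half <- matrix(TRUE, 10, 10)
  expect_equal(measure_region(img, mask_half)$mean[1], 0.4)
  expect_error(measure_region(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("measured sd reflects injected noise", {
  set.seed(9)
  img <- array(0.5 + rnorm(40 * 40, 0, 0.02), c(40, 40, 1))
  m <- measure_region(img, matrix(TRUE, 40, 40))
  expect_lt(abs(m$sd - 0.02) / 0.02, 0.2)
})

test_that("render-calibrate round trip recovers camera-weighted reflectance in all classes", {
  # full round trip, noise-free: every unshaded region's calibrated value
  # equals the camera-weighted adapted reflectance of its material
  cam <- default_camera()
  for (cond in light_conditions()$label) {
    sc <- render_scene(scene_spec(cond, noise_sd = 0, seed = 2, camera = cam))
    lin <- linearize(sc$counts, cam)
    std <- standard_set(sc$masks$standard_white, sc$masks$standard_black)
    cal <- equalize_to_standards(lin, std)
    I <- make_illuminant(cond)
    shade <- light_conditions()$fence_shade[light_conditions()$label == cond]
    for (rg in c("foreground", "background", "takeoff_board")) {
      mat <- if (rg == "foreground") "turf" else
        if (rg == "background") "sky" else "orange_paint"
      f <- if (rg == "takeoff_board") shade else 1
      want <- f * equisight:::.camera_values(material_spectrum(mat), I, cam)
      got <- region_means(cal, sc$masks[[rg]])
      expect_lt(max(abs(got - want) / want), 0.01)
    }
  }
})
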
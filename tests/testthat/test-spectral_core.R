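test_that("spectral_curve enforces its invariants", {
  expect_error(spectral_curve(c(400, 400, 410), c(1, 1, 1)), "increasing")
  expect_error(spectral_curve(400:410, rep(-1, 11)), ">= 0")
  expect_error(spectral_curve(400:410, rep(1, 5)), "equal length")
  cur <- spectral_curve(400:700, rep(0.5, 301))
  expect_s3_class(cur, "spectral_curve")
})

test_that("resampling is lossless on the target grid and guards extrapolation", {
  cur <- spectral_curve(400:700, seq(0, 1, length.out = 301))
  expect_identical(resample_spectrum(cur), cur)
  sub <- spectral_curve(seq(420, 680, by = 20), rep(0.3, 14))
  expect_error(resample_spectrum(sub, 400:700), "5 nm")
  near <- spectral_curve(seq(398, 702, by = 4), rep(0.3, 77))
  expect_equal(resample_spectrum(near, 400:700)$value, rep(0.3, 301))
})

test_that("spectra survive a CSV round trip with interpolation", {
  cur <- spectral_curve(400:700, 0.2 + 0.5 * exp(-((400:700) - 550)^2 / 5000))
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(cur, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$value, cur$value, tolerance = 1e-12)
  # coarse tabulation is interpolated onto the grid
  coarse <- spectral_curve(seq(400, 700, 10), rep(0.4, 31))
  write_spectrum_csv(coarse, path)
  expect_equal(read_spectrum_csv(path)$value, rep(0.4, 301))
})

test_that("pigment templates peak at the requested wavelength, max 1", {
  for (lmax in c(428, 539)) {
    tpl <- pigment_template(lmax)
    expect_equal(tpl$wl[which.max(tpl$value)], lmax)
    expect_equal(max(tpl$value), 1.0)
  }
  expect_error(pigment_template(300), "\\[380, 700\\]")
})

test_that("pigment template peak location error is within one grid step", {
  set.seed(42)
  for (lmax in runif(50, 420, 650)) {
    tpl <- pigment_template(lmax)
    expect_lte(abs(tpl$wl[which.max(tpl$value)] - lmax), 1)
  }
})

test_that("cone catch matches the brute-force summation oracle", {
  sys <- horse_visual_system()
  grid <- default_grid()
  turf <- material_spectrum("turf")
  flat <- flat_curve(1)
  q <- cone_catch(turf, flat, sys, adapt = TRUE)
  for (rec in c("SW", "LW")) {
    S <- sys$receptors[[rec]]$sensitivity$value
    expect_equal(unname(unclass(q)[rec]),
                 oracle_catch(turf$value, flat$value, S),
                 tolerance = 1e-9)
  }
  # unadapted too
  qu <- cone_catch(turf, flat, sys, adapt = FALSE)
  S <- sys$receptors$LW$sensitivity$value
  expect_equal(unname(unclass(qu)["LW"]),
               oracle_catch(turf$value, flat$value, S, adapt = FALSE),
               tolerance = 1e-6)
})

test_that("von Kries adaptation gives identity for perfect and flat reflectors", {
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Evening")
  q1 <- cone_catch(flat_curve(1), ill, sys, adapt = TRUE)
  expect_equal(as.numeric(q1), c(1, 1), tolerance = 1e-12)
  q05 <- cone_catch(flat_curve(0.5), ill, sys, adapt = TRUE)
  expect_equal(as.numeric(q05), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("catch is linear in reflectance and invariant to illuminant scaling", {
  sys <- horse_visual_system()
  ill <- make_illuminant("Overcast_Daytime")
  turf <- material_spectrum("turf")
  a <- 0.37
  q1 <- as.numeric(cone_catch(turf, ill, sys, adapt = FALSE))
  qa <- as.numeric(cone_catch(spectral_curve(turf$wl, a * turf$value), ill, sys,
                              adapt = FALSE))
  expect_equal(qa, a * q1, tolerance = 1e-12)
  for (k in c(0.2, 3, 11)) {
    illk <- spectral_curve(ill$wl, k * ill$value)
    expect_equal(as.numeric(cone_catch(turf, illk, sys, adapt = TRUE)),
                 as.numeric(cone_catch(turf, ill, sys, adapt = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("illuminant family has the documented spectral skews", {
  sunny <- oracle_blue_red_ratio(make_illuminant("Sunny_Daytime"))
  expect_lt(abs(sunny - 1), 0.2)
  expect_gt(oracle_blue_red_ratio(make_illuminant("Shade_Daytime")), sunny)
  expect_lt(oracle_blue_red_ratio(make_illuminant("Sunny_Evening")), sunny)
  expect_error(make_illuminant("Dawn"), "Sunny_Daytime")
})

test_that("receptor and visual system validate their parameters", {
  expect_error(receptor("SW", 500, 5,
                        sensitivity = pigment_template(428)), "peaks at")
  expect_error(visual_system(list(receptor("A", 500, 1)), weber_fraction = 2),
               "weber_fraction")
  sys <- horse_visual_system()
  expect_named(sys$receptors, c("SW", "LW"))
  expect_equal(sys$receptors$LW$abundance, 40)
  expect_equal(sys$receptors$SW$abundance, 5)
})
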
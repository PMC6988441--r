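test_that("training spectra are deterministic, bounded and smooth", {
  a <- generate_training_spectra(200, seed = 1)
  b <- generate_training_spectra(200, seed = 1)
  expect_identical(lapply(a, `[[`, "value"), lapply(b, `[[`, "value"))
  vals <- vapply(a, function(s) range(s$value), numeric(2))
  expect_true(all(vals >= 0 & vals <= 1))
  # spectral autocorrelation at a 10 nm lag
  ac10 <- vapply(a, function(s) {
    v <- s$value
    r <- suppressWarnings(stats::cor(v[1:(length(v) - 10)], v[11:length(v)]))
    if (is.na(r)) 1 else r  # flat (clipped) windows are trivially smooth
  }, numeric(1))
  expect_true(all(ac10 > 0.9))
  expect_error(generate_training_spectra(10, seed = 1), ">= 50")
})

test_that("fitted mapping is near-exact out of sample", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Daytime")
  map <- fit_mapping(generate_training_spectra(500, seed = 7), cam, sys, ill,
                     degree = 2)
  expect_true(all(map$diagnostics$r2_holdout >= 0.99))
  expect_true(all(map$diagnostics$r2_train >= 0.99))
})

test_that("degree-1 training fit never beats degree 2 (nested models)", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Overcast_Daytime")
  sp <- generate_training_spectra(300, seed = 3)
  m1 <- fit_mapping(sp, cam, sys, ill, degree = 1, seed = 5)
  m2 <- fit_mapping(sp, cam, sys, ill, degree = 2, seed = 5)
  expect_true(all(m2$diagnostics$r2_train >= m1$diagnostics$r2_train - 1e-9))
})

test_that("a camera with receptor-identical channels maps exactly", {
  sys <- horse_visual_system()
  cam <- camera_model(list(SWc = sys$receptors$SW$sensitivity,
                           LWc = sys$receptors$LW$sensitivity),
                      gamma = 1)
  ill <- make_illuminant("Sunny_Daytime")
  map <- fit_mapping(generate_training_spectra(200, seed = 2), cam, sys, ill)
  expect_true(all(abs(map$diagnostics$r2_train - 1) < 1e-9))
  expect_true(all(abs(map$diagnostics$r2_holdout - 1) < 1e-9))
})

test_that("too few or degenerate training spectra are refused", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Daytime")
  expect_error(fit_mapping(generate_training_spectra(60, seed = 1)[1:60],
                           cam, sys, ill), "10x")
  flat <- replicate(120, flat_curve(0.5), simplify = FALSE)
  expect_error(fit_mapping(flat, cam, sys, ill), "rank-deficient")
})

test_that("apply_mapping predicts the white standard's direct catch", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Daytime")
  map <- fit_mapping(generate_training_spectra(500, seed = 7), cam, sys, ill)
  cv <- equisight:::.camera_values(material_spectrum("ptfe_white"), ill, cam)
  img <- array(rep(cv, each = 12), c(3, 4, 3),
               dimnames = list(NULL, NULL, names(cv)))
  cone <- apply_mapping(img, map)
  truth <- unclass(cone_catch(material_spectrum("ptfe_white"), ill, sys))
  expect_lt(max(abs(cone[1, 1, ] - truth) / truth), 0.01)
  # zero-variance input gives zero-variance output
  expect_equal(stats::sd(cone[, , "SW"]), 0)
  expect_equal(stats::sd(cone[, , "LW"]), 0)
})

test_that("negative predictions are floored and mismatches warned", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Daytime")
  map <- fit_mapping(generate_training_spectra(500, seed = 7), cam, sys, ill)
  img <- array(-0.5, c(2, 2, 3), dimnames = list(NULL, NULL, map$channels))
  cone <- apply_mapping(img, map)
  expect_true(all(cone >= 1e-6))
  expect_gt(attr(cone, "n_floored"), 0)
  cal <- structure(array(0.2, c(2, 2, 3)),
                   provenance = list(light_condition = "Shade_Daytime"))
  expect_warning(apply_mapping(cal, map), "differs")
  expect_error(apply_mapping(cal, map, mismatch = "error"), "differs")
})

test_that("mappings survive a JSON round trip", {
  cam <- default_camera()
  sys <- horse_visual_system()
  ill <- make_illuminant("Sunny_Evening")
  map <- fit_mapping(generate_training_spectra(120, seed = 4), cam, sys, ill)
  path <- tempfile(fileext = ".json")
  write_mapping_json(map, path)
  back <- read_mapping_json(path)
  expect_equal(back$coefficients, map$coefficients, tolerance = 1e-12)
  expect_equal(back$illuminant, map$illuminant)
  expect_equal(back$degree, map$degree)
})
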
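test_that("scale calibration is the spacing over the mean bar distance", {
  pts <- list(c(100, 500), c(100, 400), c(100, 300))
  expect_equal(calibrate_scale(pts, 250), 2.5)
  # any adjacent pair gives the same scale when spacing is even
  expect_equal(calibrate_scale(pts[1:2], 250), 2.5)
  expect_equal(calibrate_scale(pts[2:3], 250), 2.5)
  expect_error(calibrate_scale(list(c(1, 1), c(1, 1)), 250), "coincident")
  expect_error(calibrate_scale(pts, -1), "> 0")
  expect_warning(calibrate_scale(list(c(0, 0), c(100, 0), c(50, 60)), 100),
                 "deviate")
})

test_that("scale calibration stays within 2% under 1 px annotation noise", {
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    pts <- lapply(0:2, function(i) c(100, 500 - 100 * i) + rnorm(2, 0, 1))
    abs(calibrate_scale(pts, 250) - 2.5) / 2.5
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("limb distances are scaled Euclidean distances", {
  expect_equal(limb_distance(c(10, 10), c(10, 10), 2.5), 0)
  expect_equal(limb_distance(c(0, 0), c(3, 4), 10), 50)
  expect_error(limb_distance(NULL, c(1, 1), 1), "missing point")
})

test_that("takeoff angle measures the dorsum against the ground line", {
  croup <- c(100, 200); sacral <- c(100, 210)  # origin (100, 205)
  expect_equal(takeoff_angle(croup, sacral, c(200, 105)), 45)
  expect_equal(takeoff_angle(croup, sacral, c(250, 205)), 0)
  expect_equal(takeoff_angle(croup, sacral, c(100, 50)), 90)
  # custom ground line
  expect_equal(takeoff_angle(croup, sacral, c(200, 105),
                             ground_direction = c(1, -1)), 0,
               tolerance = 1e-5)
  expect_error(takeoff_angle(c(0, 0), c(0, 0), c(0, 0)), "coincides")
})

test_that("takeoff angle is invariant to translation and uniform scaling", {
  base <- list(croup = c(100, 200), sacral = c(100, 210), withers = c(260, 90))
  a0 <- takeoff_angle(base$croup, base$sacral, base$withers)
  for (i in 1:20) {
    set.seed(i)
    t <- c(runif(1, -500, 500), runif(1, -500, 500))
    s <- runif(1, 0.1, 8)
    expect_equal(takeoff_angle(s * (base$croup + t), s * (base$sacral + t),
                               s * (base$withers + t)), a0, tolerance = 1e-9)
  }
})

test_that("bascule angle is the interior angle at the withers", {
  expect_equal(bascule_angle(c(0, 100), c(50, 50), c(100, 0)), 180)
  expect_equal(bascule_angle(c(0, 0), c(0, 100), c(100, 100)), 90)
  expect_error(bascule_angle(c(1, 1), c(1, 1), c(2, 2)), "coincident")
})

test_that("wither height is the scaled vertical offset", {
  expect_equal(wither_height(c(300, 100), c(310, 220), 2.5), 300)
  expect_equal(wither_height(c(300, 220), c(310, 100), 2.5), 300)
})

test_that("a noise-free synthetic jump recovers all eleven parameters exactly", {
  sj <- synthetic_jump()
  got <- jump_parameters(sj$annotation)
  for (p in names(sj$truth)) {
    expect_equal(got[[p]], sj$truth[[p]], tolerance = 1e-9, label = p)
  }
})

test_that("parameter recovery holds across varied jump geometries", {
  set.seed(33)
  for (i in 1:10) {
    sj <- synthetic_jump(
      scale_mm_per_px = runif(1, 1.5, 4),
      takeoff_distances = runif(4, 1200, 3000),
      landing_distances = runif(4, 1200, 3000),
      takeoff_angle_deg = runif(1, 10, 45),
      bascule_angle_deg = runif(1, 120, 175),
      wither_height_mm = runif(1, 300, 900))
    got <- jump_parameters(sj$annotation)
    for (p in names(sj$truth))
      expect_equal(got[[p]], sj$truth[[p]], tolerance = 1e-9, label = p)
  }
})

test_that("distances scale with mm-per-pixel; degradation under noise is modest", {
  sj1 <- synthetic_jump(scale_mm_per_px = 2)
  sj2 <- synthetic_jump(scale_mm_per_px = 4)
  # same physical truth regardless of pixel scale
  expect_equal(jump_parameters(sj1$annotation)$total_jump_distance,
               jump_parameters(sj2$annotation)$total_jump_distance,
               tolerance = 1e-9)
  # 1 px noise: distances off by a few scaled pixels at most
  sj <- synthetic_jump(noise_px = 1, seed = 8)
  got <- jump_parameters(sj$annotation)
  dist_cols <- grep("distance", names(sj$truth), value = TRUE)
  err <- abs(unlist(got[dist_cols]) - unlist(sj$truth[dist_cols]))
  # point jitter plus the ~1% scale error acting on multi-metre distances
  expect_lt(max(err), 150)
})

test_that("annotations survive a JSON round trip and missing points are named", {
  sj <- synthetic_jump()
  path <- tempfile(fileext = ".json")
  write_jump_annotation(sj$annotation, path)
  back <- read_jump_annotation(path)
  expect_equal(jump_parameters(back), jump_parameters(sj$annotation),
               tolerance = 1e-12)
  broken <- sj$annotation
  broken$apex$ears <- NULL
  expect_error(jump_parameters(broken), "apex\\$ears")
})
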
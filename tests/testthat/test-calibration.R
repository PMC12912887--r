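test_that("each background gets its prescribed standard pair", {
  expect_equal(standards_for_background("white"), c(0.4173, 0.9824))
  for (bg in c("black", "beige", "brown", "green")) {
    expect_equal(standards_for_background(bg), c(0.0488, 0.4173))
  }
})

test_that("two-point linear calibration inverts a linear camera exactly", {
  cam <- camera_model(gain = 2, offset = 10)
  img <- render_synthetic_image(
    fish_reflectance = 0.20, background_reflectance = 0.059,
    standards = standards_for_background("black"), camera = cam
  )
  lin <- fit_channel_linearisation(img, model = "linear")
  cal <- apply_linearisation(img, lin)
  fish <- measure_roi(cal, "fish")
  expect_equal(fish$mean_reflectance, 0.20, tolerance = 1e-9)
  # inverse property on the standards themselves
  for (r in c(0.0488, 0.4173)) {
    expect_equal(predict(lin, cam$response(r), "grey"), r,
                 tolerance = 1e-9)
  }
  # calibrated reflectance is non-decreasing in pixel value
  px <- seq(0, 30, length.out = 50)
  expect_true(all(diff(predict(lin, px, "grey")) >= 0))
})

test_that("white-background calibration recovers the white paper at 85.5%", {
  img <- render_synthetic_image(
    fish_reflectance = 0.30, background_reflectance = 0.855,
    standards = standards_for_background("white"),
    camera = camera_model(gain = 0.9, offset = 0.02)
  )
  lin <- fit_channel_linearisation(img)
  bg_px <- measure_roi(img, "background")$mean_reflectance
  # background ROI pixel mean is contaminated by the embedded patches, so
  # measure a clean corner patch instead
  corner <- list(region = "corner", x0 = 0, y0 = 0, x1 = 20, y1 = 10)
  corner_px <- measure_roi(img, corner)$mean_reflectance
  expect_equal(predict(lin, corner_px, "grey"), 0.855, tolerance = 1e-6)
  expect_true(bg_px > 0)
})

test_that("a power-law fit linearises a gamma-2.2 camera", {
  cam <- camera_model(gamma = 2.2)
  img <- render_synthetic_image(
    fish_reflectance = 0.20, background_reflectance = 0.30,
    standards = c(0.0488, 0.4173, 0.9824), camera = cam
  )
  lin <- fit_channel_linearisation(img, model = "power")
  ramp <- seq(0.05, 0.95, length.out = 10)
  got <- predict(lin, cam$response(ramp), "grey")
  expect_lt(max(abs(got - ramp)), 0.005)
  # monotone response preserves ordering by reflectance
  expect_true(all(diff(got) > 0))
  two_std <- render_synthetic_image(0.2, 0.3, c(0.0488, 0.4173), cam)
  expect_error(fit_channel_linearisation(two_std, model = "power"), ">= 3")
})

test_that("degenerate and non-monotone standard responses are refused", {
  img <- render_synthetic_image(0.2, 0.3, c(0.0488, 0.4173))
  std_rows <- !is.na(img$regions$nominal_reflectance)
  flat <- img
  flat$image[] <- 0.5  # all patches identical
  expect_error(fit_channel_linearisation(flat), "degenerate")
  # invert the recorded nominals so pixel decreases with reflectance
  swapped <- img
  swapped$regions$nominal_reflectance[std_rows] <-
    rev(swapped$regions$nominal_reflectance[std_rows])
  expect_error(fit_channel_linearisation(swapped), "non-monotone")
  expect_error(render_synthetic_image(0.2, 0.3, c(0.4, 0.4)), "duplicate")
})

test_that("ROI means are exact on flat and patterned regions", {
  img <- render_synthetic_image(0.5, 0.25, c(0.0488, 0.4173))
  expect_equal(measure_roi(img, "fish")$mean_reflectance, 0.5)
  # two-value checkerboard with equal counts
  cb <- img
  chk <- matrix(c(0.2, 0.8), nrow = 10, ncol = 10)
  cb$image[1:10, 1:10, 1] <- chk
  box <- list(region = "chk", x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  out <- measure_roi(cb, box)
  expect_equal(out$mean_reflectance, 0.5)
  expect_equal(out$n_pixels, 100)
  expect_error(measure_roi(img, list(x0 = 0, y0 = 0, x1 = 0, y1 = 5)),
               "empty")
  expect_error(measure_roi(img, list(x0 = 0, y0 = 0, x1 = 10^4, y1 = 5)),
               "bounds")
})

test_that("noisy flat-patch means satisfy the CLT error bound", {
  set.seed(41)
  img <- render_synthetic_image(0.5, 0.25, c(0.0488, 0.4173),
                                noise_sd = 0.02, width = 200, height = 100)
  box <- list(region = "flat", x0 = 150, y0 = 0, x1 = 200, y1 = 60)
  # 3000 px of background at N(response(0.25), 0.02^2)
  m <- measure_roi(img, box)$mean_reflectance
  expect_lt(abs(m - 0.25), 4 * 0.02 / sqrt(3000))
})

test_that("midpoint grey target is the black/white average", {
  expect_equal(midpoint_grey_target(0.059, 0.855)$target_reflectance, 0.457)
  expect_equal(midpoint_grey_target(0.3, 0.3)$target_reflectance, 0.3)
  expect_error(midpoint_grey_target(0.9, 0.1), "black <= white")
})

test_that("printer-curve search matches exhaustive nearest-level search", {
  curve <- data.frame(level = 0:255, reflectance = (0:255) / 255)
  out <- midpoint_grey_target(0.059, 0.855, curve)
  # independent oracle: brute force over all 256 levels
  target <- (0.059 + 0.855) / 2
  err <- abs(curve$reflectance - target)
  expect_equal(out$rgb_level, curve$level[which.min(err)])
  expect_equal(out$rgb_level, round(255 * target))
  # ties go to the lower level: 0.45 and 0.55 are equidistant from 0.50
  tie_curve <- data.frame(level = 0:1, reflectance = c(0.45, 0.55))
  expect_equal(midpoint_grey_target(0.40, 0.60, tie_curve)$rgb_level, 0)
  bad <- data.frame(level = 0:2, reflectance = c(0.2, 0.5, 0.4))
  expect_error(midpoint_grey_target(0.3, 0.6, bad), "increasing")
})

test_that("PNG round trip preserves image and regions", {
  img <- render_synthetic_image(0.5, 0.25, c(0.0488, 0.4173))
  path <- tempfile(fileext = ".png")
  write_synthetic_image(img, path)
  back <- read_synthetic_image(path)
  expect_equal(back$channels, img$channels)
  br <- as.data.frame(back$regions)
  expect_equal(br$region, img$regions$region)
  for (col in c("x0", "y0", "x1", "y1", "nominal_reflectance")) {
    expect_equal(as.numeric(br[[col]]), as.numeric(img$regions[[col]]))
  }
  expect_lt(max(abs(back$image - img$image)), 0.5 / 255 + 1e-9)
  unlink(c(path, paste0(path, ".regions.json")))
})
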
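test_that("cropping recentres on the section", {
  sim <- simulateEllipseImage(ellipseSpec(100, 0.5, 30),
                              canvas = c(1600, 1200))
  cropped <- cropToRegion(sim$image, cropPx = 640L)
  expect_equal(dim(pixels(cropped)), c(640L, 640L))
  expect_equal(sum(pixels(cropped) < 0.5), sum(pixels(sim$image) < 0.5))

  # ellipse pushed toward a corner: crop still contains it, centred
  tm <- ellipseMask(ellipseSpec(80, 0.5, 45), c(700, 700), 4.25)
  px <- matrix(1, 1500, 2000)
  px[30 + seq_len(700), 1200 + seq_len(700)][tm] <- 0
  cr <- cropToRegion(CalibratedImage(px, 4.25, "um"), 640L)
  expect_equal(sum(pixels(cr) < 0.5), sum(tm))
  idx <- which(pixels(cr) < 0.5, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(idx) - (640 + 1) / 2)), 10)

  blank <- CalibratedImage(matrix(0.8, 900, 900), 4.25, "um")
  expect_error(cropToRegion(blank), class = "hairmorph_no_section")
})

test_that("Chan-Vese recovers the simulated section almost exactly", {
  for (sp in list(ellipseSpec(100, 0.8, 37), ellipseSpec(60, 0.2, 120))) {
    sim <- simulateEllipseImage(sp, canvas = testCanvasEllipse)
    sm <- segmentChanVese(sim$image)
    truthMask <- ellipseMask(sp, testCanvasEllipse, 4.25)
    jaccard <- sum(maskPixels(sm) & truthMask) /
      sum(maskPixels(sm) | truthMask)
    expect_gte(jaccard, 0.97)
  }

  flat <- CalibratedImage(matrix(0.4, 200, 200), 4.25, "um")
  expect_error(segmentChanVese(flat), class = "hairmorph_no_section")
})

test_that("only the largest region survives segmentation", {
  sim <- simulateEllipseImage(ellipseSpec(90, 0.4, 10),
                              canvas = testCanvasEllipse)
  px <- pixels(sim$image)
  px[30:36, 30:36] <- 0  # debris speck far from the section
  sm <- segmentChanVese(CalibratedImage(px, 4.25, "um"))
  expect_false(any(maskPixels(sm)[25:41, 25:41]))
  expect_equal(sum(maskPixels(sm)), sum(pixels(sim$image) < 0.5),
               tolerance = 0.01)
})

test_that("section measures match analytic circle and ellipse oracles", {
  # circle, diameter 100 um at 4.25 px/um
  sim <- simulateEllipseImage(ellipseSpec(100, 0),
                              canvas = testCanvasEllipse)
  m <- measureSection(segmentChanVese(sim$image), 4.25, "circle")
  expect_equal(m$area_um2, pi * 50^2, tolerance = 5e-3)
  expect_lte(m$eccentricity, 0.05)

  # semi-axes a = 60, b = 30 um: eccentricity sqrt(1 - 1/4)
  sp <- ellipseSpec(120, sqrt(1 - 0.25), 25)
  expect_equal(sp@minDiameterUm, 60, tolerance = 1e-12)
  sim2 <- simulateEllipseImage(sp, canvas = testCanvasEllipse)
  m2 <- measureSection(segmentChanVese(sim2$image), 4.25, "ellipse")
  expect_equal(m2$eccentricity, sqrt(0.75), tolerance = 0.01)
  expect_equal(m2$max_diameter_um, 120, tolerance = 0.02)
  expect_equal(m2$min_diameter_um, 60, tolerance = 0.02)

  # single-pixel mask: degenerate conventions
  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  ms <- measureSection(single, 4.25, "px")
  expect_equal(ms$area_um2, 1 / 4.25^2)
  expect_identical(ms$eccentricity, 0)
  expect_error(measureSection(matrix(FALSE, 5, 5), 4.25), "empty")
})

test_that("moment axes agree with the EBImage oracle", {
  sp <- ellipseSpec(110, 0.7, 63)
  mask <- ellipseMask(sp, testCanvasEllipse, 4.25)
  mine <- measureSection(mask, 1, "m")  # px units
  feats <- EBImage::computeFeatures.moment(EBImage::bwlabel(mask))
  expect_equal(mine$max_diameter_um, unname(feats[1L, "m.majoraxis"]),
               tolerance = 0.01)
  expect_equal(mine$eccentricity, unname(feats[1L, "m.eccentricity"]),
               tolerance = 0.01)
})

test_that("measures are rotation invariant", {
  res <- lapply(c(0, 37, 90), function(rot) {
    sim <- simulateEllipseImage(ellipseSpec(100, 0.6, rot),
                                canvas = testCanvasEllipse)
    measureSection(segmentChanVese(sim$image), 4.25, "rot")
  })
  areas <- vapply(res, `[[`, numeric(1), "area_um2")
  eccs <- vapply(res, `[[`, numeric(1), "eccentricity")
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
  expect_lt(diff(range(eccs)), 0.02)
  # pixel-count area consistent with the moments-equivalent ellipse area
  for (r in res)
    expect_equal(r$area_um2,
                 pi * r$max_diameter_um * r$min_diameter_um / 4,
                 tolerance = 0.02)
})

test_that("directory analysis skips corrupt files and reruns identically", {
  d <- withr::local_tempdir(); o <- withr::local_tempdir()
  generateEllipseDataset(3, d, seed = 14, canvas = testCanvasEllipse)
  writeLines("garbage", file.path(d, "corrupt.tiff"))
  expect_message(s1 <- analyzeSectionDir(d, 4.25, outputDir = o),
                 "corrupt")
  expect_identical(nrow(s1), 3L)
  expect_true(file.exists(file.path(o, "summary_section.csv")))
  s2 <- suppressMessages(analyzeSectionDir(d, 4.25))
  expect_identical(s1, s2)
  expect_true(all(s1$eccentricity >= 0 & s1$eccentricity < 1))
  expect_true(all(s1$min_diameter_um <= s1$max_diameter_um))
})
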
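test_that("arcPoints places points exactly on the circle", {
  # r = 1 mm, thetaStart = 0, 3 points: angles 0, pi/4, pi/2
  p <- arcPoints(arcSpec(radiusMm = 1, nPoints = 3))
  expect_equal(p[, "x"], c(1, sqrt(2) / 2, 0), tolerance = 1e-12)
  expect_equal(p[, "y"], c(0, sqrt(2) / 2, 1), tolerance = 1e-12)

  # r = 0.5 mm sweeps pi rad: first and last points are antipodal
  p <- arcPoints(arcSpec(radiusMm = 0.5, nPoints = 25))
  expect_equal(sqrt(sum((p[1L, ] - p[25L, ])^2)), 1, tolerance = 1e-12)

  # property: on-circle, chord bound, constant arc length r * sweep
  set.seed(7)
  for (k in 1:20) {
    r <- runif(1, 0.5, 10)
    sp <- arcSpec(radiusMm = r, thetaStart = runif(1, 0, pi - 1e-9))
    ctr <- runif(2, -5, 5)
    p <- arcPoints(sp, center = ctr)
    d <- sqrt((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2)
    expect_equal(d, rep(r, nrow(p)), tolerance = 1e-9)
    expect_lte(max(dist(p)), 2 * r + 1e-9)
    expect_equal(r * (pi / (2 * r)), pi / 2)
  }
})

test_that("arc and ellipse specs reject invalid parameters", {
  expect_error(arcSpec(radiusMm = -1), "positive")
  expect_error(arcSpec(radiusMm = 1, thetaStart = pi), "thetaStart")
  expect_error(arcSpec(), "exactly one")
  expect_error(ellipseSpec(100, eccentricity = 1), "eccentricity")
  expect_error(validObject(new("EllipseSpec", maxDiameterUm = 50,
                               minDiameterUm = 60, eccentricity = 0,
                               rotationDeg = 0)))
})

test_that("simulated arc images contain the requested disjoint fragments", {
  sim <- simulateArcImage(1, nFragments = 25, canvas = testCanvasArc,
                          seed = 5)
  px <- pixels(sim$image)
  expect_equal(dim(px), c(testCanvasArc[2L], testCanvasArc[1L]))
  lab <- EBImage::bwlabel(px < 0.5)
  expect_equal(max(lab), 25)
  expect_identical(nrow(sim$truth), 25L)
  expect_true(all(sim$truth$curvature_per_mm == 1))
  expect_true(all(sim$truth$length_mm == pi / 2))

  # high curvature: every fragment fits a circle of diameter 2r plus stroke
  sim2 <- simulateArcImage(2, nFragments = 10, canvas = c(900, 700),
                           seed = 3)
  lab2 <- EBImage::bwlabel(pixels(sim2$image) < 0.5)
  limit <- 2 * (1 / 2) * 132 + 5 + 3  # 2r in px + line width + raster slack
  for (k in seq_len(max(lab2))) {
    idx <- which(lab2 == k, arr.ind = TRUE)
    hull <- idx[grDevices::chull(idx), , drop = FALSE]
    expect_lte(max(dist(hull)), limit)
  }
})

test_that("arc simulation is seed-deterministic and fails on tiny canvases", {
  a <- simulateArcImage(0.8, nFragments = 4, canvas = c(1000, 800),
                        seed = 11)
  b <- simulateArcImage(0.8, nFragments = 4, canvas = c(1000, 800),
                        seed = 11)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth, b$truth)
  expect_error(simulateArcImage(0.1, nFragments = 2, canvas = c(150, 150),
                                seed = 1), "canvas too small")
  expect_error(simulateArcImage(2, nFragments = 500,
                                canvas = c(400, 400), seed = 1),
               "disjoint")
})

test_that("rasterized ellipses match their analytic geometry", {
  # circle: eccentricity 0, diameter 100 um at 4.25 px/um
  sim <- simulateEllipseImage(ellipseSpec(100, 0), canvas = c(700, 700))
  fg <- sum(pixels(sim$image) < 0.5)
  expect_equal(fg / 4.25^2, pi * 50^2, tolerance = 5e-3)
  expect_equal(sim$truth$min_diameter_um, sim$truth$max_diameter_um)

  # eccentricity 0.8 fixes the minor diameter at 60 um
  sp <- ellipseSpec(100, 0.8)
  expect_equal(sp@minDiameterUm, 60, tolerance = 1e-12)
  sim2 <- simulateEllipseImage(sp, canvas = c(700, 700))
  expect_equal(sim2$truth$area_um2, pi * 50 * 30, tolerance = 1e-12)

  expect_error(simulateEllipseImage(ellipseSpec(300, 0),
                                    canvas = c(700, 700)),
               "exceeds the canvas")
})

test_that("arc dataset generation writes files, truth and is reproducible", {
  d <- withr::local_tempdir()
  tr <- generateArcDataset(c(1.0), d, seed = 2, nFragments = 3,
                           canvas = c(1000, 800))
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$curvature_per_mm, 1.0)
  files <- list.files(d, pattern = "\\.tiff$")
  expect_length(files, 1L)
  csv <- read.csv(file.path(d, "arc_truth.csv"))
  expect_equal(csv$length_mm, pi / 2, tolerance = 1e-12)
  expect_identical(sub("\\.tiff$", "", files), csv$image_id)
})

test_that("ellipse dataset generation samples within the study bounds", {
  d <- withr::local_tempdir()
  tr <- generateEllipseDataset(5, d, seed = 9, canvas = c(700, 700))
  expect_identical(nrow(tr), 5L)
  expect_length(list.files(d, pattern = "\\.tiff$"), 5L)
  expect_true(all(tr$eccentricity >= 0 & tr$eccentricity < 1))
  expect_true(all(tr$min_diameter_um <= tr$max_diameter_um))
  expect_true(all(tr$max_diameter_um >= 50 & tr$max_diameter_um <= 120))
  d2 <- withr::local_tempdir()
  tr2 <- generateEllipseDataset(5, d2, seed = 9, canvas = c(700, 700))
  rownames(tr) <- rownames(tr2) <- NULL
  expect_identical(tr, tr2)
})
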
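test_that("ridge filter responds on centrelines and is silent on flats", {
  expect_true(all(ridgeEnhance(matrix(0.7, 60, 80)) < 1e-10))
  expect_identical(dim(ridgeEnhance(matrix(runif(300), 15, 20))),
                   c(15L, 20L))
  expect_error(ridgeEnhance(array(0, c(4, 4, 3))), "2-D")

  sim <- simulateArcImage(1, nFragments = 1, canvas = c(700, 600),
                          seed = 21)
  resp <- ridgeEnhance(pixels(sim$image))
  # the strongest responses must sit within 2 px of the true centreline,
  # i.e. at distance ~ r from the circle centre recovered from the stroke
  idx <- which(pixels(sim$image) < 0.5, arr.ind = TRUE)
  fit <- fitCircleTaubin(cbind(idx[, 2L], idx[, 1L]))  # stroke centreline
  top <- order(resp, decreasing = TRUE)[1:100]
  ti <- arrayInd(top, dim(resp))
  d <- sqrt((ti[, 2L] - fit@center[1L])^2 + (ti[, 1L] - fit@center[2L])^2)
  expect_lt(max(abs(d - fit@radiusPx)), 2)
})

test_that("binarization keeps fragments and drops specks", {
  sim <- simulateArcImage(0.5, nFragments = 25, canvas = testCanvasArc,
                          seed = 31)
  px <- pixels(sim$image)
  mask <- binarizeAndClean(ridgeEnhance(px))
  expect_equal(max(EBImage::bwlabel(mask)), 25)

  # ten isolated 3-px specks must not change the component count
  px2 <- px
  set.seed(4)
  for (k in 1:10) {
    i <- sample(20:1900, 1); j <- sample(20:2500, 1)
    if (all(px2[i + (-6:6), j + (-6:6)] == 1)) px2[i, j + 0:2] <- 0
  }
  mask2 <- binarizeAndClean(ridgeEnhance(px2))
  expect_equal(max(EBImage::bwlabel(mask2)),
               max(EBImage::bwlabel(mask)))

  expect_warning(empty <- binarizeAndClean(matrix(0, 40, 40)), "empty")
  expect_false(any(empty))
})

test_that("skeletonization yields one simple trace per fragment", {
  sim <- simulateArcImage(1, nFragments = 1, canvas = c(700, 600),
                          seed = 8)
  mask <- binarizeAndClean(ridgeEnhance(pixels(sim$image)))
  tr <- skeletonizeAndSplit(mask)
  expect_length(tr, 1L)
  expect_true(validObject(tr[[1L]]))
  # raw pixel count depends on orientation (diagonal chains use fewer
  # pixels per mm); it must stay within the geometric bounds, and the
  # corrected estimator must land on the true length
  npix <- nrow(tracePath(tr[[1L]]))
  Lpx <- pi / 2 * 132
  expect_gte(npix, Lpx / sqrt(2) * 0.97)
  expect_lte(npix, (Lpx + 8) * 1.03)
  expect_equal(fragmentLength(tr[[1L]], 132), pi / 2, tolerance = 0.015)

  sim2 <- simulateArcImage(1.5, nFragments = 2, canvas = c(900, 700),
                           seed = 12)
  mask2 <- binarizeAndClean(ridgeEnhance(pixels(sim2$image)))
  expect_length(skeletonizeAndSplit(mask2), 2L)

  expect_identical(skeletonizeAndSplit(matrix(FALSE, 30, 30)), list())
})

test_that("crossing strokes are split at the branch point, never merged", {
  m <- strokeMask(200, 200, c(100, 30), c(100, 170)) |
    strokeMask(200, 200, c(30, 100), c(170, 100))
  tr <- skeletonizeAndSplit(m, minLengthPx = 16L)
  expect_length(tr, 4L)
  for (t in tr) {
    p <- tracePath(t)
    # each arm is simple: interior pixels have exactly two path neighbours
    expect_true(all(abs(diff(p)) <= 1))
  }
})

test_that("fragment length applies the corrected chain-code estimator", {
  kulpa <- pi / 8 * (1 + sqrt(2))
  horiz <- FragmentTrace(cbind(5L, 1:10))
  expect_equal(fragmentLength(horiz, 132), kulpa * 9 / 132)
  diag10 <- FragmentTrace(cbind(1:10, 1:10))
  expect_equal(fragmentLength(diag10, 1), kulpa * 9 * sqrt(2))
  expect_equal(fragmentLength(FragmentTrace(cbind(3L, 3L)), 132), 0)

  # end to end: a rasterized arc of true length pi/2 mm reads within 1%
  sim <- simulateArcImage(0.7, nFragments = 1, canvas = c(700, 600),
                          seed = 40)
  mask <- binarizeAndClean(ridgeEnhance(pixels(sim$image)))
  tr <- skeletonizeAndSplit(mask)
  expect_equal(fragmentLength(tr[[1L]], 132), pi / 2, tolerance = 0.01)
})

test_that("Taubin fit is exact on noiseless circles", {
  fit <- fitCircleTaubin(cbind(c(0, 1, 0), c(1, 0, -1)))
  expect_equal(fit@center, c(0, 0), tolerance = 1e-12)
  expect_equal(fit@radiusPx, 1, tolerance = 1e-12)

  th <- seq(0, 1.2, length.out = 25)
  pts <- cbind(40 + 250 * cos(th), -10 + 250 * sin(th))
  fit <- fitCircleTaubin(pts)
  expect_equal(fit@radiusPx, 250, tolerance = 1e-6)
  expect_lt(fit@residual, 1e-9)
  expect_false(fit@degenerate)
})

test_that("Taubin fit agrees with the geometric least-squares oracle", {
  set.seed(99)
  for (k in 1:5) {
    th <- seq(0.3, 0.3 + runif(1, 0.6, 2), length.out = 25)
    pts <- cbind(250 * cos(th) + rnorm(25), 250 * sin(th) + rnorm(25))
    taubin <- fitCircleTaubin(pts)
    geo <- geomCircleFit(pts)
    expect_equal(taubin@radiusPx, geo$radius, tolerance = 0.02)
  }
  # noiseless arcs spanning >= 30 degrees: agreement within 0.1%
  th <- seq(0, pi / 6, length.out = 40)
  pts <- cbind(500 * cos(th), 500 * sin(th))
  expect_equal(fitCircleTaubin(pts)@radiusPx, geomCircleFit(pts)$radius,
               tolerance = 1e-3)
})

test_that("degenerate and invalid circle-fit inputs are handled", {
  expect_error(fitCircleTaubin(cbind(1:2, 1:2)), "3 points")
  fit <- fitCircleTaubin(cbind(1:20, 2 * (1:20) + 3))
  expect_true(fit@degenerate)
  expect_identical(fragmentCurvature(fit, 132), 0)
})

test_that("curvature is the reciprocal radius in mm", {
  mk <- function(r) new("CircleFit", center = c(0, 0), radiusPx = r,
                        residual = 0, degenerate = FALSE)
  expect_equal(fragmentCurvature(mk(132), 132), 1)
  expect_equal(fragmentCurvature(mk(66), 132), 2)
  # scale equivariance: doubling resolution and pixel radius together
  expect_equal(fragmentCurvature(mk(200), 100),
               fragmentCurvature(mk(400), 200))
})

test_that("single-image analysis recovers simulated truth", {
  sim <- simulateArcImage(1, nFragments = 25, canvas = testCanvasArc,
                          seed = 17)
  out <- analyzeCurvatureImage(sim$image, imageId = "sim")
  expect_identical(out$summary$hair_count, 25L)
  expect_equal(out$summary$mean_curvature_per_mm, 1, tolerance = 0.01)
  expect_equal(out$summary$median_curvature_per_mm, 1, tolerance = 0.01)
  expect_equal(out$summary$mean_length_mm, pi / 2, tolerance = 0.01)
  expect_identical(nrow(out$fragments), 25L)

  one <- simulateArcImage(0.4, nFragments = 1, canvas = c(900, 800),
                          seed = 23)
  s1 <- analyzeCurvatureImage(one$image, imageId = "one")$summary
  expect_equal(s1$mean_curvature_per_mm, s1$median_curvature_per_mm)

  blank <- CalibratedImage(matrix(1, 300, 300), 132, "mm")
  expect_warning(s0 <- analyzeCurvatureImage(blank, "blank")$summary)
  expect_identical(s0$hair_count, 0L)
  expect_true(is.na(s0$mean_curvature_per_mm))
})

test_that("directory analysis is deterministic and skips bad files", {
  d <- withr::local_tempdir(); o <- withr::local_tempdir()
  generateArcDataset(c(0.5, 1.5), d, seed = 6, nFragments = 3,
                     canvas = c(1100, 900))
  writeLines("not a tiff", file.path(d, "broken.tiff"))
  expect_message(
    s1 <- analyzeCurvatureDir(d, 132, outputDir = o, saveRaw = TRUE),
    "broken")
  expect_identical(nrow(s1), 2L)
  expect_true(file.exists(file.path(o, "summary_curvature.csv")))
  expect_length(list.files(o, pattern = "_fragments\\.csv$"), 2L)
  s2 <- suppressMessages(analyzeCurvatureDir(d, 132))
  expect_identical(s1, s2)

  empty <- withr::local_tempdir()
  s0 <- analyzeCurvatureDir(empty, 132)
  expect_identical(nrow(s0), 0L)
  expect_identical(names(s0)[1:2], c("image_id", "hair_count"))
})
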
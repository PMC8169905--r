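# Cross-section pipeline: crop -> Chan-Vese segmentation -> moment-based
# geometry (area, min/max diameter, eccentricity).

#' @noRd
.noSection <- function(msg) {
  stop(errorCondition(msg, class = c("hairmorph_no_section", "error")))
}

#' Crop a section micrograph around the fiber
#'
#' Locates the darkest coherent blob by coarse Otsu thresholding and
#' returns a square crop centred on its centroid. Cropping keeps the
#' active-contour segmentation cheap on full-size canvases. A no-op when
#' the image is already no larger than the crop window.
#'
#' @param image a [CalibratedImage-class].
#' @param cropPx side length of the square crop, px. The default
#'   comfortably contains the largest sections in the validation range
#'   (120 um at 4.25 px/um is 510 px).
#' @return A cropped [CalibratedImage-class].
#' @export
cropToRegion <- function(image, cropPx = 640L) {
  stopifnot(is(image, "CalibratedImage"))
  px <- pixels(image)
  if (nrow(px) <= cropPx && ncol(px) <= cropPx) return(image)
  rng <- range(px)
  if (diff(rng) < 0.05)
    .noSection("no section found: image has no contrast")
  # blob detection on a stride-subsampled copy: centroid accuracy of a few
  # pixels is ample for centring a crop window
  stride <- max(1L, ceiling(max(dim(px)) / 1500L))
  sub <- px[seq(1L, nrow(px), by = stride), seq(1L, ncol(px), by = stride)]
  sub01 <- (sub - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(sub01))
  lab <- EBImage::bwlabel(sub01 < th)
  areas <- tabulate(lab[lab > 0])
  if (!length(areas))
    .noSection("no section found: no dark region below threshold")
  best <- which.max(areas)
  idx <- which(lab == best, arr.ind = TRUE)
  ci <- round((mean(idx[, 1L]) - 1) * stride) + 1L
  cj <- round((mean(idx[, 2L]) - 1) * stride) + 1L
  half <- cropPx %/% 2L
  r0 <- min(max(1L, ci - half), max(1L, nrow(px) - cropPx + 1L))
  c0 <- min(max(1L, cj - half), max(1L, ncol(px) - cropPx + 1L))
  r1 <- min(nrow(px), r0 + cropPx - 1L)
  c1 <- min(ncol(px), c0 + cropPx - 1L)
  CalibratedImage(px[r0:r1, c0:c1], resolution(image),
                  resolutionUnit(image))
}

#' Segment a cross-section with a Chan-Vese active contour
#'
#' Two-phase piecewise-constant Chan-Vese segmentation (level-set
#' formulation, intensity-seeded initial level set, semi-implicit
#' Gauss-Seidel updates). The
#' phase with the lower mean intensity is taken as the section, the
#' largest connected region is retained and its holes are filled. If the
#' two phase means are indistinguishable the image is reported as
#' containing no section; if the iteration budget is exhausted the current
#' mask is returned with the \code{converged} flag unset and a warning.
#'
#' @param image a (cropped) [CalibratedImage-class].
#' @param mu boundary-length penalty on the \code{[0, 1]} intensity scale
#'   (default 0.25); larger values smooth the contour.
#' @param tol stop when fewer than this fraction of pixels change phase
#'   in one sweep (default 1e-3).
#' @param maxIter iteration budget (default 200).
#' @return A [SectionMask-class].
#' @examples
#' sim <- simulateEllipseImage(ellipseSpec(100, 0.6), canvas = c(640, 640))
#' m <- segmentChanVese(sim$image)
#' sum(maskPixels(m))
#' @export
segmentChanVese <- function(image, mu = 0.25, tol = 1e-3,
                            maxIter = 200L) {
  stopifnot(is(image, "CalibratedImage"))
  px <- pixels(image)
  cv <- .chanvese_cpp(px, mu, tol, as.integer(maxIter), 0.5, 1.0)
  if (!cv$converged)
    warning("Chan-Vese did not converge within ", maxIter, " iterations")
  inside <- cv$phi >= 0
  mIn <- mean(px[inside]); mOut <- mean(px[!inside])
  if (!is.finite(mIn) || !is.finite(mOut) || abs(mIn - mOut) < 0.02)
    .noSection("degenerate segmentation: phases are indistinguishable")
  fg <- if (mIn < mOut) inside else !inside
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  if (!length(areas))
    .noSection("degenerate segmentation: empty foreground")
  mask <- lab == which.max(areas)
  mask <- EBImage::fillHull(mask) > 0
  idx <- which(mask, arr.ind = TRUE)
  new("SectionMask", mask = mask,
      centroid = c(mean(idx[, 1L]), mean(idx[, 2L])),
      converged = isTRUE(cv$converged))
}

#' @noRd
.regionMoments <- function(idx) {
  mi <- mean(idx[, 1L]); mj <- mean(idx[, 2L])
  di <- idx[, 1L] - mi; dj <- idx[, 2L] - mj
  list(mu20 = mean(dj * dj), mu02 = mean(di * di), mu11 = mean(di * dj),
       centroid = c(mi, mj))
}

#' Measure cross-sectional geometry of a segmented region
#'
#' Area is the foreground pixel count divided by the squared resolution.
#' Minimum and maximum diameters are the minor/major axis lengths of the
#' moments-equivalent ellipse (the ellipse with the same second central
#' moments as the region), so the reported eccentricity
#' \code{sqrt(1 - b^2/a^2)} is self-consistent with the diameters.
#'
#' @param mask a [SectionMask-class] or logical matrix.
#' @param resolutionPpum pixels per micrometre.
#' @param imageId identifier for the output row.
#' @return One-row data frame: image_id, area_um2, min_diameter_um,
#'   max_diameter_um, eccentricity.
#' @examples
#' sim <- simulateEllipseImage(ellipseSpec(100), canvas = c(640, 640))
#' m <- segmentChanVese(sim$image)
#' measureSection(m, 4.25)
#' @export
measureSection <- function(mask, resolutionPpum, imageId = "section") {
  m <- if (is(mask, "SectionMask")) maskPixels(mask) else mask
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: nothing to measure")
  areaUm2 <- nrow(idx) / resolutionPpum^2
  mom <- .regionMoments(idx)
  tr <- (mom$mu20 + mom$mu02) / 2
  disc <- sqrt(max(0, (mom$mu20 - mom$mu02)^2 / 4 + mom$mu11^2))
  lmax <- tr + disc; lmin <- max(0, tr - disc)
  majorPx <- 4 * sqrt(lmax)  # axis lengths of the moments-equivalent ellipse
  minorPx <- 4 * sqrt(lmin)
  ecc <- if (majorPx > 0) sqrt(max(0, 1 - (minorPx / majorPx)^2)) else 0
  data.frame(image_id = imageId,
             area_um2 = areaUm2,
             min_diameter_um = minorPx / resolutionPpum,
             max_diameter_um = majorPx / resolutionPpum,
             eccentricity = min(ecc, 1 - 1e-12))
}

#' @noRd
.measureRegions <- function(mask, resolutionPpum, imageId, minAreaPx) {
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minAreaPx)
  rows <- lapply(seq_along(keep), function(k) {
    r <- measureSection(lab == keep[k], resolutionPpum,
                        imageId = if (length(keep) > 1L)
                          sprintf("%s_r%02d", imageId, k) else imageId)
    r
  })
  do.call(rbind, rows)
}

#' Batch cross-section analysis over a directory of TIFFs
#'
#' For each readable TIFF: crop to the section, segment with Chan-Vese,
#' and measure. Failures (unreadable files, blank images) are logged and
#' skipped without aborting the batch.
#'
#' @param inputDir directory of grayscale section micrographs.
#' @param resolutionPpum pixels per micrometre (microscope calibration;
#'   4.25 for the simulated validation images).
#' @param outputDir if non-\code{NULL}, \code{summary_section.csv} is
#'   written there.
#' @param cropPx crop window passed to [cropToRegion()].
#' @param multi if \code{TRUE}, emit one row per segmented region above
#'   \code{minAreaPx} instead of the largest region only (section chips
#'   can carry several embedded hairs).
#' @param minAreaPx smallest region reported under \code{multi}.
#' @param ... passed to [segmentChanVese()].
#' @return Data frame with one row per section (or region).
#' @export
analyzeSectionDir <- function(inputDir, resolutionPpum = 4.25,
                              outputDir = NULL, cropPx = 640L,
                              multi = FALSE, minAreaPx = 200L, ...) {
  files <- .listTiffs(inputDir)
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  rows <- list()
  for (f in files) {
    id <- .imageId(f)
    row <- tryCatch({
      img <- readGrayscaleTIFF(f, resolution = resolutionPpum, unit = "um")
      img <- cropToRegion(img, cropPx = cropPx)
      sm <- segmentChanVese(img, ...)
      if (multi)
        .measureRegions(maskPixels(sm), resolutionPpum, id, minAreaPx)
      else
        measureSection(sm, resolutionPpum, imageId = id)
    }, error = function(e) {
      message("skipping '", basename(f), "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[id]] <- row
  }
  schema <- c("image_id", "area_um2", "min_diameter_um", "max_diameter_um",
              "eccentricity")
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(schema)),
                           schema))
  rownames(out) <- NULL
  if (!is.null(outputDir))
    .writeCsv(out, schema, file.path(outputDir, "summary_section.csv"))
  out
}
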
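# Ground-truth simulators. Arcs and ellipses are rasterized analytically
# (distance tests on pixel centres, no anti-aliasing) so that the truth
# tables are exact by construction.

#' @noRd
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample points along a circular arc
#'
#' Returns \code{nPoints} coordinates on the circle of radius
#' \code{radiusMm} about \code{center}, at angles uniformly spaced between
#' \code{thetaStart} and \code{thetaStart + pi / (2 radiusMm)}. With this
#' angular sweep every arc has true length \code{pi/2} mm regardless of
#' curvature: \code{r * (pi / (2 r)) = pi/2}.
#'
#' @param spec an [ArcSpec-class].
#' @param center circle centre \code{c(x, y)} in mm.
#' @return Numeric matrix with columns \code{x}, \code{y} (mm), one row
#'   per point, ordered by angle.
#' @examples
#' arcPoints(arcSpec(radiusMm = 1, nPoints = 3))  # (1,0), (.71,.71), (0,1)
#' @export
arcPoints <- function(spec, center = c(0, 0)) {
  stopifnot(is(spec, "ArcSpec"))
  validObject(spec)
  theta <- seq(spec@thetaStart, spec@thetaStart + pi / (2 * spec@radiusMm),
               length.out = spec@nPoints)
  cbind(x = center[1L] + spec@radiusMm * cos(theta),
        y = center[2L] + spec@radiusMm * sin(theta))
}

# Rasterize one arc (annulus sector + round end caps) into 'px' in place.
# Returns the bounding box used, c(r0, r1, c0, c1).
#' @noRd
.stampArc <- function(px, cx, cy, radiusPx, thetaStart, sweep, widthPx) {
  h <- widthPx / 2
  thetaEnd <- thetaStart + sweep
  thetaFine <- seq(thetaStart, thetaEnd,
                   length.out = max(32L, ceiling(radiusPx * sweep)))
  xs <- cx + radiusPx * cos(thetaFine)
  ys <- cy + radiusPx * sin(thetaFine)
  c0 <- max(1L, floor(min(xs) - h - 1)); c1 <- min(ncol(px), ceiling(max(xs) + h + 1))
  r0 <- max(1L, floor(min(ys) - h - 1)); r1 <- min(nrow(px), ceiling(max(ys) + h + 1))
  jj <- c0:c1; ii <- r0:r1
  dx <- matrix(jj - cx, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  dy <- matrix(ii - cy, nrow = length(ii), ncol = length(jj))
  d <- sqrt(dx^2 + dy^2)
  rel <- (atan2(dy, dx) - thetaStart) %% (2 * pi)
  fg <- (abs(d - radiusPx) <= h & rel <= sweep)
  for (end in c(thetaStart, thetaEnd)) {
    ex <- cx + radiusPx * cos(end); ey <- cy + radiusPx * sin(end)
    fg <- fg | ((dx - (ex - cx))^2 + (dy - (ey - cy))^2 <= h^2)
  }
  px[ii, jj][fg] <- 0
  list(px = px, bbox = c(r0, r1, c0, c1))
}

#' Simulate one calibrated image of hair-fragment arcs
#'
#' Draws \code{nFragments} disjoint dark arcs of identical curvature (and
#' hence identical true length \code{pi/2} mm) on a light canvas, with
#' start angles drawn uniformly on \code{(0, pi)} and positions placed by
#' rejection sampling so that fragment bounding boxes keep a minimum
#' clearance. The rasterization is binary (no anti-aliasing) so the ground
#' truth is unambiguous.
#'
#' @param curvaturePerMm true curvature of every fragment, 1/mm.
#' @param nFragments number of arcs per image (default 25).
#' @param canvas image size as \code{c(width, height)} in pixels; the
#'   full-scale default is \code{c(5200, 3900)}.
#' @param resolutionPpmm spatial calibration, pixels per mm (default 132).
#' @param seed optional integer; the same seed reproduces the image and
#'   truth table bit for bit.
#' @param imageId identifier recorded in the truth table.
#' @param lineWidthPx stroke width of the rasterized arcs (default 5 px:
#'   thin relative to the smallest radius at 132 px/mm, thick enough for
#'   the skeleton to recover the centre line).
#' @param clearancePx minimum clearance between fragment bounding boxes
#'   (default 10 px); the analysis pipeline assumes non-touching fragments.
#' @param maxTries placement attempts per fragment before giving up.
#' @return A list with \code{image} (a [CalibratedImage-class]) and
#'   \code{truth} (data frame: image_id, element_id, curvature_per_mm,
#'   length_mm).
#' @examples
#' sim <- simulateArcImage(1, nFragments = 5, canvas = c(1000, 800),
#'                         seed = 7)
#' sim$truth
#' @export
simulateArcImage <- function(curvaturePerMm, nFragments = 25L,
                             canvas = c(5200L, 3900L),
                             resolutionPpmm = 132, seed = NULL,
                             imageId = "arc", lineWidthPx = 5,
                             clearancePx = 10, maxTries = 500L) {
  if (curvaturePerMm <= 0) stop("'curvaturePerMm' must be positive")
  .withSeed(seed, {
    radiusMm <- 1 / curvaturePerMm
    radiusPx <- radiusMm * resolutionPpmm
    sweep <- pi / (2 * radiusMm)
    w <- canvas[1L]; hgt <- canvas[2L]
    px <- matrix(1, nrow = hgt, ncol = w)
    boxes <- matrix(numeric(0), ncol = 4L)
    margin <- lineWidthPx / 2 + 2
    for (k in seq_len(nFragments)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        thetaStart <- runif(1L, 0, pi)
        thetaFine <- seq(thetaStart, thetaStart + sweep, length.out = 64L)
        relx <- radiusPx * cos(thetaFine); rely <- radiusPx * sin(thetaFine)
        # admissible centre range so the arc (plus stroke) fits the canvas
        cxLo <- margin - min(relx); cxHi <- w - margin - max(relx)
        cyLo <- margin - min(rely); cyHi <- hgt - margin - max(rely)
        if (cxLo >= cxHi || cyLo >= cyHi)
          stop("canvas too small for arcs of curvature ", curvaturePerMm,
               " /mm", call. = FALSE)
        cx <- runif(1L, cxLo, cxHi); cy <- runif(1L, cyLo, cyHi)
        box <- c(cy + min(rely) - margin, cy + max(rely) + margin,
                 cx + min(relx) - margin, cx + max(relx) + margin)
        clash <- FALSE
        if (nrow(boxes)) {
          clash <- any(box[1L] - clearancePx < boxes[, 2L] &
                       box[2L] + clearancePx > boxes[, 1L] &
                       box[3L] - clearancePx < boxes[, 4L] &
                       box[4L] + clearancePx > boxes[, 3L])
        }
        if (!clash) {
          st <- .stampArc(px, cx, cy, radiusPx, thetaStart, sweep,
                          lineWidthPx)
          px <- st$px
          boxes <- rbind(boxes, box)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", nFragments, " disjoint fragments after ",
             maxTries, " tries per fragment; enlarge the canvas",
             call. = FALSE)
    }
    truth <- data.frame(image_id = imageId,
                        element_id = seq_len(nFragments),
                        curvature_per_mm = curvaturePerMm,
                        length_mm = pi / 2)
    list(image = CalibratedImage(px, resolutionPpmm, "mm"), truth = truth)
  })
}

#' Generate the arc validation dataset
#'
#' Writes one TIFF per curvature value plus a per-image truth table. The
#' default grid is 20 curvatures evenly spaced on \code{[0.1, 2]} 1/mm,
#' each image holding 25 fragments of true length \code{pi/2} mm.
#'
#' @param curvatureGrid curvature values, 1/mm; one image per value.
#' @param outDir output directory (created if missing).
#' @param seed optional integer seed; per-image seeds are derived from it.
#' @param nFragments,canvas,resolutionPpmm,lineWidthPx passed to
#'   [simulateArcImage()].
#' @return The truth data frame (image_id, curvature_per_mm, length_mm,
#'   n_fragments), invisibly; also written to \code{arc_truth.csv}.
#' @examples
#' d <- tempfile(); dir.create(d)
#' tr <- generateArcDataset(c(0.5, 1), d, seed = 1, nFragments = 3,
#'                          canvas = c(900, 700))
#' @export
generateArcDataset <- function(curvatureGrid = seq(0.1, 2,
                                                   length.out = 20L),
                               outDir, seed = NULL, nFragments = 25L,
                               canvas = c(5200L, 3900L),
                               resolutionPpmm = 132, lineWidthPx = 5) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  ids <- sprintf("arc_%02d_c%s", seq_along(curvatureGrid),
                 formatC(curvatureGrid, format = "f", digits = 3))
  rows <- vector("list", length(curvatureGrid))
  for (i in seq_along(curvatureGrid)) {
    sim <- simulateArcImage(curvatureGrid[i], nFragments = nFragments,
                            canvas = canvas,
                            resolutionPpmm = resolutionPpmm,
                            seed = if (is.null(seed)) NULL else seed + i,
                            imageId = ids[i], lineWidthPx = lineWidthPx)
    writeGrayscaleTIFF(sim$image, file.path(outDir,
                                            paste0(ids[i], ".tiff")))
    rows[[i]] <- data.frame(image_id = ids[i],
                            curvature_per_mm = curvatureGrid[i],
                            length_mm = pi / 2,
                            n_fragments = nFragments)
  }
  truth <- do.call(rbind, rows)
  .writeCsv(truth, c("image_id", "curvature_per_mm", "length_mm",
                     "n_fragments"),
            file.path(outDir, "arc_truth.csv"))
  invisible(truth)
}

#' Rasterize the exact foreground mask of an ellipse
#'
#' Used both by the simulator and as the ground-truth mask when scoring
#' segmentation overlap.
#'
#' @param spec an [EllipseSpec-class].
#' @param canvas \code{c(width, height)} in pixels.
#' @param resolutionPpum pixels per micrometre.
#' @return Logical matrix, \code{TRUE} inside the centred ellipse.
#' @export
ellipseMask <- function(spec, canvas = c(5200L, 3900L),
                        resolutionPpum = 4.25) {
  stopifnot(is(spec, "EllipseSpec"))
  a <- spec@maxDiameterUm / 2 * resolutionPpum
  b <- spec@minDiameterUm / 2 * resolutionPpum
  if (2 * a >= min(canvas))
    stop("ellipse diameter exceeds the canvas at this resolution",
         call. = FALSE)
  cx <- (canvas[1L] + 1) / 2
  cy <- (canvas[2L] + 1) / 2
  phi <- spec@rotationDeg * pi / 180
  mask <- matrix(FALSE, nrow = canvas[2L], ncol = canvas[1L])
  c0 <- max(1L, floor(cx - a - 2)); c1 <- min(canvas[1L], ceiling(cx + a + 2))
  r0 <- max(1L, floor(cy - a - 2)); r1 <- min(canvas[2L], ceiling(cy + a + 2))
  jj <- c0:c1; ii <- r0:r1
  dx <- matrix(jj - cx, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  dy <- matrix(ii - cy, nrow = length(ii), ncol = length(jj))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  mask[ii, jj] <- (u / a)^2 + (v / b)^2 <= 1
  mask
}

#' Simulate one calibrated cross-section image
#'
#' Draws a single filled dark ellipse, centred on the canvas, on a light
#' ground. When \code{spec} is \code{NULL} the geometry is sampled as in
#' the validation study: maximum diameter uniform on (50, 120) um,
#' eccentricity uniform on (0, 1), rotation uniform on (0, 360) degrees.
#'
#' @param spec an [EllipseSpec-class], or \code{NULL} to sample one.
#' @param canvas \code{c(width, height)} px; default \code{c(5200, 3900)}.
#' @param resolutionPpum pixels per micrometre (default 4.25).
#' @param seed optional integer seed (used only when sampling).
#' @param imageId identifier recorded in the truth table.
#' @return List with \code{image} ([CalibratedImage-class]), \code{truth}
#'   (data frame: image_id, min_diameter_um, max_diameter_um, area_um2,
#'   eccentricity; area is the analytic \code{pi a b}) and \code{spec}.
#' @examples
#' sim <- simulateEllipseImage(ellipseSpec(100, 0.8), canvas = c(700, 600))
#' sim$truth
#' @export
simulateEllipseImage <- function(spec = NULL, canvas = c(5200L, 3900L),
                                 resolutionPpum = 4.25, seed = NULL,
                                 imageId = "ellipse") {
  if (is.null(spec)) {
    spec <- .withSeed(seed,
      ellipseSpec(maxDiameterUm = runif(1L, 50, 120),
                  eccentricity = runif(1L),
                  rotationDeg = runif(1L, 0, 360)))
  }
  mask <- ellipseMask(spec, canvas, resolutionPpum)
  px <- matrix(1, nrow = canvas[2L], ncol = canvas[1L])
  px[mask] <- 0
  truth <- data.frame(image_id = imageId,
                      min_diameter_um = spec@minDiameterUm,
                      max_diameter_um = spec@maxDiameterUm,
                      area_um2 = pi * spec@maxDiameterUm *
                        spec@minDiameterUm / 4,
                      eccentricity = spec@eccentricity)
  list(image = CalibratedImage(px, resolutionPpum, "um"), truth = truth,
       spec = spec)
}

#' Generate the ellipse validation dataset
#'
#' @param n number of simulated sections (default 100).
#' @param outDir output directory (created if missing).
#' @param seed optional integer seed.
#' @param canvas,resolutionPpum passed to [simulateEllipseImage()].
#' @return The truth data frame, invisibly; also written to
#'   \code{ellipse_truth.csv}.
#' @export
generateEllipseDataset <- function(n = 100L, outDir, seed = NULL,
                                   canvas = c(5200L, 3900L),
                                   resolutionPpum = 4.25) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  specs <- .withSeed(seed, {
    maxD <- runif(n, 50, 120)
    ecc <- runif(n)
    rot <- runif(n, 0, 360)
    lapply(seq_len(n),
           function(i) ellipseSpec(maxD[i], ecc[i], rot[i]))
  })
  ids <- sprintf("ellipse_%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulateEllipseImage(specs[[i]], canvas = canvas,
                                resolutionPpum = resolutionPpum,
                                imageId = ids[i])
    writeGrayscaleTIFF(sim$image, file.path(outDir,
                                            paste0(ids[i], ".tiff")))
    rows[[i]] <- sim$truth
  }
  truth <- do.call(rbind, rows)
  .writeCsv(truth, c("image_id", "min_diameter_um", "max_diameter_um",
                     "area_um2", "eccentricity"),
            file.path(outDir, "ellipse_truth.csv"))
  invisible(truth)
}
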
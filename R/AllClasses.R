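#' @import methods
NULL

#' CalibratedImage: a grayscale micrograph with spatial calibration
#'
#' Container for a single-channel intensity grid together with its spatial
#' resolution. Longitudinal (curvature) images are calibrated in pixels per
#' millimetre; cross-section images in pixels per micrometre. Intensities
#' are stored as doubles in \code{[0, 1]}, origin at the top-left pixel,
#' coordinates as (row, col).
#'
#' @slot pixels numeric matrix of intensities in \code{[0, 1]}.
#' @slot resolution positive scalar, pixels per unit length.
#' @slot unit either \code{"mm"} or \code{"um"}: the length unit the
#'   resolution refers to.
#'
#' @seealso [readGrayscaleTIFF()], [simulateArcImage()],
#'   [simulateEllipseImage()]
#' @export
setClass("CalibratedImage",
  representation(pixels = "matrix", resolution = "numeric",
                 unit = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
      msg <- c(msg, "'pixels' must be a 2-D numeric matrix")
    if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
        object@resolution <= 0)
      msg <- c(msg, "'resolution' must be a single positive number")
    if (length(object@unit) != 1L || !object@unit %in% c("mm", "um"))
      msg <- c(msg, "'unit' must be \"mm\" or \"um\"")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix of grayscale intensities in \code{[0, 1]}.
#' @param resolution pixels per unit length (e.g. 132 px/mm for
#'   longitudinal images, 4.25 px/um for sections).
#' @param unit \code{"mm"} or \code{"um"}.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(matrix(1, 50, 80), resolution = 132, unit = "mm")
#' resolution(img)
#' @export
CalibratedImage <- function(pixels, resolution, unit = c("mm", "um")) {
  unit <- match.arg(unit)
  new("CalibratedImage", pixels = pixels, resolution = as.numeric(resolution),
      unit = unit)
}

#' @describeIn CalibratedImage-class image dimensions (rows, cols)
#' @param x a \code{CalibratedImage}
#' @export
setMethod("dim", "CalibratedImage", function(x) dim(x@pixels))

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat("CalibratedImage: ", d[2L], " x ", d[1L], " px (width x height), ",
      format(object@resolution), " px/", object@unit, "\n", sep = "")
  rng <- range(object@pixels)
  cat("  intensity range [", format(rng[1L], digits = 4), ", ",
      format(rng[2L], digits = 4), "]\n", sep = "")
})

#' FragmentTrace: the skeleton path of one hair fragment
#'
#' An ordered, simple, 8-connected path of pixel coordinates along the
#' 1-pixel-wide skeleton of a hair fragment, with the counts of axial
#' (4-neighbour) and diagonal steps used for the chain-code length
#' correction.
#'
#' @slot path integer matrix with columns (row, col), one row per pixel, in
#'   traversal order.
#' @slot nAxial number of horizontal/vertical steps along the path.
#' @slot nDiagonal number of diagonal steps along the path.
#' @export
setClass("FragmentTrace",
  representation(path = "matrix", nAxial = "integer", nDiagonal = "integer"),
  validity = function(object) {
    n <- nrow(object@path)
    if (ncol(object@path) != 2L)
      return("'path' must have two columns (row, col)")
    if (n >= 2L) {
      d <- abs(diff(object@path))
      if (any(pmax(d[, 1L], d[, 2L]) != 1L))
        return("'path' must be a connected 8-neighbour chain")
      if (object@nAxial + object@nDiagonal != n - 1L)
        return("step counts must sum to length(path) - 1")
    }
    TRUE
  })

FragmentTrace <- function(path) {
  path <- as.matrix(path)
  storage.mode(path) <- "integer"
  if (nrow(path) < 2L) {
    nA <- 0L; nD <- 0L
  } else {
    d <- abs(diff(path))
    diag <- d[, 1L] == 1L & d[, 2L] == 1L
    nD <- sum(diag)
    nA <- nrow(path) - 1L - nD
  }
  new("FragmentTrace", path = path, nAxial = as.integer(nA),
      nDiagonal = as.integer(nD))
}

setMethod("show", "FragmentTrace", function(object) {
  cat("FragmentTrace: ", nrow(object@path), " px (",
      object@nAxial, " axial + ", object@nDiagonal, " diagonal steps)\n",
      sep = "")
})

#' CircleFit: result of an algebraic circle fit
#'
#' @slot center fitted centre (x, y) in pixel coordinates.
#' @slot radiusPx fitted radius in pixels (\code{Inf} when degenerate).
#' @slot residual RMS orthogonal distance of the points to the fitted
#'   circle, in pixels.
#' @slot degenerate \code{TRUE} when the points are numerically collinear;
#'   such fragments are reported with curvature 0 (straight hair).
#' @seealso [fitCircleTaubin()]
#' @export
setClass("CircleFit",
  representation(center = "numeric", radiusPx = "numeric",
                 residual = "numeric", degenerate = "logical"),
  validity = function(object) {
    if (length(object@center) != 2L) return("'center' must have length 2")
    if (!object@degenerate && (!is.finite(object@radiusPx) ||
                               object@radiusPx <= 0))
      return("'radiusPx' must be positive unless the fit is degenerate")
    if (is.finite(object@residual) && object@residual < 0)
      return("'residual' must be non-negative")
    TRUE
  })

setMethod("show", "CircleFit", function(object) {
  if (object@degenerate) {
    cat("CircleFit: degenerate (collinear points)\n")
  } else {
    cat("CircleFit: centre (", format(object@center[1L], digits = 6), ", ",
        format(object@center[2L], digits = 6), "), radius ",
        format(object@radiusPx, digits = 6), " px, RMS residual ",
        format(object@residual, digits = 4), " px\n", sep = "")
  }
})

#' SectionMask: segmented cross-section of a hair fiber
#'
#' @slot mask logical matrix, \code{TRUE} on the retained section region
#'   (single 8-connected region, holes filled).
#' @slot centroid region centroid as (row, col) in pixels.
#' @slot converged whether the active contour met its tolerance within the
#'   iteration budget.
#' @seealso [segmentChanVese()], [measureSection()]
#' @export
setClass("SectionMask",
  representation(mask = "matrix", centroid = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("'mask' must be logical")
    if (length(object@centroid) != 2L) return("'centroid' must have length 2")
    TRUE
  })

setMethod("show", "SectionMask", function(object) {
  cat("SectionMask: ", sum(object@mask), " foreground px, centroid (",
      format(object@centroid[1L], digits = 5), ", ",
      format(object@centroid[2L], digits = 5), ")",
      if (!object@converged) " [contour not converged]", "\n", sep = "")
})

#' ArcSpec: parameters of one simulated arc
#'
#' A circular arc of radius \code{radiusMm} starting at angle
#' \code{thetaStart} and sweeping \code{pi / (2 radiusMm)} radians, so that
#' every simulated arc has the same true length \code{pi/2} mm regardless
#' of its curvature.
#'
#' @slot radiusMm arc radius in mm.
#' @slot curvaturePerMm reciprocal radius, 1/mm.
#' @slot thetaStart start angle in radians, in \code{[0, pi)}.
#' @slot nPoints number of points used when sampling the arc as discrete
#'   coordinates (see [arcPoints()]).
#' @export
setClass("ArcSpec",
  representation(radiusMm = "numeric", curvaturePerMm = "numeric",
                 thetaStart = "numeric", nPoints = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@radiusMm <= 0) msg <- c(msg, "'radiusMm' must be positive")
    if (abs(object@radiusMm * object@curvaturePerMm - 1) > 1e-8)
      msg <- c(msg, "'curvaturePerMm' must equal 1 / radiusMm")
    if (object@thetaStart < 0 || object@thetaStart >= pi)
      msg <- c(msg, "'thetaStart' must lie in [0, pi)")
    if (object@nPoints < 2L) msg <- c(msg, "'nPoints' must be at least 2")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ArcSpec
#'
#' Exactly one of \code{radiusMm} and \code{curvaturePerMm} must be given.
#'
#' @param radiusMm arc radius in mm.
#' @param curvaturePerMm curvature in 1/mm (reciprocal radius).
#' @param thetaStart start angle in radians, in \code{[0, pi)}.
#' @param nPoints number of sampled points (default 25).
#' @return An [ArcSpec-class] object.
#' @examples
#' arcSpec(curvaturePerMm = 0.5, thetaStart = 1)
#' @export
arcSpec <- function(radiusMm = NULL, curvaturePerMm = NULL, thetaStart = 0,
                    nPoints = 25L) {
  if (is.null(radiusMm) == is.null(curvaturePerMm))
    stop("give exactly one of 'radiusMm' and 'curvaturePerMm'")
  if (is.null(radiusMm)) {
    if (curvaturePerMm <= 0) stop("curvature must be positive")
    radiusMm <- 1 / curvaturePerMm
  } else {
    curvaturePerMm <- 1 / radiusMm
  }
  new("ArcSpec", radiusMm = radiusMm, curvaturePerMm = curvaturePerMm,
      thetaStart = thetaStart, nPoints = as.integer(nPoints))
}

setMethod("show", "ArcSpec", function(object) {
  cat("ArcSpec: curvature ", format(object@curvaturePerMm, digits = 5),
      " /mm, thetaStart ", format(object@thetaStart, digits = 4),
      " rad, sweep ", format(pi / (2 * object@radiusMm), digits = 4),
      " rad\n", sep = "")
})

#' EllipseSpec: parameters of one simulated cross-section
#'
#' @slot maxDiameterUm major-axis length 2a, in micrometres.
#' @slot minDiameterUm minor-axis length 2b, in micrometres.
#' @slot eccentricity \code{sqrt(1 - (b/a)^2)}, in \code{[0, 1)}.
#' @slot rotationDeg major-axis orientation in degrees, \code{[0, 360)}.
#' @export
setClass("EllipseSpec",
  representation(maxDiameterUm = "numeric", minDiameterUm = "numeric",
                 eccentricity = "numeric", rotationDeg = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@minDiameterUm > object@maxDiameterUm + 1e-9)
      msg <- c(msg, "minimum diameter must not exceed maximum diameter")
    if (object@eccentricity < 0 || object@eccentricity >= 1)
      msg <- c(msg, "'eccentricity' must lie in [0, 1)")
    ratio <- object@minDiameterUm / object@maxDiameterUm
    if (abs(object@eccentricity - sqrt(max(0, 1 - ratio^2))) > 1e-6)
      msg <- c(msg, "'eccentricity' inconsistent with diameter ratio")
    if (object@rotationDeg < 0 || object@rotationDeg >= 360)
      msg <- c(msg, "'rotationDeg' must lie in [0, 360)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an EllipseSpec
#'
#' The minor diameter is derived from the major diameter and the
#' eccentricity: \code{2b = 2a * sqrt(1 - e^2)}.
#'
#' @param maxDiameterUm major-axis length (2a) in micrometres.
#' @param eccentricity in \code{[0, 1)}; 0 gives a circle.
#' @param rotationDeg orientation of the major axis in degrees.
#' @return An [EllipseSpec-class] object.
#' @examples
#' ellipseSpec(100, eccentricity = 0.8)  # minor diameter 60 um
#' @export
ellipseSpec <- function(maxDiameterUm, eccentricity = 0, rotationDeg = 0) {
  minD <- maxDiameterUm * sqrt(1 - eccentricity^2)
  new("EllipseSpec", maxDiameterUm = as.numeric(maxDiameterUm),
      minDiameterUm = minD, eccentricity = as.numeric(eccentricity),
      rotationDeg = as.numeric(rotationDeg %% 360))
}

setMethod("show", "EllipseSpec", function(object) {
  cat("EllipseSpec: 2a = ", format(object@maxDiameterUm, digits = 5),
      " um, 2b = ", format(object@minDiameterUm, digits = 5),
      " um, e = ", format(object@eccentricity, digits = 4),
      ", rotation ", format(object@rotationDeg, digits = 4), " deg\n",
      sep = "")
})
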
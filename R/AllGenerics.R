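#' Accessors for calibrated images and derived objects
#'
#' @param x a [CalibratedImage-class], [FragmentTrace-class],
#'   [CircleFit-class] or [SectionMask-class] object.
#' @return \code{pixels} returns the intensity matrix; \code{resolution}
#'   the calibration in px per unit; \code{resolutionUnit} the unit tag
#'   (\code{"mm"} or \code{"um"}); \code{tracePath} the (row, col) pixel
#'   path of a trace; \code{maskPixels} the logical mask of a segmented
#'   section.
#' @name accessors
#' @examples
#' img <- CalibratedImage(matrix(0.5, 10, 10), 132, "mm")
#' resolution(img)
#' resolutionUnit(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setMethod("resolution", "CalibratedImage", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("resolutionUnit", function(x) standardGeneric("resolutionUnit"))
#' @rdname accessors
#' @export
setMethod("resolutionUnit", "CalibratedImage", function(x) x@unit)

#' @rdname accessors
#' @export
setGeneric("tracePath", function(x) standardGeneric("tracePath"))
#' @rdname accessors
#' @export
setMethod("tracePath", "FragmentTrace", function(x) x@path)

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setMethod("maskPixels", "SectionMask", function(x) x@mask)
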
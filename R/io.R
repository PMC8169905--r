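#' Read a grayscale TIFF as a calibrated image
#'
#' Reads an 8- or 16-bit TIFF into a [CalibratedImage-class]. RGB images
#' are converted to grayscale by Rec. 709 luminance with a warning;
#' microscope calibration cannot be trusted from TIFF tags, so the spatial
#' resolution must be supplied by the caller.
#'
#' @param path path to a TIFF file.
#' @param resolution pixels per unit length.
#' @param unit \code{"mm"} (longitudinal images) or \code{"um"} (sections).
#' @return A [CalibratedImage-class].
#' @examples
#' sim <- simulateArcImage(1, nFragments = 3, canvas = c(600, 450),
#'                         seed = 1)
#' tf <- tempfile(fileext = ".tiff")
#' writeGrayscaleTIFF(sim$image, tf)
#' img <- readGrayscaleTIFF(tf, resolution = 132, unit = "mm")
#' @export
readGrayscaleTIFF <- function(path, resolution, unit = c("mm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop("TIFF file not found: ", path, call. = FALSE)
  px <- tryCatch(tiff::readTIFF(path),
                 error = function(e)
                   stop("unreadable TIFF '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    if (nch >= 3L) {
      warning("RGB TIFF '", basename(path),
              "' converted to grayscale by luminance")
      px <- 0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
    } else {
      px <- px[, , 1L]
    }
  }
  CalibratedImage(px, resolution, unit)
}

#' Write a calibrated image as an 8-bit grayscale TIFF
#'
#' @param image a [CalibratedImage-class].
#' @param path output path.
#' @param compression passed to [tiff::writeTIFF()]; LZW keeps the large
#'   simulated canvases small on disk.
#' @return The path, invisibly.
#' @export
writeGrayscaleTIFF <- function(image, path, compression = "LZW") {
  stopifnot(is(image, "CalibratedImage"))
  tiff::writeTIFF(pixels(image), path, bits.per.sample = 8L,
                  compression = compression)
  invisible(path)
}

# Schema-checked CSV writer: refuses to write anything if the record
# columns do not match the declared schema.
#' @noRd
.writeCsv <- function(records, schema, path) {
  if (!identical(names(records), schema))
    stop("record columns (", paste(names(records), collapse = ", "),
         ") do not match schema (", paste(schema, collapse = ", "), ")",
         call. = FALSE)
  write.csv(records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @noRd
.listTiffs <- function(dir) {
  sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                  full.names = TRUE))
}

#' @noRd
.imageId <- function(path) sub("\\.tiff?$", "", basename(path),
                               ignore.case = TRUE)
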
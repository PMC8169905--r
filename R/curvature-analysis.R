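# Longitudinal pipeline: ridge filter -> binarize/clean -> skeletonize ->
# split into single-fragment traces -> Taubin circle fit per fragment.

#' Enhance dark curvilinear structures
#'
#' Hessian-based ridge filter: at each scale the image is convolved with
#' Gaussian second-derivative kernels and the largest Hessian eigenvalue
#' (positive across a dark ridge on a light ground) is retained,
#' scale-normalized by sigma^2; the response is the maximum over scales.
#'
#' @param image a [CalibratedImage-class] or a numeric matrix in
#'   \code{[0, 1]}.
#' @param scales Gaussian scales (sigma, px) matched to the expected
#'   stroke half-width; the default covers hair widths of roughly 4-9 px.
#' @return Numeric response matrix, same dimensions as the input, zero
#'   away from ridges.
#' @export
ridgeEnhance <- function(image, scales = c(2, 3)) {
  px <- if (is(image, "CalibratedImage")) pixels(image) else image
  if (!is.matrix(px))
    stop("'image' must be a single-channel (2-D) grayscale image")
  .ridge_response_cpp(px, as.numeric(scales))
}

#' Binarize a ridge response and remove specks
#'
#' Thresholds the response with Otsu's method, removes connected
#' components below a minimum area, and fills holes. An empty result is
#' returned with a warning (the image then yields a hair count of 0), not
#' an error, so batch runs continue.
#'
#' @param response ridge-response matrix from [ridgeEnhance()].
#' @param minArea smallest component area (px) kept; rejects dust specks.
#' @return Logical foreground mask.
#' @export
binarizeAndClean <- function(response, minArea = 30L) {
  if (max(response) <= 0) {
    warning("empty foreground: no ridge response above zero")
    return(matrix(FALSE, nrow(response), ncol(response)))
  }
  r01 <- response / max(response)
  th <- EBImage::otsu(EBImage::Image(r01))
  mask <- r01 > th
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea)
  if (!length(keep)) {
    warning("empty foreground after speck removal")
    return(matrix(FALSE, nrow(response), ncol(response)))
  }
  mask <- matrix(lab %in% keep, nrow(response), ncol(response))
  mask <- EBImage::fillHull(mask) > 0
  mask
}

# Neighbour offsets, axial first so path tracing prefers 4-neighbour steps.
.NB <- cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
             dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))

#' @noRd
.skelDegrees <- function(skel, pix) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- integer(nrow(pix))
  for (k in seq_len(8L)) {
    i <- pix[, 1L] + .NB[k, 1L]
    j <- pix[, 2L] + .NB[k, 2L]
    ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
    hit <- logical(nrow(pix))
    hit[ok] <- skel[cbind(i[ok], j[ok])]
    deg <- deg + hit
  }
  deg
}

#' @noRd
.neighboursOf <- function(skel, i, j) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix(0L, 0L, 2L)
  for (k in seq_len(8L)) {
    ii <- i + .NB[k, 1L]; jj <- j + .NB[k, 2L]
    if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && skel[ii, jj])
      out <- rbind(out, c(ii, jj))
  }
  out
}

# Remove short spurs: walk inward from each skeleton tip; if a branch point
# is reached within 'spurLengthPx' steps the walked pixels are deleted.
#' @noRd
.pruneSpurs <- function(skel, spurLengthPx) {
  repeat {
    pix <- which(skel, arr.ind = TRUE)
    if (!nrow(pix)) return(skel)
    deg <- .skelDegrees(skel, pix)
    isBranch <- matrix(FALSE, nrow(skel), ncol(skel))
    isBranch[pix[deg >= 3L, , drop = FALSE]] <- TRUE
    tips <- pix[deg == 1L, , drop = FALSE]
    removed <- FALSE
    for (t in seq_len(nrow(tips))) {
      cur <- tips[t, ]
      if (!skel[cur[1L], cur[2L]]) next
      walk <- matrix(cur, 1L, 2L)
      prev <- c(0L, 0L)
      hitBranch <- FALSE
      while (nrow(walk) <= spurLengthPx) {
        nbs <- .neighboursOf(skel, cur[1L], cur[2L])
        nbs <- nbs[!(nbs[, 1L] == prev[1L] & nbs[, 2L] == prev[2L]), ,
                   drop = FALSE]
        if (!nrow(nbs)) break
        nxt <- nbs[1L, ]
        if (isBranch[nxt[1L], nxt[2L]]) { hitBranch <- TRUE; break }
        prev <- cur; cur <- nxt
        walk <- rbind(walk, cur)
      }
      if (hitBranch) {
        skel[walk] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(skel)
  }
}

#' Skeletonize a cleaned mask and split it into fragment traces
#'
#' Thins the mask to one-pixel width (Zhang-Suen), prunes short spurs,
#' deletes branch points so that crossing or touching fragments are split
#' into simple branches, and traces each remaining path in order. Traces
#' shorter than \code{minLengthPx} pixels are dropped.
#'
#' @param mask logical foreground mask from [binarizeAndClean()].
#' @param minLengthPx minimum trace length in pixels (default 16, about
#'   0.12 mm at 132 px/mm).
#' @param spurLengthPx longest skeleton spur removed during pruning.
#' @return List of [FragmentTrace-class] objects (possibly empty).
#' @export
skeletonizeAndSplit <- function(mask, minLengthPx = 16L,
                                spurLengthPx = 10L) {
  if (!any(mask)) return(list())
  skel <- .thin_cpp(mask)
  skel <- .pruneSpurs(skel, spurLengthPx)
  pix <- which(skel, arr.ind = TRUE)
  if (!nrow(pix)) return(list())
  deg <- .skelDegrees(skel, pix)
  # split at branch points
  skel[pix[deg >= 3L, , drop = FALSE]] <- FALSE
  pix <- which(skel, arr.ind = TRUE)
  if (!nrow(pix)) return(list())
  deg <- .skelDegrees(skel, pix)
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  traces <- list()
  trace_from <- function(start) {
    cur <- start
    path <- matrix(cur, 1L, 2L)
    visited[cur[1L], cur[2L]] <<- TRUE
    repeat {
      nbs <- .neighboursOf(skel, cur[1L], cur[2L])
      nbs <- nbs[!visited[nbs], , drop = FALSE]
      if (!nrow(nbs)) break
      cur <- nbs[1L, ]
      visited[cur[1L], cur[2L]] <<- TRUE
      path <- rbind(path, cur)
    }
    path
  }
  # open paths first (start from tips), then any leftover cycles
  tipOrder <- order(deg != 1L)
  for (k in tipOrder) {
    start <- pix[k, ]
    if (visited[start[1L], start[2L]]) next
    path <- trace_from(start)
    if (nrow(path) >= minLengthPx)
      traces[[length(traces) + 1L]] <- FragmentTrace(path)
  }
  traces
}

#' Corrected path length of a fragment trace
#'
#' Chain-code length of the skeleton path with the classical digitized-
#' curve correction (Kulpa): diagonal steps are weighted \code{sqrt(2)}
#' relative to axial steps and the total is scaled by
#' \code{pi/8 * (1 + sqrt(2))} (about 0.948), which removes the
#' systematic overestimation of smooth curves sampled on a square grid
#' at arbitrary orientation. Without the scale factor a digitized
#' straight line at 22.5 degrees would read about 8 percent too long.
#'
#' @param trace a [FragmentTrace-class].
#' @param resolutionPpmm pixels per mm.
#' @return Length in mm (0 for a single-pixel trace).
#' @examples
#' tr <- FragmentTrace(cbind(1, 1:10))  # horizontal run of 10 px
#' fragmentLength(tr, 132)              # 9 * 0.948 / 132 mm
#' @export
fragmentLength <- function(trace, resolutionPpmm) {
  stopifnot(is(trace, "FragmentTrace"))
  kulpa <- pi / 8 * (1 + sqrt(2))
  kulpa * (trace@nAxial + sqrt(2) * trace@nDiagonal) / resolutionPpmm
}

#' Taubin algebraic circle fit
#'
#' Fits a circle by minimizing the Taubin-normalized algebraic distance
#' (Newton iteration on the characteristic polynomial). Near-unbiased for
#' short arcs, which is what makes curvature estimation on low-curvature
#' fragments work. Numerically collinear input is returned as a degenerate
#' fit (straight hair, curvature 0), not an error.
#'
#' @param points numeric matrix with columns (x, y), at least 3 rows.
#' @return A [CircleFit-class].
#' @examples
#' fitCircleTaubin(cbind(c(0, 1, 0), c(1, 0, -1)))  # unit circumcircle
#' @export
fitCircleTaubin <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("circle fitting needs at least 3 points")
  mx <- mean(points[, 1L]); my <- mean(points[, 2L])
  x <- points[, 1L] - mx; y <- points[, 2L] - my
  # collinearity: smallest eigenvalue of the point covariance
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 / 4 + sxy^2))
  lmin <- tr / 2 - disc; lmax <- tr / 2 + disc
  if (lmax <= 0 || lmin / lmax < 1e-9)
    return(new("CircleFit", center = c(NA_real_, NA_real_),
               radiusPx = Inf, residual = sqrt(max(0, lmin)),
               degenerate = TRUE))
  z <- x * x + y * y
  Mxx <- sxx; Myy <- syy; Mxy <- sxy
  Mxz <- mean(x * z); Myz <- mean(y * z); Mzz <- mean(z * z)
  Mz <- Mxx + Myy
  CovXY <- Mxx * Myy - Mxy^2
  VarZ <- Mzz - Mz^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- VarZ * Mz + 4 * CovXY * Mz - Mxz^2 - Myz^2
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Mzz * CovXY - 2 * Mxz * Myz * Mxy +
    Mz^2 * CovXY
  A22 <- 2 * A2; A33 <- 3 * A3
  xr <- 0
  for (iter in seq_len(99L)) {
    fy <- A0 + xr * (A1 + xr * (A2 + xr * A3))
    dy <- A1 + xr * (A22 + xr * A33)
    if (!is.finite(fy) || !is.finite(dy) || dy == 0) break
    xnew <- xr - fy / dy
    if (!is.finite(xnew) || abs(xnew - xr) < 1e-14 * (abs(xr) + 1)) {
      xr <- xnew
      break
    }
    xr <- xnew
  }
  DET <- xr^2 - xr * Mz + CovXY
  if (!is.finite(DET) || abs(DET) < 1e-30)
    return(new("CircleFit", center = c(NA_real_, NA_real_),
               radiusPx = Inf, residual = NA_real_, degenerate = TRUE))
  cx <- (Mxz * (Myy - xr) - Myz * Mxy) / DET / 2
  cy <- (Myz * (Mxx - xr) - Mxz * Mxy) / DET / 2
  r <- sqrt(cx^2 + cy^2 + Mz + 2 * xr)
  resid <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
  new("CircleFit", center = c(cx + mx, cy + my), radiusPx = r,
      residual = resid, degenerate = FALSE)
}

#' Curvature from a circle fit
#'
#' Curvature is the reciprocal of the fitted radius expressed in mm:
#' \code{resolution / radiusPx}. Degenerate (straight) fragments report 0,
#' the low end of the phenotype scale.
#'
#' @param fit a [CircleFit-class].
#' @param resolutionPpmm pixels per mm.
#' @return Curvature in 1/mm.
#' @export
fragmentCurvature <- function(fit, resolutionPpmm) {
  stopifnot(is(fit, "CircleFit"))
  if (fit@degenerate) return(0)
  resolutionPpmm / fit@radiusPx
}

#' Measure fragment curvature and length in one image
#'
#' Full longitudinal pipeline for a single calibrated image: polarity
#' check (hairs are assumed dark on light ground; a predominantly dark
#' image is inverted), ridge enhancement, binarization and cleaning,
#' skeletonization and splitting, then a Taubin circle fit and corrected
#' length per fragment.
#'
#' @param image a [CalibratedImage-class] calibrated in px/mm.
#' @param imageId identifier used in the summary row.
#' @param scales,minArea,minLengthPx,spurLengthPx pipeline parameters; see
#'   [ridgeEnhance()], [binarizeAndClean()], [skeletonizeAndSplit()].
#' @return List with \code{summary} (one-row data frame: image_id,
#'   hair_count, mean/median curvature, mean/median length) and
#'   \code{fragments} (per-fragment data frame: element_id,
#'   curvature_per_mm, length_mm).
#' @examples
#' sim <- simulateArcImage(1, nFragments = 4, canvas = c(1100, 900),
#'                         seed = 2)
#' analyzeCurvatureImage(sim$image, imageId = "demo")$summary
#' @export
analyzeCurvatureImage <- function(image, imageId = "image",
                                  scales = c(2, 3), minArea = 30L,
                                  minLengthPx = 16L, spurLengthPx = 10L) {
  stopifnot(is(image, "CalibratedImage"))
  if (resolutionUnit(image) != "mm")
    stop("curvature analysis expects an image calibrated in px/mm")
  px <- pixels(image)
  if (mean(px) < 0.5) {
    message("image '", imageId,
            "' is predominantly dark; inverting so hairs are dark on light")
    px <- 1 - px
  }
  resp <- ridgeEnhance(px, scales = scales)
  mask <- binarizeAndClean(resp, minArea = minArea)
  traces <- skeletonizeAndSplit(mask, minLengthPx = minLengthPx,
                                spurLengthPx = spurLengthPx)
  res <- resolution(image)
  n <- length(traces)
  # Circle fit: when an element carries a single trace, fit on all of the
  # element's pixels (both stroke edges constrain the centre line, and
  # quantization noise averages out); when a component was split into
  # several traces (crossing hairs), fit each trace's own skeleton path.
  lab <- EBImage::bwlabel(mask)
  compOf <- vapply(traces, function(t) {
    p <- tracePath(t)[1L, ]
    as.integer(lab[p[1L], p[2L]])
  }, integer(1L))
  curv <- numeric(n); len <- numeric(n)
  for (k in seq_len(n)) {
    p <- tracePath(traces[[k]])
    pts <- if (compOf[k] > 0L && sum(compOf == compOf[k]) == 1L) {
      idx <- which(lab == compOf[k], arr.ind = TRUE)
      cbind(idx[, 2L], idx[, 1L])        # (x, y) = (col, row)
    } else {
      cbind(p[, 2L], p[, 1L])
    }
    fit <- fitCircleTaubin(pts)
    curv[k] <- fragmentCurvature(fit, res)
    len[k] <- fragmentLength(traces[[k]], res)
  }
  summary <- data.frame(
    image_id = imageId,
    hair_count = n,
    mean_curvature_per_mm = if (n) mean(curv) else NA_real_,
    median_curvature_per_mm = if (n) median(curv) else NA_real_,
    mean_length_mm = if (n) mean(len) else NA_real_,
    median_length_mm = if (n) median(len) else NA_real_)
  fragments <- data.frame(element_id = seq_len(n), curvature_per_mm = curv,
                          length_mm = len)
  list(summary = summary, fragments = fragments)
}

#' Batch curvature analysis over a directory of TIFFs
#'
#' Processes every \code{.tiff}/\code{.tif} in \code{inputDir} in filename
#' order. Unreadable files are logged and skipped; they never abort the
#' batch. Rerunning on the same inputs produces an identical summary.
#'
#' @param inputDir directory of grayscale TIFFs.
#' @param resolutionPpmm pixels per mm (camera calibration; required).
#' @param outputDir if non-\code{NULL}, \code{summary_curvature.csv} (and,
#'   with \code{saveRaw}, one \code{<image_id>_fragments.csv} per image)
#'   is written there.
#' @param saveRaw also write per-fragment tables.
#' @param ... passed to [analyzeCurvatureImage()].
#' @return The summary data frame, one row per readable image.
#' @export
analyzeCurvatureDir <- function(inputDir, resolutionPpmm,
                                outputDir = NULL, saveRaw = FALSE, ...) {
  files <- .listTiffs(inputDir)
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  rows <- list(); frags <- list()
  for (f in files) {
    id <- .imageId(f)
    out <- tryCatch({
      img <- readGrayscaleTIFF(f, resolution = resolutionPpmm, unit = "mm")
      analyzeCurvatureImage(img, imageId = id, ...)
    }, error = function(e) {
      message("skipping '", basename(f), "': ", conditionMessage(e))
      NULL
    })
    if (is.null(out)) next
    rows[[id]] <- out$summary
    frags[[id]] <- out$fragments
  }
  schema <- c("image_id", "hair_count", "mean_curvature_per_mm",
              "median_curvature_per_mm", "mean_length_mm",
              "median_length_mm")
  summary <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(schema)),
                           schema))
  rownames(summary) <- NULL
  if (!is.null(outputDir)) {
    .writeCsv(summary, schema, file.path(outputDir,
                                         "summary_curvature.csv"))
    if (saveRaw) {
      for (id in names(frags))
        .writeCsv(frags[[id]],
                  c("element_id", "curvature_per_mm", "length_mm"),
                  file.path(outputDir, paste0(id, "_fragments.csv")))
    }
  }
  summary
}
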
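# Accuracy metrics comparing pipeline estimates against simulated truth.

#' Root mean squared error
#'
#' \code{sqrt(mean((est - truth)^2))}, in the units of the variable.
#'
#' @param estimates,truths numeric vectors of equal length.
#' @return Non-negative scalar.
#' @examples
#' rmse(c(1, 2, 4), c(1, 2, 3))  # sqrt(1/3)
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("'estimates' and 'truths' must have equal length")
  if (!length(estimates)) stop("empty input")
  sqrt(mean((estimates - truths)^2))
}

#' Mean percent error
#'
#' Default (\code{mode = "mean_relative"}): mean of
#' \code{|est - truth| / truth * 100} over elements; elements with zero
#' truth are excluded with a warning. The alternative mode normalizes the
#' RMSE by the mean truth, \code{rmse / mean(truth) * 100}, for
#' sensitivity checks against reports whose denominator is unstated.
#'
#' @param estimates,truths numeric vectors of equal length.
#' @param mode \code{"mean_relative"} or \code{"rmse_over_mean"}.
#' @return Percent error (scalar, in percent units).
#' @export
percentError <- function(estimates, truths,
                         mode = c("mean_relative", "rmse_over_mean")) {
  mode <- match.arg(mode)
  if (length(estimates) != length(truths))
    stop("'estimates' and 'truths' must have equal length")
  if (mode == "rmse_over_mean")
    return(rmse(estimates, truths) / mean(truths) * 100)
  zero <- truths == 0
  if (any(zero)) {
    warning(sum(zero), " element(s) with zero truth excluded from ",
            "relative error")
    estimates <- estimates[!zero]; truths <- truths[!zero]
  }
  if (!length(truths)) stop("no nonzero truths for relative error")
  mean(abs(estimates - truths) / truths) * 100
}

#' Squared Pearson correlation
#'
#' @param estimates,truths numeric vectors (n >= 2) with nonzero variance.
#' @return r-squared in \code{[0, 1]}; invariant to affine transforms of
#'   either argument.
#' @export
rSquared <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("'estimates' and 'truths' must have equal length")
  if (length(estimates) < 2L) stop("r-squared needs at least 2 points")
  if (var(estimates) == 0 || var(truths) == 0)
    stop("r-squared undefined: zero variance")
  stats::cor(estimates, truths)^2
}

#' @noRd
.loadTable <- function(x) {
  if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
}

#' @noRd
.validatePair <- function(est, truth, estCols, truthCols, labels) {
  est <- .loadTable(est); truth <- .loadTable(truth)
  missing <- setdiff(truth$image_id, est$image_id)
  extra <- setdiff(est$image_id, truth$image_id)
  if (length(missing) || length(extra))
    stop("unmatched image ids: ",
         paste(c(missing, extra), collapse = ", "))
  m <- merge(est, truth, by = "image_id")
  out <- lapply(seq_along(labels), function(k) {
    e <- m[[estCols[k]]]; t <- m[[truthCols[k]]]
    n <- length(e)
    r2 <- if (n >= 2L && var(e) > 0 && var(t) > 0) rSquared(e, t)
      else NA_real_
    data.frame(metric = labels[k], rmse = rmse(e, t),
               percent_error = percentError(e, t), r_squared = r2,
               n = n)
  })
  do.call(rbind, out)
}

#' Validate curvature estimates against simulated truth
#'
#' Joins the per-image summary (estimated mean curvature and mean length)
#' to the generator's truth table by \code{image_id} and reports RMSE,
#' mean percent error and r-squared for curvature and length.
#'
#' @param estimates summary data frame from [analyzeCurvatureDir()], or a
#'   path to \code{summary_curvature.csv}.
#' @param truth truth data frame from [generateArcDataset()], or a path
#'   to \code{arc_truth.csv}.
#' @return Data frame with rows \code{curvature} and \code{length} and
#'   columns metric, rmse, percent_error, r_squared, n. \code{r_squared}
#'   is \code{NA} when fewer than two images (or zero variance) make it
#'   undefined.
#' @export
validateCurvature <- function(estimates, truth) {
  .validatePair(estimates, truth,
                estCols = c("mean_curvature_per_mm", "mean_length_mm"),
                truthCols = c("curvature_per_mm", "length_mm"),
                labels = c("curvature", "length"))
}

#' Validate cross-section estimates against simulated truth
#'
#' @param estimates summary data frame from [analyzeSectionDir()], or a
#'   path to \code{summary_section.csv}.
#' @param truth truth data frame from [generateEllipseDataset()], or a
#'   path to \code{ellipse_truth.csv}.
#' @return Data frame with rows \code{area} and \code{eccentricity}; see
#'   [validateCurvature()].
#' @export
validateSection <- function(estimates, truth) {
  est <- .loadTable(estimates)
  .validatePair(est, truth,
                estCols = c("area_um2.x", "eccentricity.x"),
                truthCols = c("area_um2.y", "eccentricity.y"),
                labels = c("area", "eccentricity"))
}
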
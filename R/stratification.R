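# Synthetic admixed cohorts and the regression machinery used to show
# that ancestry stratification induces trait-trait correlations which
# vanish once ancestry enters the model as a covariate.

#' Simulate an admixed cohort with ancestry-driven traits
#'
#' Each individual carries an African ancestry proportion drawn from a
#' two-component Beta mixture spanning \code{[0, 1]} (the shape of an
#' admixed sample), and three phenotypes - melanin index, hair curvature
#' and cross-sectional eccentricity - that are monotone functions of
#' ancestry plus heteroscedastic noise whose standard deviation grows
#' linearly with ancestry (trait variance increases with African
#' ancestry). There is no direct trait-trait coupling unless
#' \code{directEffect} is set, in which case eccentricity enters the
#' curvature model with that slope.
#'
#' @param n cohort size (default 140, the demonstration sample size).
#' @param effects list of \code{c(intercept, ancestry_slope)} per trait;
#'   defaults: melanin \code{c(30, 45)} (reflectance units), curvature
#'   \code{c(0.2, 1.3)} (1/mm), eccentricity \code{c(0.55, 0.2)}.
#' @param noise list of \code{c(c0, c1)} per trait: noise SD is
#'   \code{c0 + c1 * ancestry}; defaults melanin \code{c(1, 2.5)},
#'   curvature \code{c(0.05, 0.2)}, eccentricity \code{c(0.05, 0.1)}.
#' @param directEffect slope of a true eccentricity -> curvature effect
#'   (default 0: any marginal association is pure stratification).
#' @param ancestryShapes Beta shape pairs of the two mixture components.
#' @param seed optional integer seed; the same seed reproduces the cohort.
#' @return Data frame with columns ancestry, melanin_index,
#'   curvature_per_mm, eccentricity.
#' @examples
#' coh <- synthCohort(140, seed = 1)
#' cor(coh$curvature_per_mm, coh$eccentricity)  # confounded, positive
#' @export
synthCohort <- function(n = 140L,
                        effects = list(melanin = c(30, 45),
                                       curvature = c(0.2, 1.3),
                                       eccentricity = c(0.55, 0.2)),
                        noise = list(melanin = c(1, 2.5),
                                     curvature = c(0.05, 0.2),
                                     eccentricity = c(0.05, 0.1)),
                        directEffect = 0, ancestryShapes = list(c(2, 5),
                                                                c(5, 2)),
                        seed = NULL) {
  if (n < 10L) stop("'n' must be at least 10")
  need <- c("melanin", "curvature", "eccentricity")
  if (!all(need %in% names(effects)) || !all(need %in% names(noise)))
    stop("'effects' and 'noise' must name melanin, curvature and ",
         "eccentricity")
  if (!all(vapply(c(effects[need], noise[need]), length, 1L) == 2L))
    stop("each effects/noise entry must be c(intercept, slope) / c(c0, c1)")
  .withSeed(seed, {
    comp <- sample.int(2L, n, replace = TRUE)
    anc <- numeric(n)
    for (k in 1:2) {
      sel <- comp == k
      anc[sel] <- rbeta(sum(sel), ancestryShapes[[k]][1L],
                        ancestryShapes[[k]][2L])
    }
    sdOf <- function(cc) cc[1L] + cc[2L] * anc
    mel <- effects$melanin[1L] + effects$melanin[2L] * anc +
      rnorm(n, 0, sdOf(noise$melanin))
    ecc <- effects$eccentricity[1L] + effects$eccentricity[2L] * anc +
      rnorm(n, 0, sdOf(noise$eccentricity))
    ecc <- pmin(pmax(ecc, 0), 1 - 1e-6)
    curv <- effects$curvature[1L] + effects$curvature[2L] * anc +
      directEffect * ecc + rnorm(n, 0, sdOf(noise$curvature))
    curv <- pmax(curv, 0)
    data.frame(ancestry = anc, melanin_index = mel,
               curvature_per_mm = curv, eccentricity = ecc)
  })
}

#' Fit a (weighted) trait regression
#'
#' Ordinary least squares of \code{y} on \code{x} - linear or quadratic
#' (\code{y = a + b0 x + b1 x^2}) - optionally with an ancestry covariate
#' \code{z} (\code{y = a + b0 x + b1 z}). With \code{weighted = TRUE} the
#' model is refit with weights \code{1 / yhat^2}, where \code{yhat} are
#' the fitted values of the unweighted pass; this downweights the
#' high-ancestry end where trait variance is larger. With equal weights
#' the weighted fit coincides with OLS.
#'
#' @param y,x response and predictor vectors.
#' @param z optional covariate (ancestry proportion).
#' @param form \code{"linear"} or \code{"quadratic"} in \code{x}.
#' @param weighted refit with \code{1/yhat^2} weights.
#' @return List of class \code{"hairmorphFit"}: \code{coefficients}
#'   (estimate, std.error, p.value), \code{residuals}, \code{weights}
#'   (\code{NULL} if unweighted), \code{weighted}, and the underlying
#'   \code{lm} fit.
#' @examples
#' coh <- synthCohort(140, seed = 3)
#' fitTraitModel(coh$curvature_per_mm, coh$eccentricity,
#'               z = coh$ancestry)$coefficients
#' @export
fitTraitModel <- function(y, x, z = NULL,
                          form = c("linear", "quadratic"),
                          weighted = FALSE) {
  form <- match.arg(form)
  df <- data.frame(y = y, x = x)
  fml <- if (form == "quadratic") y ~ x + I(x^2) else y ~ x
  if (!is.null(z)) {
    if (form == "quadratic")
      stop("the quadratic form is used without a covariate")
    df$z <- z
    fml <- y ~ x + z
  }
  npar <- if (form == "quadratic" || !is.null(z)) 3L else 2L
  if (nrow(df) <= npar)
    stop("need more observations than parameters")
  fit0 <- lm(fml, data = df)
  if (qr(fit0)$rank < npar) stop("singular design matrix")
  fit <- fit0
  w <- NULL
  if (weighted) {
    yhat <- fitted(fit0)
    if (any(yhat == 0))
      stop("cannot form 1/yhat^2 weights: zero fitted value")
    df$.w <- 1 / yhat^2
    fit <- lm(fml, data = df, weights = .w)
    w <- df$.w
  }
  sm <- summary(fit)$coefficients
  structure(list(coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1L],
                                           std.error = sm[, 2L],
                                           p.value = sm[, 4L],
                                           row.names = NULL),
                 residuals = resid(fit), weights = w,
                 weighted = weighted, fit = fit),
            class = "hairmorphFit")
}

#' @export
print.hairmorphFit <- function(x, ...) {
  cat("Trait regression (", if (x$weighted) "weighted, 1/yhat^2"
      else "OLS", "):\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Ancestry-corrected trait-trait association
#'
#' Regresses each trait on ancestry, then regresses the residuals of one
#' on the residuals of the other. Under pure stratification (no direct
#' coupling) the residual-on-residual slope is null; a real trait-trait
#' effect survives the correction.
#'
#' Trait variance grows with ancestry, so the residual regression is
#' weighted by \code{1 / yhatA^2} (fitted values of the unweighted
#' traitA-on-ancestry pass, the same weighting used by [fitTraitModel()])
#' and the slope is tested with heteroscedasticity-consistent (HC3)
#' standard errors; plain OLS inference here is anti-conservative under
#' ancestry-dependent variance. Set \code{weighted = FALSE} for the
#' unweighted fit (HC3 inference is kept either way).
#'
#' @param traitA,traitB trait vectors.
#' @param ancestry ancestry proportions, same length.
#' @param weighted use \code{1/yhatA^2} weights in the residual
#'   regression (default \code{TRUE}).
#' @return List: residualsA, residualsB, slope, p.
#' @examples
#' coh <- synthCohort(140, seed = 5)
#' out <- ancestryCorrectedAssociation(coh$curvature_per_mm,
#'                                     coh$eccentricity, coh$ancestry)
#' out$p  # typically not significant: the marginal link was confounding
#' @export
ancestryCorrectedAssociation <- function(traitA, traitB, ancestry,
                                         weighted = TRUE) {
  n <- length(ancestry)
  if (length(traitA) != n || length(traitB) != n)
    stop("inputs must have equal length")
  fitA <- lm(traitA ~ ancestry)
  rA <- resid(fitA)
  rB <- resid(lm(traitB ~ ancestry))
  df <- data.frame(rA = unname(rA), rB = unname(rB))
  if (weighted) {
    yhat <- fitted(fitA)
    if (any(yhat == 0))
      stop("cannot form 1/yhat^2 weights: zero fitted value")
    df$.w <- 1 / yhat^2
    fit <- lm(rA ~ rB, data = df, weights = .w)
  } else {
    fit <- lm(rA ~ rB, data = df)
  }
  ct <- lmtest::coeftest(fit, vcov = sandwich::vcovHC(fit, type = "HC3"))
  list(residualsA = df$rA, residualsB = df$rB,
       slope = unname(ct["rB", 1L]), p = unname(ct["rB", 4L]))
}

#' Bin continuous curvature into ordinal classes
#'
#' Assigns each curvature the half-open interval \code{[t_k, t_{k+1})} it
#' falls in, for user-supplied thresholds (e.g. the published curve-type
#' cut-offs); a value equal to a threshold joins the upper bin. With no
#' thresholds all values share one bin.
#'
#' @param curvatures numeric vector, 1/mm.
#' @param thresholds strictly increasing numeric vector of cut points.
#' @return Ordered factor with levels \code{1 .. length(thresholds) + 1}.
#' @examples
#' binCurvature(c(0.2, 0.7, 1.5), c(0.5, 1.0))  # bins 1, 2, 3
#' @export
binCurvature <- function(curvatures, thresholds = numeric(0)) {
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("'thresholds' must be strictly increasing")
  bins <- findInterval(curvatures, thresholds) + 1L
  factor(bins, levels = seq_len(length(thresholds) + 1L), ordered = TRUE)
}

#' Monte Carlo summary of the stratification demonstration
#'
#' Repeats [synthCohort()] plus both analyses across seeds and reports
#' the fraction of cohorts in which (i) the marginal
#' curvature-eccentricity association is significant and (ii) the
#' ancestry-corrected association is significant, at the given alpha.
#'
#' @param nSeeds number of replicate cohorts (default 100).
#' @param n cohort size per replicate.
#' @param directEffect true eccentricity -> curvature slope (0 for the
#'   pure-stratification demonstration).
#' @param alpha two-sided significance threshold (default 0.05).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return List: marginal_significant, adjusted_significant (fractions in
#'   \code{[0, 1]}), nSeeds.
#' @export
stratificationDemo <- function(nSeeds = 100L, n = 140L, directEffect = 0,
                               alpha = 0.05, seed = 1L) {
  marg <- logical(nSeeds); adj <- logical(nSeeds)
  for (r in seq_len(nSeeds)) {
    coh <- synthCohort(n, directEffect = directEffect, seed = seed + r)
    mfit <- fitTraitModel(coh$curvature_per_mm, coh$eccentricity)
    marg[r] <- mfit$coefficients$p.value[2L] < alpha
    ca <- ancestryCorrectedAssociation(coh$curvature_per_mm,
                                       coh$eccentricity, coh$ancestry)
    adj[r] <- ca$p < alpha
  }
  list(marginal_significant = mean(marg),
       adjusted_significant = mean(adj), nSeeds = nSeeds)
}
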
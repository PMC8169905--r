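---
title: "Measuring hair fiber morphology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hair fiber morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hairmorph quantifies two aspects of hair fiber morphology from calibrated
grayscale micrographs: the **curvature** of short fiber fragments
photographed lying flat in a dish, and the **cross-sectional geometry**
(area, diameters, eccentricity) of embedded fibers cut perpendicular to
their axis. This vignette explains the underlying models, the tunable
parameters and their defaults, what the bundled simulators do and do not
emulate, and the numerical choices made where the design was open.

## The curvature model

A fiber fragment cut to a few millimetres and washed free of grooming
artifacts relaxes to (a close approximation of) a circular arc when it
settles flat in two dimensions. Curvature is therefore defined as the
reciprocal of the radius of the circle best fitting the fragment's
centreline, in mm^-1^: straight hair has curvature near 0; tightly curled
hair in the human range reaches about 2 mm^-1^ (a 0.5 mm radius).

The pipeline (`analyzeCurvatureImage()`) is:

1. **Polarity check.** Fibers are assumed dark on a light ground (light
   fibers are dyed before imaging). A predominantly dark image is
   inverted.
2. **Ridge enhancement** (`ridgeEnhance()`). A Hessian eigenvalue filter:
   at each Gaussian scale $\sigma$ the image is convolved with
   second-derivative-of-Gaussian kernels and the largest eigenvalue
   $\lambda_1$ of the Hessian is retained where positive (a dark ridge
   has a positive principal second derivative across it), normalized by
   $\sigma^2$ so responses are comparable across scales; the output is
   the maximum over scales. Default `scales = c(2, 3)` px, matched to
   fiber stroke widths of roughly 4--9 px (0.03--0.07 mm at the default
   132 px/mm calibration). Images of unusually thick fibers or different
   calibration should widen this range.
3. **Binarization and cleaning** (`binarizeAndClean()`). Otsu's threshold
   on the normalized response (parameter free, adequate for
   high-contrast dishes), removal of components below `minArea = 30` px
   (dust specks), hole filling.
4. **Skeletonization and splitting** (`skeletonizeAndSplit()`).
   Zhang--Suen thinning followed by a sequential pass that deletes every
   remaining 8-simple, non-endpoint pixel (Yokoi connectivity number 1),
   leaving a strict one-pixel-wide skeleton. Spurs up to
   `spurLengthPx = 10` px are pruned; branch points are then deleted so
   touching or crossing fibers split into simple paths rather than
   corrupting a single circle fit; paths shorter than
   `minLengthPx = 16` px (about 0.12 mm) are dropped.
5. **Circle fit and measures.** Each fragment gets a Taubin circle fit
   and a corrected path length (below).

### The Taubin circle fit

`fitCircleTaubin()` minimizes the Taubin-normalized algebraic distance
$\sum_i (|p_i - c|^2 - R^2)^2 / (4 R^2)$ via Newton iteration on the
characteristic polynomial of the scatter moments. Among non-iterative
circle fits it is nearly unbiased on short arcs, which matters here: at
curvature 0.1 mm^-1^ a fragment of length $\pi/2$ mm spans only 9 degrees
of its circle. Numerically collinear points (covariance eigenvalue ratio
below 10^-9^) return a degenerate fit, reported as curvature 0 — straight
hair is a valid phenotype, not an error.

The fit is applied to **all pixels of a labeled element** when the
element contains a single skeleton trace: both stroke edges constrain the
centreline and the quantization noise of individual pixels averages out
(per-fragment curvature scatter drops three- to four-fold compared with
fitting the skeleton path alone). When a component was split at branch
points, each trace's own path pixels are fit instead, since the
component's pixel set then mixes several fibers.

### Fragment length and the chain-code correction

Length is measured on the skeleton path as a chain code: $n_a$ axial
steps and $n_d$ diagonal steps. The naive estimator
$n_a + \sqrt{2}\,n_d$ systematically overestimates smooth curves sampled
on a square grid — a digitized straight line at 22.5 degrees reads about
8% long, and averaged over orientations the bias is near +5%. hairmorph
therefore uses the classical corrected estimator (Kulpa):

$$ L = \frac{\pi}{8}\left(1 + \sqrt{2}\right)\,(n_a + \sqrt{2}\, n_d), $$

whose leading coefficient (about 0.948) makes the estimator unbiased for
straight segments at uniformly distributed orientation. On simulated
arcs this lands within 1% of the true length; the plain
$\sqrt 2$-weighted count missed by 4--5%.

## The cross-section model

Sections are segmented with a **two-phase piecewise-constant Chan--Vese
active contour** (`segmentChanVese()`), chosen because section
micrographs have strong intensity differences but often poorly defined
edges. The energy balances two region-fidelity terms against a boundary
length penalty `mu` (default 0.25 on the [0, 1] intensity scale; larger
values smooth the contour). The level-set evolution uses semi-implicit
Gauss--Seidel updates with time step 0.5 and a smoothed delta function of
width 1.

One numerical choice deserves a note: the conventional checkerboard
initialization can freeze under Gauss--Seidel sweeps on high-contrast
images — both phases start with nearly equal means, the data forces
vanish, and the stopping rule (fewer than `tol` of pixels changing phase
per sweep, default 10^-3^) triggers on a stalled state. The initial level
set is therefore seeded from the intensities themselves
($\phi_0 = \bar I - I$, so darker-than-average pixels start inside),
which separates the phase means from the first iteration. A minimum of
five sweeps is enforced before the stopping rule is consulted; if the
iteration budget (`maxIter = 200`) is exhausted the current mask is
returned with a warning flag. If the two phase means remain within 0.02
the image is reported as containing no section.

After segmentation the largest connected region is retained (chips can
carry several embedded fibers; `multi = TRUE` reports one row per region
instead) and holes are filled. `measureSection()` then reports:

* **area**: foreground pixel count divided by the squared resolution;
* **minimum / maximum diameter**: the minor and major axis lengths of
  the *moments-equivalent ellipse* (the ellipse with the same second
  central moments as the region), $4\sqrt{\lambda_{\min}}$ and
  $4\sqrt{\lambda_{\max}}$ px;
* **eccentricity**: $\sqrt{1 - b^2/a^2}$ with $a,b$ the semi-axes above.

Moment-ellipse axes (rather than Feret diameters) were chosen so that
the reported diameters and the eccentricity formula are self-consistent:
the $a$ and $b$ in the eccentricity are exactly the reported
max/min diameters halved. For convex sections the pixel-count area and
the moment-ellipse area $\pi a b$ agree within 2%, which the test suite
checks as a consistency invariant.

Full-size canvases are first cropped (`cropToRegion()`, default 640 px
window) around the darkest coherent blob, located by Otsu thresholding
on a stride-subsampled copy; a centroid accurate to a few pixels is ample
for centring the crop, and it keeps the active contour cheap.

Microscope calibration cannot be trusted from TIFF tags, so the spatial
resolution is always a required argument (132 px/mm for the longitudinal
rig, 4.25 px/um for the section microscope of the validation setup).

## The simulators and what passing them proves

`generateArcDataset()` draws, per image, 25 disjoint dark arcs of
identical curvature on a light 5200 x 3900 px canvas at 132 px/mm. Each
arc starts at an angle drawn uniformly on $(0, \pi)$ and sweeps
$\pi / (2r)$ radians, so **every arc has true length $\pi/2$ mm
regardless of curvature** — length recovery can be checked against a
single constant. The default grid is 20 curvatures evenly spaced on
[0.1, 2] mm^-1^, the range observed in human scalp hair. Arcs are
rasterized analytically (a pixel is foreground iff its centre lies in
the annulus sector or the round end caps), with a 5 px stroke — thin
relative to the smallest radius (66 px), thick enough for the skeleton
to recover the centreline — and no anti-aliasing, so the ground truth is
unambiguous. Placement is rejection sampling with a 10 px clearance
between bounding boxes, because the analysis assumes non-touching
fragments.

`generateEllipseDataset()` draws one centred filled ellipse per image
(canvas 5200 x 3900 px at 4.25 px/um): maximum diameter uniform on
(50, 120) um — the human scalp range — eccentricity uniform on (0, 1),
rotation uniform on (0, 360) degrees. The truth table stores the
analytic area $\pi a b$, both diameters and the eccentricity.

Everything is seed-deterministic: the same seed reproduces images and
truth tables bit for bit.

What the simulators deliberately do **not** emulate: fiber texture and
the medulla, overlapping or touching fragments, illumination gradients,
sensor noise, debris, and partial focus. Passing the validation studies
therefore demonstrates that the measurement chain — filtering,
segmentation, skeletonization, fitting, calibration arithmetic — is
accurate on ideal geometry; it does not certify performance on difficult
real micrographs, where the cleaning parameters above are the knobs that
matter.

## Validation metrics

`rmse()` is $\sqrt{\tfrac1n \sum_i (\hat x_i - x_i)^2}$ — with the square
root, as both the name and the magnitudes of the headline accuracy
figures require. `percentError()` defaults to the mean per-element
relative error $\tfrac{100}{n}\sum |\hat x_i - x_i| / x_i$; because
reported percent errors in the literature sometimes use the RMSE divided
by the mean truth instead, that alternative is available as
`mode = "rmse_over_mean"` for sensitivity checks. `rSquared()` is the
squared Pearson correlation (affine invariant in either argument).
Validation joins estimates to truth per image — the study design
compares each image's *mean* estimated curvature and length against that
image's simulated values.

## The stratification demonstration

`synthCohort()` emulates the structure of an admixed African–European
cohort without using any human data. Per individual: an African ancestry
proportion from an equal mixture of Beta(2, 5) and Beta(5, 2) (spanning
[0, 1] with both ancestry poles represented), and three phenotypes that
are linear in ancestry plus heteroscedastic Gaussian noise whose SD
grows linearly with ancestry (trait variance in such cohorts increases
with African ancestry):

| trait | mean | noise SD | units |
|---|---|---|---|
| melanin index | 30 + 45 a | 1 + 2.5 a | reflectance units |
| curvature | 0.2 + 1.3 a | 0.05 + 0.2 a | mm^-1^ |
| eccentricity | 0.55 + 0.2 a | 0.05 + 0.1 a | — |

The intercepts and slopes are illustrative magnitudes for the published
trait ranges (curvature 0.1--2 mm^-1^, eccentricity clustered around
0.5--0.8); no real-cohort effect sizes are published to calibrate
against, and the demonstration is qualitative by construction. There is
**no direct trait–trait coupling** unless `directEffect` is set.

Because both curvature and eccentricity are driven by ancestry, they are
marginally correlated; regressing each trait on ancestry and testing the
residual-on-residual slope (`ancestryCorrectedAssociation()`) removes
the association. Two inference choices:

* the residual regression is **weighted by $1/\hat y_i^2$** (fitted
  values of the unweighted trait-on-ancestry pass) — the same weighting
  `fitTraitModel()` offers for its full and reduced models, appropriate
  when the noise SD scales with the trait mean;
* the slope is tested with **HC3 heteroscedasticity-consistent standard
  errors**. Plain OLS p-values are anti-conservative here (empirical
  type-I error 8--13% at $\alpha = 0.05$ across seeds); with weighting
  plus HC3 the empirical rate is 3--7%, and an injected direct effect of
  0.5 is still detected with the correct sign in over 95% of cohorts of
  n = 140.

Significance is two-sided at $\alpha = 0.05$, the conventional choice.
`binCurvature()` maps continuous curvature to ordinal curl types with
half-open intervals $[t_k, t_{k+1})$; the thresholds come from an
external published typology and are deliberately config-only — the
defaults make no claim to match any particular scheme.

## Problem sizes and determinism

The test suite runs the full study designs (20 images x 25 fragments;
100 ellipses; 100 cohorts) on reduced canvases (2600 x 1950 and
1024 x 768 px) — the per-fragment geometry, calibration and sample sizes
are identical, only the empty background shrinks. The acceptance script
(`scripts/acceptance.R`) re-runs both studies at the full
5200 x 3900 px canvas. All randomness flows from a single `--seed`.

## Known limitations

* Curvature is two-dimensional; fibers with three-dimensional crimp that
  do not settle flat are measured as their planar projection.
* Crossing fibers are split at skeleton branch points; the resulting
  sub-fragments are fit separately, which is robust but discards the
  correspondence between arms of the same fiber.
* Wave period, curl diameter per fiber, cuticle/medulla delineation and
  oblique-cut correction of sections are out of scope.
* Heavily textured or unevenly lit micrographs may need the ridge
  scales, `minArea` and Chan--Vese `mu` adjusted; the defaults are tuned
  for the high-contrast acquisition protocols the package targets.
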
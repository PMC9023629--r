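.asMask <- function(voi) {
  v <- if (is(voi, "SegmentationResult")) voi@mask else .asVolume(voi)
  array(as.integer(v >= 0.5), dim(v))
}

.voiWeights <- function(voi) {
  v <- if (is(voi, "SegmentationResult")) voi@mask else .asVolume(voi)
  v
}

#' Binary erosion with a spherical structuring element
#'
#' Fractional masks are binarized at 0.5 first. A 1 cm erosion of the
#' healthy-liver mask is the standard way to avoid edge effects in
#' uniformity measurements.
#'
#' @param mask binary or fractional 3D array (or [SegmentationResult-class]).
#' @param radius erosion radius in mm; 0 is the identity.
#' @param spacing voxel spacing in mm.
#' @return binary integer array.
#' @export
erodeVoi <- function(mask, radius, spacing) {
  m <- .asMask(mask)
  if (radius <= 0) return(m)
  out <- cppErodeBall(m, as.integer(dim(m)), radius / spacing)
  if (sum(out) == 0)
    stop(sprintf("erosion by %g mm empties the mask", radius))
  array(out, dim(m))
}

#' Coefficient of variation within a VOI
#'
#' 100 x (population standard deviation / mean) over the voxels with VOI
#' fraction at least 0.5; the uniformity metric of the protocol.
#'
#' @param image a [SpectImage-class] or 3D array.
#' @param voi binary or fractional mask.
#' @return COV in percent.
#' @export
imageCOV <- function(image, voi) {
  img <- .asVolume(image)
  m <- .asMask(voi) > 0
  if (!any(m)) stop("empty VOI")
  x <- img[m]
  mu <- mean(x)
  if (mu <= 0) stop("VOI mean must be positive")
  100 * sqrt(mean((x - mu)^2)) / mu
}

#' Contrast recovery coefficient
#'
#' \deqn{Q = \frac{C_S/C_B - 1}{R - 1} \times 100}
#' with \eqn{C_S} the mean intensity in the sphere VOI, \eqn{C_B} the mean
#' in the background (healthy-liver) VOI and \eqn{R} the nominal
#' sphere-to-background activity concentration ratio (0 for cold spheres,
#' 10 for the hot Ho spheres). VOI means are occupancy-weighted.
#'
#' @param image a [SpectImage-class] or 3D array.
#' @param sphere sphere VOI (binary or fractional).
#' @param background background VOI.
#' @param R nominal concentration ratio; must differ from 1.
#' @return list with \code{Q} (percent), \code{CS}, \code{CB}, \code{R}.
#' @export
contrastRecovery <- function(image, sphere, background, R) {
  if (R == 1) stop("R = 1 leaves the contrast recovery undefined")
  img <- .asVolume(image)
  ws <- .voiWeights(sphere); wb <- .voiWeights(background)
  if (sum(ws) == 0 || sum(wb) == 0) stop("empty VOI")
  cs <- sum(img * ws) / sum(ws)
  cb <- sum(img * wb) / sum(wb)
  if (cb <= 0) stop("background mean must be positive")
  list(Q = (cs / cb - 1) / (R - 1) * 100, CS = cs, CB = cb, R = R)
}

#' Sorensen-Dice overlap index
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} on masks binarized at 0.5; two empty
#' masks have Dice 1 by convention.
#'
#' @param a,b masks on the same grid.
#' @return Dice index in [0, 1].
#' @export
diceIndex <- function(a, b) {
  ma <- .asMask(a); mb <- .asMask(b)
  if (!identical(dim(ma), dim(mb))) stop("masks are not on the same grid")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' Recovered volume as a percentage of nominal
#'
#' @param mask binary or fractional mask (binarized at 0.5).
#' @param nominal nominal volume in mL (positive).
#' @param spacing voxel spacing in mm.
#' @return percent of the nominal volume.
#' @export
volumeRecovery <- function(mask, nominal, spacing) {
  if (nominal <= 0) stop("nominal volume must be positive")
  if (is(mask, "SegmentationResult")) {
    spacing <- mask@spacing
    mask <- mask@mask
  }
  100 * sum(.asMask(mask)) * prod(spacing) / 1000 / nominal
}

#' Count density within a VOI
#'
#' Occupancy-weighted mean voxel value divided by the voxel volume in mL:
#' the dosimetry-relevant intensity (counts/mL) of a reconstruction.
#'
#' @param image a [SpectImage-class] or 3D array.
#' @param voi fractional or binary VOI used as weights.
#' @param spacing voxel spacing in mm for plain arrays.
#' @return counts per mL.
#' @export
countDensity <- function(image, voi, spacing = NULL) {
  if (is(image, "SpectImage") && is.null(spacing)) spacing <- image@spacing
  img <- .asVolume(image)
  w <- .voiWeights(voi)
  if (sum(w) == 0) stop("empty VOI")
  (sum(img * w) / sum(w)) / (prod(spacing) / 1000)
}

#' Percent difference between paired count densities
#'
#' 100 x (dual - single) / single; the per-procedure impact of the added Tc
#' activity on the Ho count density.
#'
#' @param dual count density from the dual-isotope reconstruction.
#' @param single count density from the Ho-only reconstruction.
#' @return percent difference.
#' @export
percentDifference <- function(dual, single) {
  if (any(single == 0)) stop("single-scan count density must be nonzero")
  100 * (dual - single) / single
}

#' Fit the COV-versus-activity relation
#'
#' Least-squares fit of \eqn{COV(A) = \sqrt{a/A + b^2}}: Poisson noise
#' falls with the square root of the activity while the offset b captures
#' the activity-independent nonuniformity from the limited imaging
#' resolution.
#'
#' @param activities activities in MBq (positive, at least 3 points).
#' @param covs COV values in percent.
#' @return list with \code{a}, \code{b}, \code{fitted}, \code{residuals}
#'   and \code{rms}.
#' @export
fitCovOffset <- function(activities, covs) {
  if (length(activities) < 3) stop("need at least 3 points")
  if (any(activities <= 0)) stop("activities must be positive")
  if (length(activities) != length(covs)) stop("length mismatch")
  # linearised start: COV^2 = a/A + b^2
  st <- stats::coef(stats::lm(I(covs^2) ~ I(1 / activities)))
  p0 <- c(a = max(st[2], 0), b = sqrt(max(st[1], 1e-8)))
  obj <- function(p) sum((covs - sqrt(p[1] / activities + p[2]^2))^2)
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = c(0, 0))
  a <- unname(fit$par[1]); b <- unname(fit$par[2])
  fitted <- sqrt(a / activities + b^2)
  res <- covs - fitted
  list(a = a, b = b, fitted = fitted, residuals = res,
       rms = sqrt(mean(res^2)))
}

#' Two-sided Welch t test
#'
#' Unequal-variance t test between two groups of metric values (e.g. COV
#' with vs without Ho present). Two identical constant groups return t = 0,
#' p = 1.
#'
#' @param groupA,groupB numeric vectors with at least 2 values each.
#' @return list with \code{t} and \code{p}.
#' @export
welchTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (isTRUE(all.equal(mean(groupA), mean(groupB))))
      return(list(t = 0, p = 1))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, p = 0))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}
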
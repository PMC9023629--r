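#' OSEM reconstruction parameters
#'
#' Clinical defaults: 10 iterations, 8 interleaved subsets, attenuation and
#' scatter correction, no post-reconstruction filtering.
#'
#' @param iterations OSEM iterations.
#' @param subsets interleaved angle subsets (angle i goes to subset
#'   i mod subsets); must divide the number of angles.
#' @param scatterMode \code{"none"}, \code{"dew"} or \code{"tew"}.
#' @param k DEW k-factor.
#' @param attenuation apply attenuation modelling.
#' @return a [ReconParams-class].
#' @export
reconParams <- function(iterations = 10L, subsets = 8L,
                        scatterMode = "none", k = 1.0, attenuation = TRUE) {
  new("ReconParams", iterations = as.integer(iterations),
      subsets = as.integer(subsets), scatterMode = scatterMode, k = k,
      attenuation = attenuation)
}

#' Triple-energy-window scatter estimate
#'
#' Estimates the scatter in the Tc photopeak window from the two flanking
#' narrow windows:
#' \deqn{S_E = (C_L/W_L + C_U/W_U) \times W_{PP}/2}
#' where \eqn{C_L, C_U} are the recorded 118 and 170 keV projections and
#' \eqn{W_L, W_U, W_{PP}} the widths in keV of the lower, upper and
#' photopeak windows (14.16, 20.4 and 21 keV for the protocol defaults).
#' The estimate is clipped at zero.
#'
#' @param cL lower scatter window projections (array, any shape).
#' @param cU upper scatter window projections, same shape as \code{cL}.
#' @param windows named list holding the \code{sc118}, \code{tc140} and
#'   \code{sc170} windows (defaults to the protocol windows).
#' @return array of estimated photopeak scatter counts, same shape.
#' @examples
#' tewScatterEstimate(100, 50)  # ~99.89
#' @export
tewScatterEstimate <- function(cL, cU, windows = defaultEnergyWindows()) {
  if (!identical(dim(cL), dim(cU)) || length(cL) != length(cU))
    stop("C_L and C_U must have the same shape")
  wl <- windowWidthKeV(windows$sc118)
  wu <- windowWidthKeV(windows$sc170)
  wpp <- windowWidthKeV(windows$tc140)
  pmax((cL / wl + cU / wu) * wpp / 2, 0)
}

#' Dual-energy-window downscatter estimate for the Ho photopeak
#'
#' The 118 keV window projections scaled by the k-factor estimate the
#' downscatter (from Tc and from Ho's own high-energy emissions and
#' bremsstrahlung) in the 81 keV photopeak window. No window-width
#' rescaling is applied: the k-factor absorbs the width ratio.
#'
#' @param c118 118 keV window projections.
#' @param k positive scale factor.
#' @return array of estimated scatter counts.
#' @export
dewScatterEstimate <- function(c118, k) {
  if (k <= 0) stop("k-factor must be positive")
  pmax(k * c118, 0)
}

#' OSEM reconstruction with additive scatter
#'
#' Ordered-subsets EM with the multiplicative update
#' \deqn{x \gets x \frac{A_s^T (y_s / (A_s x + s_s))}{A_s^T 1}}
#' where \eqn{A} is the attenuated, PSF-matched rotation projector and
#' \eqn{s} the additive scatter estimate (entering the forward model, not
#' subtracted from the counts, which preserves Poisson statistics and
#' nonnegativity). The estimate starts as ones on the body support (voxels
#' with nonzero attenuation) and a floor of 1e-12 is added to forward
#' projections before division.
#'
#' @param photopeak array (u, v, angle) of photopeak counts.
#' @param scatter scatter estimate of the same shape, or NULL.
#' @param mu attenuation volume (1/cm), or NULL; also defines the support.
#' @param geom an [AcquisitionGeometry-class] or angle vector (radians).
#' @param spacing voxel spacing in mm.
#' @param params a [ReconParams-class]; \code{scatterMode} is metadata here,
#'   the scatter argument is what is used.
#' @param psfSigma PSF sigma in mm, matched to the acquisition.
#' @param isotope label stored in the result.
#' @param keepIterates return per-iteration images in the provenance
#'   (small problems only).
#' @return a [SpectImage-class] of reconstructed counts per voxel.
#' @export
osemReconstruct <- function(photopeak, scatter = NULL, mu = NULL, geom,
                            spacing, params = reconParams(), psfSigma = 0,
                            isotope = "", keepIterates = FALSE) {
  pd <- dim(photopeak)
  if (length(pd) != 3L) stop("photopeak must be a (u, v, angle) array")
  if (min(photopeak) < 0) stop("negative counts in photopeak data")
  if (!is.null(scatter)) {
    if (!identical(dim(scatter), pd))
      stop("scatter estimate shape does not match the photopeak data")
    scatter <- pmax(scatter, 0)
  }
  angles <- if (is(geom, "AcquisitionGeometry")) orbitAngles(geom)
            else as.numeric(geom)
  if (length(angles) != pd[3]) stop("angle count mismatch")
  muv <- if (is.null(mu) || !params@attenuation) numeric(0)
         else .asVolume(mu)
  d <- c(pd[1], pd[1], pd[2])   # square in-plane grid
  if (length(muv)) d <- dim(.asVolume(mu))
  res <- cppOsem(photopeak,
                 if (is.null(scatter)) numeric(0) else scatter, muv,
                 as.integer(d), angles, spacing[2] / 10,
                 psfSigma / spacing[1], params@iterations, params@subsets,
                 isTRUE(keepIterates))
  prov <- list(kind = "osem", iterations = params@iterations,
               subsets = params@subsets, scatterMode = params@scatterMode,
               k = params@k, attenuation = params@attenuation,
               psfSigma = psfSigma)
  if (keepIterates) prov$iterates <- res$iterates
  new("SpectImage", data = res$image, spacing = as.numeric(spacing),
      isotope = isotope, provenance = prov)
}

#' Reconstruct the Ho and Tc images from a dual-isotope acquisition
#'
#' The Ho image is the OSEM reconstruction of the 81 keV window with the
#' k-scaled dual-energy-window scatter estimate; the Tc image is the OSEM
#' reconstruction of the 140 keV window with the triple-energy-window
#' estimate. Attenuation maps are evaluated at 81 and 140 keV respectively.
#'
#' @param ps a [ProjectionSet-class] containing all four windows.
#' @param labels the [LabelVolume-class] providing attenuation maps.
#' @param k DEW k-factor for the Ho reconstruction.
#' @param params a [ReconParams-class].
#' @param psfSigma PSF sigma in mm (match the simulating detector).
#' @param which which images to reconstruct (\code{"both"}, \code{"ho"},
#'   \code{"tc"}).
#' @return list with elements \code{ho} and/or \code{tc} ([SpectImage-class]).
#' @export
reconstructPair <- function(ps, labels, k = 1.0, params = reconParams(),
                            psfSigma = 5, which = c("both", "ho", "tc")) {
  which <- match.arg(which)
  wn <- dimnames(ps@counts)[[4]]
  need <- c("ho81", "sc118", "tc140", "sc170")
  miss <- setdiff(need, wn)
  if (length(miss))
    stop("missing energy window: ", paste(miss, collapse = ", "))
  out <- list()
  if (which %in% c("both", "ho")) {
    mu81 <- attenuationMap(labels, 81)
    sc <- dewScatterEstimate(ps@counts[, , , "sc118"], k)
    p <- params; p@scatterMode <- "dew"; p@k <- k
    out$ho <- osemReconstruct(ps@counts[, , , "ho81"], sc, mu81,
                              ps@geometry, ps@spacing, p, psfSigma,
                              isotope = "ho")
  }
  if (which %in% c("both", "tc")) {
    mu140 <- attenuationMap(labels, 140)
    sc <- tewScatterEstimate(ps@counts[, , , "sc118"],
                             ps@counts[, , , "sc170"], ps@windows)
    p <- params; p@scatterMode <- "tew"
    out$tc <- osemReconstruct(ps@counts[, , , "tc140"], sc, mu140,
                              ps@geometry, ps@spacing, p, psfSigma,
                              isotope = "tc")
  }
  out
}
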
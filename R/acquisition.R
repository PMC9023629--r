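#' Energy window constructors and arithmetic
#'
#' The clinical dual-isotope protocol acquires four windows: the Ho
#' photopeak at 81 keV (15 pct wide), a scatter window at 118 keV (12 pct),
#' the Tc photopeak at 140 keV (15 pct) and an upper scatter window at
#' 170 keV (12 pct). Bounds are centre * (1 +/- width/2) and the absolute
#' width in keV is centre * width.
#'
#' @param name window label.
#' @param center centre in keV.
#' @param width width as a fraction of the centre.
#' @return `energyWindow`: an [EnergyWindow-class]; `windowBounds`: numeric
#'   \code{c(lo, hi)} in keV; `windowWidthKeV`: the absolute width in keV;
#'   `defaultEnergyWindows`: a named list of the four protocol windows.
#' @examples
#' windowBounds(energyWindow("tc140", 140, 0.15))  # 129.5 150.5
#' @export
energyWindow <- function(name, center, width) {
  new("EnergyWindow", name = name, center = as.numeric(center),
      width = as.numeric(width))
}

#' @rdname energyWindow
#' @param w an [EnergyWindow-class].
#' @export
windowBounds <- function(w) {
  if (w@width <= 0 || w@width >= 2)
    stop("window width fraction must be in (0, 2)")
  c(lo = w@center * (1 - w@width / 2), hi = w@center * (1 + w@width / 2))
}

#' @rdname energyWindow
#' @export
windowWidthKeV <- function(w) w@center * w@width

#' @rdname energyWindow
#' @export
defaultEnergyWindows <- function() {
  list(ho81 = energyWindow("ho81", 81, 0.15),
       sc118 = energyWindow("sc118", 118, 0.12),
       tc140 = energyWindow("tc140", 140, 0.15),
       sc170 = energyWindow("sc170", 170, 0.12))
}

#' Acquisition geometry, detector and crosstalk model constructors
#'
#' `acquisitionGeometry` describes the step-and-shoot orbit (modelled as
#' circular). `detectorModel` sets the in-plane Gaussian PSF, the photopeak
#' count sensitivities and the broad blur applied to downscatter components.
#' `scatterModel` sets the window contamination coefficients; its default
#' `cHo` coefficients lie on a continuum that the triple-energy-window
#' interpolation reproduces exactly at 140 keV, so TEW can undo the Ho
#' contamination of the Tc photopeak the way it does for the real smooth
#' bremsstrahlung continuum.
#'
#' @param nAngles number of projection angles (default 120, clinical).
#' @param orbit orbit coverage in degrees (default 360).
#' @param dwell seconds per projection (default 20, clinical protocol).
#' @return an [AcquisitionGeometry-class], [DetectorModel-class] or
#'   [ScatterModel-class].
#' @export
acquisitionGeometry <- function(nAngles = 120L, orbit = 360, dwell = 20) {
  new("AcquisitionGeometry", nAngles = as.integer(nAngles), orbit = orbit,
      dwell = dwell)
}

#' @rdname acquisitionGeometry
#' @param psfSigma in-plane PSF sigma in mm (default 5, medium-energy
#'   collimator scale).
#' @param sensitivity named counts/s/MBq at the primary photopeaks. The Tc
#'   default matches the system sensitivity of a medium-energy collimator
#'   camera at 140 keV (about 100 counts/s/MBq); the Ho default is about
#'   13x lower, reflecting the 6.7 pct emission probability of the 81 keV
#'   Ho gamma against 89 pct for 140 keV Tc: this is what makes Tc
#'   downscatter a first-order contamination of the Ho photopeak window.
#' @param scatterSigma sigma in mm of the broad downscatter blur (default 30).
#' @export
detectorModel <- function(psfSigma = 5, sensitivity = c(ho = 7.5, tc = 100),
                          scatterSigma = 30) {
  new("DetectorModel", psfSigma = psfSigma, sensitivity = sensitivity,
      scatterSigma = scatterSigma)
}

#' @rdname acquisitionGeometry
#' @param cTc118 fraction of the Tc primary flux contaminating the 118 keV
#'   window (default 0.10).
#' @param kTrue true 81/118 crosstalk ratio generated by the simulator
#'   (default 1.0); DEW with k = kTrue removes the Tc crosstalk exactly.
#' @param cHo named Ho contamination fractions for the four windows.
#' @export
scatterModel <- function(cTc118 = 0.10, kTrue = 1.0,
                         cHo = c("81" = 0.15, "118" = 0.12,
                                 "140" = NA, "170" = 0.08)) {
  if (is.na(cHo["140"])) {
    # window-integrated value of the continuum reconstructed by TEW
    wl <- windowWidthKeV(energyWindow("sc118", 118, 0.12))
    wu <- windowWidthKeV(energyWindow("sc170", 170, 0.12))
    wpp <- windowWidthKeV(energyWindow("tc140", 140, 0.15))
    cHo["140"] <- (cHo["118"] / wl + cHo["170"] / wu) * wpp / 2
  }
  new("ScatterModel", cTc118 = cTc118, kTrue = kTrue, cHo = cHo)
}

#' Orbit angles in radians
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return numeric vector of projection angles (radians).
#' @export
orbitAngles <- function(geom) {
  seq(0, geom@orbit * pi / 180, length.out = geom@nAngles + 1L)[1:geom@nAngles]
}

.asVolume <- function(x) if (is(x, "SpectImage")) x@data else x

#' Attenuated forward projection
#'
#' Rotation-based parallel-beam projector: for each angle the volume is
#' resampled on the rotated grid (bilinear), attenuated line integrals are
#' accumulated along the detector direction with the half-voxel
#' self-attenuation convention, and the projection is blurred with the
#' in-plane Gaussian PSF. Linear in the activity.
#'
#' @param activity 3D array or [SpectImage-class]; values per voxel.
#' @param mu attenuation volume in 1/cm matching \code{activity}, or NULL
#'   for no attenuation.
#' @param geom an [AcquisitionGeometry-class] (or a numeric vector of angles
#'   in radians).
#' @param spacing voxel spacing in mm (taken from \code{activity} when it is
#'   a [SpectImage-class]).
#' @param psfSigma PSF sigma in mm.
#' @return array (detector u, detector v, angle) of expected counts per unit
#'   sensitivity and time.
#' @export
forwardProject <- function(activity, mu = NULL, geom, spacing = NULL,
                           psfSigma = 0) {
  if (is(activity, "SpectImage") && is.null(spacing))
    spacing <- activity@spacing
  act <- .asVolume(activity)
  muv <- if (is.null(mu)) numeric(0) else .asVolume(mu)
  if (anyNA(act) || (length(muv) && anyNA(muv)))
    stop("NaN/NA in projector inputs")
  if (length(muv) && !identical(dim(act), dim(muv)))
    stop("activity and attenuation volumes must share a grid")
  angles <- if (is(geom, "AcquisitionGeometry")) orbitAngles(geom)
            else as.numeric(geom)
  d <- dim(act)
  cppForwardProject(act, muv, as.integer(d), angles, spacing[2] / 10,
                    psfSigma / spacing[1])
}

#' Adjoint of the forward projector
#'
#' @param proj array (u, v, angle).
#' @param mu attenuation volume or NULL.
#' @param geom geometry or angle vector (radians).
#' @param dim integer(3) volume dimensions.
#' @param spacing voxel spacing in mm.
#' @param psfSigma PSF sigma in mm.
#' @return 3D backprojected volume.
#' @export
backProject <- function(proj, mu = NULL, geom, dim, spacing, psfSigma = 0) {
  muv <- if (is.null(mu)) numeric(0) else .asVolume(mu)
  angles <- if (is(geom, "AcquisitionGeometry")) orbitAngles(geom)
            else as.numeric(geom)
  cppBackProject(proj, muv, as.integer(dim), angles, spacing[2] / 10,
                 psfSigma / spacing[1])
}

#' Simulate a dual-isotope multi-window acquisition
#'
#' Generates noiseless expected counts in the four energy windows. Each
#' isotope's primary photopeak term is the attenuated, PSF-blurred forward
#' projection of its activity map scaled by sensitivity and dwell time.
#' Downscatter terms are the primary-equivalent flux additionally blurred
#' with the broad scatter kernel and scaled by the window contamination
#' coefficients: Tc contaminates the 118 keV window (\code{cTc118}) and the
#' 81 keV window (\code{kTrue * cTc118}); Ho contaminates all four windows
#' via \code{cHo}; nothing from Tc reaches the 170 keV window. Attenuation
#' of a downscatter component uses the photopeak-energy map of the
#' originating isotope.
#'
#' @param labels a [LabelVolume-class] built by [buildPhantom()].
#' @param detector a [DetectorModel-class].
#' @param scatter a [ScatterModel-class].
#' @param geom an [AcquisitionGeometry-class].
#' @param activities named numeric, total effective MBq per isotope
#'   (\code{c(ho = ..., tc = ...)}); each isotope's stored compartment
#'   distribution is rescaled to this total. Missing entries default to the
#'   totals stored in the phantom.
#' @param windows named list of the four [EnergyWindow-class] objects.
#' @return a [ProjectionSet-class] of noiseless expected counts.
#' @export
simulateAcquisition <- function(labels, detector = detectorModel(),
                                scatter = scatterModel(),
                                geom = acquisitionGeometry(),
                                activities = NULL,
                                windows = defaultEnergyWindows()) {
  stopifnot(is(labels, "LabelVolume"))
  vv <- voxelVolumeML(labels)
  stored <- c(ho = 0, tc = 0)
  for (a in labels@activity)
    for (iso in names(a)) stored[iso] <- stored[iso] + a[[iso]]
  if (is.null(activities)) activities <- stored
  if (any(activities < 0)) stop("activities must be >= 0")
  bad <- setdiff(names(activities), c("ho", "tc"))
  if (length(bad)) stop("unknown isotope: ", paste(bad, collapse = ", "))
  angles <- orbitAngles(geom)
  dwell <- geom@dwell
  d <- labels@grid@dim
  spacing <- labels@grid@spacing

  # primary-equivalent photopeak count flux per isotope
  flux <- function(iso, energy) {
    conc <- activityMap(labels, iso)@data             # MBq/mL
    tot <- sum(conc) * vv
    want <- activities[iso]
    if (is.na(want)) want <- stored[iso]
    if (tot > 0 && want >= 0) conc <- conc * (want / tot)
    mu <- attenuationMap(labels, energy)@data
    p <- cppForwardProject(conc * vv, mu, as.integer(d), angles,
                           spacing[2] / 10,
                           detector@psfSigma / spacing[1])
    p * detector@sensitivity[iso] * dwell
  }
  zero <- array(0, c(d[1], d[3], length(angles)))
  fHo <- if (!is.na(activities["ho"]) && activities["ho"] > 0 ||
             (is.na(activities["ho"]) && stored["ho"] > 0))
    flux("ho", 81) else zero
  fTc <- if (!is.na(activities["tc"]) && activities["tc"] > 0 ||
             (is.na(activities["tc"]) && stored["tc"] > 0))
    flux("tc", 140) else zero
  pd <- as.integer(c(d[1], d[3], length(angles)))
  sSig <- detector@scatterSigma / spacing[1]
  bHo <- if (sum(fHo) > 0) cppBlurProjections(fHo, pd, sSig) else fHo
  bTc <- if (sum(fTc) > 0) cppBlurProjections(fTc, pd, sSig) else fTc

  cnt <- array(0, c(pd, 4L),
               dimnames = list(NULL, NULL, NULL, names(windows)))
  cHo <- scatter@cHo
  cnt[, , , "ho81"] <- fHo + cHo["81"] * bHo +
    scatter@kTrue * scatter@cTc118 * bTc
  cnt[, , , "sc118"] <- cHo["118"] * bHo + scatter@cTc118 * bTc
  cnt[, , , "tc140"] <- fTc + cHo["140"] * bHo
  cnt[, , , "sc170"] <- cHo["170"] * bHo
  eff <- c(ho = unname(if (is.na(activities["ho"])) stored["ho"]
                       else activities["ho"]),
           tc = unname(if (is.na(activities["tc"])) stored["tc"]
                       else activities["tc"]))
  new("ProjectionSet", counts = cnt, geometry = geom, windows = windows,
      spacing = spacing,
      provenance = list(activities = eff, noiseless = TRUE, seed = NA,
                        detector = list(psfSigma = detector@psfSigma,
                                        sensitivity = detector@sensitivity,
                                        scatterSigma = detector@scatterSigma),
                        scatter = list(cTc118 = scatter@cTc118,
                                       kTrue = scatter@kTrue,
                                       cHo = scatter@cHo),
                        volDim = d))
}

#' Add Poisson counting noise to expected projections
#'
#' Independent Poisson draw per bin; the seed is recorded in the provenance
#' and a fixed seed reproduces the realisation exactly.
#'
#' @param ps a noiseless [ProjectionSet-class].
#' @param seed integer RNG seed.
#' @return a [ProjectionSet-class] with integer-valued counts.
#' @export
addPoissonNoise <- function(ps, seed) {
  lam <- ps@counts
  if (min(lam) < 0) stop("negative expected counts")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  noisy <- array(as.numeric(stats::rpois(length(lam), lam)),
                 dim = dim(lam), dimnames = dimnames(lam))
  pv <- ps@provenance
  pv$noiseless <- FALSE
  pv$seed <- as.integer(seed)
  new("ProjectionSet", counts = noisy, geometry = ps@geometry,
      windows = ps@windows, spacing = ps@spacing, provenance = pv)
}
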
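#' @import methods
NULL

#' Voxel grid geometry
#'
#' Defines a regular voxel grid: array dimensions, voxel spacing in mm and
#' the world coordinate (mm) of the centre of voxel (1,1,1). By default the
#' grid is centred on the world origin. Voxel indices are mapped to world
#' coordinates at voxel centres.
#'
#' @slot dim integer(3), number of voxels per axis (at least 16 per axis).
#' @slot spacing numeric(3), voxel size in mm per axis (positive).
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @exportClass GridGeometry
setClass("GridGeometry",
         representation(dim = "integer", spacing = "numeric",
                        origin = "numeric"))

setValidity("GridGeometry", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 16L))
    return("grid dimensions must be a triple with at least 16 voxels per axis")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("voxel spacing must be positive on all axes")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Phantom compartment
#'
#' One compartment of a digital phantom: an analytic sphere or ellipsoid (or
#' an explicit fractional mask), its per-isotope activities in MBq and its
#' attenuation class.
#'
#' @slot name character label.
#' @slot shape one of \code{"sphere"}, \code{"ellipsoid"}, \code{"mask"}.
#' @slot center numeric(3) world centre in mm (analytic shapes).
#' @slot semiAxes numeric(3) semi-axes in mm (a sphere stores its radius in
#'   all three entries).
#' @slot mask fractional occupancy array for \code{"mask"} shapes.
#' @slot activity named numeric, MBq per isotope (e.g. \code{c(ho = 250)}).
#' @slot attenuationClass \code{"water"}, \code{"lung"} or \code{"air"}.
#' @slot nominalVolume analytic volume in mL (mask shapes: integral of the
#'   mask times the voxel volume, set when the phantom is built).
#' @exportClass Compartment
setClass("Compartment",
         representation(name = "character", shape = "character",
                        center = "numeric", semiAxes = "numeric",
                        mask = "ANY", activity = "numeric",
                        attenuationClass = "character",
                        nominalVolume = "numeric"))

setValidity("Compartment", function(object) {
  if (!object@shape %in% c("sphere", "ellipsoid", "mask"))
    return("shape must be 'sphere', 'ellipsoid' or 'mask'")
  if (object@shape != "mask" && any(object@semiAxes <= 0))
    return(sprintf("compartment '%s': radius/semi-axes must be positive",
                   object@name))
  if (length(object@activity) && any(object@activity < 0))
    return(sprintf("compartment '%s': activities must be >= 0", object@name))
  if (!object@attenuationClass %in% c("water", "lung", "air"))
    return(sprintf("compartment '%s': unknown attenuation class '%s'",
                   object@name, object@attenuationClass))
  TRUE
})

#' Digital phantom specification
#'
#' A voxel grid plus an ordered list of compartments. Compartments are listed
#' outermost first; a later compartment is carved out of every earlier one
#' (the tumour spheres are carved out of the liver, so sphere voxels do not
#' count toward healthy-liver occupancy).
#'
#' @slot grid a [GridGeometry-class].
#' @slot compartments list of [Compartment-class] objects.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(grid = "GridGeometry", compartments = "list"))

setValidity("PhantomSpec", function(object) {
  if (!all(vapply(object@compartments, is, logical(1), "Compartment")))
    return("compartments must all be Compartment objects")
  nm <- vapply(object@compartments, function(c) c@name, character(1))
  if (anyDuplicated(nm)) return("compartment names must be unique")
  TRUE
})

#' Fractional compartment occupancy volumes
#'
#' Per-compartment fractional occupancy (values in [0, 1]) on the phantom
#' grid, the ground truth for all volumes of interest. Carving has been
#' applied, so occupancies sum to at most 1 per voxel. Carries forward the
#' per-compartment activities, attenuation classes and nominal volumes.
#'
#' @slot grid the [GridGeometry-class].
#' @slot fractions named list of 3D arrays, one per compartment.
#' @slot nominalVolumes named numeric, analytic compartment volumes in mL.
#' @slot activity named list of per-compartment activity vectors (MBq).
#' @slot attenuationClass named character per compartment.
#' @exportClass LabelVolume
setClass("LabelVolume",
         representation(grid = "GridGeometry", fractions = "list",
                        nominalVolumes = "numeric", activity = "list",
                        attenuationClass = "character"))

#' Reconstructed or simulated 3D image
#'
#' A voxel volume with spacing metadata: an activity concentration map
#' (MBq/mL), an attenuation map (1/cm) or a reconstruction (counts per
#' voxel). Values are nonnegative.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot isotope isotope label ("ho", "tc") or "" where not applicable.
#' @slot provenance list of generating parameters.
#' @exportClass SpectImage
setClass("SpectImage",
         representation(data = "array", spacing = "numeric",
                        isotope = "character", provenance = "list"))

setValidity("SpectImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be positive, length 3")
  TRUE
})

#' Energy window
#'
#' An acquisition energy window, given as centre (keV) and fractional width;
#' bounds are centre * (1 +/- width/2).
#'
#' @slot name window label.
#' @slot center centre in keV.
#' @slot width width as a fraction of the centre (e.g. 0.15 for 15 pct).
#' @exportClass EnergyWindow
setClass("EnergyWindow",
         representation(name = "character", center = "numeric",
                        width = "numeric"))

setValidity("EnergyWindow", function(object) {
  if (object@center <= 0) return("window centre must be positive")
  if (object@width <= 0 || object@width >= 2)
    return("window width fraction must be in (0, 2)")
  TRUE
})

#' SPECT acquisition geometry
#'
#' Step-and-shoot orbit description: number of angles, orbit coverage in
#' degrees and dwell time per projection. The orbit is modelled as circular.
#'
#' @slot nAngles number of projection angles (>= 4).
#' @slot orbit orbit coverage in degrees.
#' @slot dwell seconds per projection.
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
         representation(nAngles = "integer", orbit = "numeric",
                        dwell = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  if (object@nAngles < 4L) return("need at least 4 projection angles")
  if (object@dwell <= 0) return("dwell time must be positive")
  TRUE
})

#' Detector response model
#'
#' Abstraction of the camera and collimator: an in-plane Gaussian PSF, a
#' count sensitivity per isotope photopeak and the width of the broad blur
#' applied to downscatter components.
#'
#' @slot psfSigma in-plane Gaussian PSF sigma in mm.
#' @slot sensitivity named counts/s/MBq for the primary photopeaks
#'   (\code{c(ho = ..., tc = ...)}).
#' @slot scatterSigma sigma (mm) of the broad blur applied to downscatter.
#' @exportClass DetectorModel
setClass("DetectorModel",
         representation(psfSigma = "numeric", sensitivity = "numeric",
                        scatterSigma = "numeric"))

setValidity("DetectorModel", function(object) {
  if (object@psfSigma < 0 || object@scatterSigma < 0 ||
      any(object@sensitivity < 0))
    return("detector parameters must be >= 0")
  TRUE
})

#' Window crosstalk model
#'
#' The contamination coefficients that generate downscatter in the simulator
#' and that the window-based corrections must undo. Tc contaminates the
#' 118 keV window with fraction \code{cTc118} of its primary flux and the
#' 81 keV window with \code{kTrue * cTc118}; Ho contaminates all four windows
#' via \code{cHo} (high-energy gammas plus bremsstrahlung). Nothing from Tc
#' reaches the 170 keV window (140 keV photons cannot upscatter).
#'
#' @slot cTc118 fraction of Tc primary flux in the 118 keV window.
#' @slot kTrue true crosstalk ratio between the 81 and 118 keV Tc terms.
#' @slot cHo named numeric, Ho contamination fraction per window
#'   (names "81", "118", "140", "170").
#' @exportClass ScatterModel
setClass("ScatterModel",
         representation(cTc118 = "numeric", kTrue = "numeric",
                        cHo = "numeric"))

setValidity("ScatterModel", function(object) {
  if (object@cTc118 < 0 || object@kTrue < 0 || any(object@cHo < 0))
    return("contamination coefficients must be >= 0")
  if (!all(c("81", "118", "140", "170") %in% names(object@cHo)))
    return("cHo must be named for the windows 81, 118, 140, 170")
  TRUE
})

#' Multi-window projection data
#'
#' Per-window, per-angle 2D count projections with geometry metadata; the
#' simulator's output and the reconstructor's input. The counts array has
#' dimensions (detector u, detector v, angle, window) with window names in
#' the dimnames; Poisson realisations are integer-valued.
#'
#' @slot counts 4D array of counts.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot windows named list of [EnergyWindow-class] objects.
#' @slot spacing numeric(3), voxel/detector pixel spacing in mm of the grid
#'   the projections were generated from.
#' @slot provenance list (effective activities, seed, noiseless flag, ...).
#' @exportClass ProjectionSet
setClass("ProjectionSet",
         representation(counts = "array", geometry = "AcquisitionGeometry",
                        windows = "list", spacing = "numeric",
                        provenance = "list"))

setValidity("ProjectionSet", function(object) {
  d <- dim(object@counts)
  if (length(d) != 4L) return("counts must be a 4D array (u, v, angle, window)")
  if (d[3] != object@geometry@nAngles)
    return("angle dimension does not match the acquisition geometry")
  if (d[4] != length(object@windows))
    return("window dimension does not match the window list")
  if (min(object@counts) < 0) return("counts must be >= 0")
  TRUE
})

#' OSEM reconstruction parameters
#'
#' @slot iterations number of OSEM iterations (default 10).
#' @slot subsets number of interleaved angle subsets (default 8); must
#'   divide the number of angles.
#' @slot scatterMode \code{"none"}, \code{"dew"} or \code{"tew"}.
#' @slot k DEW scale factor applied to the 118 keV window (k > 0).
#' @slot attenuation logical, apply attenuation modelling (default TRUE).
#' @exportClass ReconParams
setClass("ReconParams",
         representation(iterations = "integer", subsets = "integer",
                        scatterMode = "character", k = "numeric",
                        attenuation = "logical"))

setValidity("ReconParams", function(object) {
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@subsets < 1L) return("subsets must be >= 1")
  if (!object@scatterMode %in% c("none", "dew", "tew"))
    return("scatterMode must be 'none', 'dew' or 'tew'")
  if (object@scatterMode == "dew" && object@k <= 0)
    return("DEW k-factor must be positive")
  TRUE
})

#' Threshold segmentation parameters
#'
#' @slot sigma Gaussian smoothing sigma in mm (default 15).
#' @slot alpha threshold as a fraction of the smoothed maximum (default 0.40).
#' @exportClass SegmentationParams
setClass("SegmentationParams",
         representation(sigma = "numeric", alpha = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  TRUE
})

#' Threshold segmentation result
#'
#' @slot mask logical/integer 3D array, the healthy-liver mask.
#' @slot threshold threshold in image units (alpha x smoothed maximum).
#' @slot params the [SegmentationParams-class] used.
#' @slot spacing voxel spacing in mm.
#' @slot coldSpheres list produced by [extractColdSpheres()] (may be empty).
#' @exportClass SegmentationResult
setClass("SegmentationResult",
         representation(mask = "array", threshold = "numeric",
                        params = "SegmentationParams", spacing = "numeric",
                        coldSpheres = "list"))

#' k-factor sweep result
#'
#' Per-k reconstruction summaries from a phantom-mode or paired-mode sweep.
#'
#' @slot mode \code{"phantom"} or \code{"paired"}.
#' @slot perScan data.frame with one row per (k, scan) or (k, pair).
#' @slot summary data.frame with one row per k (slope and reference-activity
#'   error in phantom mode; median, IQR and median absolute pair difference
#'   in paired mode).
#' @slot grid the k grid swept.
#' @slot refActivity reference Tc activity (MBq) for the interpolated error.
#' @exportClass KFactorSweep
setClass("KFactorSweep",
         representation(mode = "character", perScan = "data.frame",
                        summary = "data.frame", grid = "numeric",
                        refActivity = "numeric"))
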
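#' Accessor generics
#'
#' Small accessor set for the package's containers: `imageData` returns the
#' raw array of a [SpectImage-class], `voxelSpacing` the mm spacing of any
#' gridded object, `counts` the 4D count array of a [ProjectionSet-class],
#' `isotope` the isotope label and `voxelVolumeML` the voxel volume in mL.
#'
#' @param object a package object.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("isotope", function(object) standardGeneric("isotope"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeML", function(object) standardGeneric("voxelVolumeML"))

#' @rdname accessors
#' @export
setMethod("imageData", "SpectImage", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "SpectImage", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "GridGeometry", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(object) object@grid@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ProjectionSet", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("counts", "ProjectionSet", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("isotope", "SpectImage", function(object) object@isotope)

#' @rdname accessors
#' @export
setMethod("voxelVolumeML", "GridGeometry",
          function(object) prod(object@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("voxelVolumeML", "SpectImage",
          function(object) prod(object@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("voxelVolumeML", "LabelVolume",
          function(object) prod(object@grid@spacing) / 1000)

#' @describeIn accessors dimensions of the image array.
#' @export
setMethod("dim", "SpectImage", function(x) dim(x@data))

#' @describeIn accessors grid dimensions of the label volume.
#' @export
setMethod("dim", "LabelVolume", function(x) x@grid@dim)

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %s voxels, %s mm spacing\n",
              paste(object@dim, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec with %d compartments on a %s grid\n",
              length(object@compartments),
              paste(object@grid@dim, collapse = "x")))
  for (cp in object@compartments) {
    act <- if (length(cp@activity))
      paste(sprintf("%s=%.3g MBq", names(cp@activity), cp@activity),
            collapse = ", ")
    else "no activity"
    cat(sprintf("  %-8s %-9s %7.1f mL  [%s]  %s\n", cp@name, cp@shape,
                cp@nominalVolume, cp@attenuationClass, act))
  }
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %d compartments on a %s grid\n",
              length(object@fractions),
              paste(object@grid@dim, collapse = "x")))
  vv <- voxelVolumeML(object)
  for (nm in names(object@fractions))
    cat(sprintf("  %-8s recovered %7.1f mL (nominal %7.1f mL)\n", nm,
                sum(object@fractions[[nm]]) * vv, object@nominalVolumes[nm]))
})

setMethod("show", "SpectImage", function(object) {
  cat(sprintf("SpectImage [%s]: %s voxels, %s mm, range [%.4g, %.4g]\n",
              if (nzchar(object@isotope)) object@isotope else "-",
              paste(dim(object@data), collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "ProjectionSet: %d x %d bins, %d angles, windows [%s]\n",
    d[1], d[2], d[3], paste(names(object@windows), collapse = ", ")))
  pv <- object@provenance
  if (!is.null(pv$activities))
    cat(sprintf("  activities: %s; %s\n",
                paste(sprintf("%s=%.3g MBq", names(pv$activities),
                              pv$activities), collapse = ", "),
                if (isTRUE(pv$noiseless)) "noiseless expectation"
                else sprintf("Poisson realisation (seed %s)",
                             as.character(pv$seed))))
})

setMethod("show", "KFactorSweep", function(object) {
  cat(sprintf("KFactorSweep (%s mode): %d k values in [%.2f, %.2f]\n",
              object@mode, length(object@grid), min(object@grid),
              max(object@grid)))
  print(object@summary, digits = 4)
})
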
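#' Write and read reconstructed or simulated volumes
#'
#' Volumes are stored as NIfTI-1 (RAS+, voxel size in the header, 64-bit
#' float so the round trip is lossless) with a JSON sidecar carrying the
#' isotope label and provenance.
#'
#' @param img a [SpectImage-class].
#' @param path file path; \code{.nii.gz} is appended when missing.
#' @return `writeSpectImage`: the path, invisibly. `readSpectImage`: a
#'   [SpectImage-class].
#' @export
writeSpectImage <- function(img, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  nii <- RNifti::asNifti(img@data)
  RNifti::pixdim(nii) <- img@spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  prov <- img@provenance
  prov$iterates <- NULL
  jsonlite::write_json(list(isotope = img@isotope, spacing = img@spacing,
                            provenance = prov),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSpectImage
#' @export
readSpectImage <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  nii <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list(isotope = "", spacing = RNifti::pixdim(nii),
                    provenance = list())
  arr <- array(as.numeric(nii), dim(nii))
  new("SpectImage", data = arr, spacing = as.numeric(meta$spacing),
      isotope = if (is.null(meta$isotope)) "" else meta$isotope,
      provenance = as.list(meta$provenance))
}

#' Write and read multi-window projection data
#'
#' The count array is stored as a 4D NIfTI-1 volume (lossless 64-bit float)
#' and the acquisition metadata (windows, geometry, spacing, provenance) as
#' a JSON sidecar; the loader validates the header against the array shape.
#'
#' @param ps a [ProjectionSet-class].
#' @param path file path; \code{.nii.gz} is appended when missing.
#' @return `writeProjectionSet`: the path, invisibly. `readProjectionSet`:
#'   a [ProjectionSet-class].
#' @export
writeProjectionSet <- function(ps, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  nii <- RNifti::asNifti(ps@counts)
  RNifti::writeNifti(nii, path, datatype = "double")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  win <- lapply(ps@windows, function(w)
    list(name = w@name, center = w@center, width = w@width))
  prov <- rapply(ps@provenance, function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }, classes = c("numeric", "integer", "character"), how = "replace")
  jsonlite::write_json(
    list(shape = dim(ps@counts),
         windows = win,
         windowOrder = dimnames(ps@counts)[[4]],
         geometry = list(nAngles = ps@geometry@nAngles,
                         orbit = ps@geometry@orbit,
                         dwell = ps@geometry@dwell),
         spacing = ps@spacing,
         provenance = prov),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeProjectionSet
#' @export
readProjectionSet <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = FALSE)
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim(nii))
  if (!identical(as.integer(dim(arr)),
                 as.integer(unlist(meta$shape))))
    stop("projection array shape does not match the sidecar header")
  dimnames(arr) <- list(NULL, NULL, NULL,
                        as.character(unlist(meta$windowOrder)))
  windows <- lapply(meta$windows, function(w)
    energyWindow(w$name, w$center, w$width))
  names(windows) <- vapply(windows, function(w) w@name, character(1))
  prov <- lapply(meta$provenance, function(x)
    if (is.list(x)) lapply(x, function(y) unlist(y)) else unlist(x))
  if (!is.null(prov$activities))
    prov$activities <- unlist(meta$provenance$activities)
  geom <- acquisitionGeometry(meta$geometry$nAngles, meta$geometry$orbit,
                              meta$geometry$dwell)
  new("ProjectionSet", counts = arr, geometry = geom, windows = windows,
      spacing = as.numeric(unlist(meta$spacing)), provenance = prov)
}

#' Write and read a phantom specification as YAML
#'
#' Analytic compartments (spheres and ellipsoids) round-trip exactly;
#' mask-type compartments are not serialisable to YAML.
#'
#' @param spec a [PhantomSpec-class].
#' @param path YAML file path.
#' @return `writePhantomSpec`: the path, invisibly. `readPhantomSpec`: a
#'   [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  comps <- lapply(spec@compartments, function(cp) {
    if (cp@shape == "mask")
      stop("mask-type compartments cannot be written to YAML")
    list(name = cp@name, shape = cp@shape, center = cp@center,
         semiAxes = cp@semiAxes,
         activity = as.list(cp@activity),
         attenuationClass = cp@attenuationClass)
  })
  yaml::write_yaml(list(grid = list(dim = spec@grid@dim,
                                    spacing = spec@grid@spacing,
                                    origin = spec@grid@origin),
                        compartments = comps), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- gridGeometry(y$grid$dim, y$grid$spacing, y$grid$origin)
  comps <- lapply(y$compartments, function(cp) {
    act <- unlist(cp$activity)
    if (is.null(act)) act <- numeric(0)
    if (cp$shape == "sphere")
      sphereCompartment(cp$name, unlist(cp$center), cp$semiAxes[[1]],
                        activity = act,
                        attenuationClass = cp$attenuationClass)
    else
      ellipsoidCompartment(cp$name, unlist(cp$center), unlist(cp$semiAxes),
                           activity = act,
                           attenuationClass = cp$attenuationClass)
  })
  phantomSpec(grid, comps)
}

#' Write a binary mask as NIfTI
#'
#' @param mask binary 3D array or [SegmentationResult-class].
#' @param path file path.
#' @param spacing voxel spacing in mm for plain arrays.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path, spacing = NULL) {
  if (is(mask, "SegmentationResult")) {
    spacing <- mask@spacing
    mask <- mask@mask
  }
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  nii <- RNifti::asNifti(array(as.integer(mask >= 0.5), dim(mask)))
  RNifti::pixdim(nii) <- spacing
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}
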
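#' Threshold segmentation parameters
#'
#' @param sigma 3D Gaussian smoothing sigma in mm (default 15, the width
#'   found to minimise the variance of segmented volumes).
#' @param alpha threshold as a fraction of the smoothed maximum (default
#'   0.40, the averaged calibrated value).
#' @return a [SegmentationParams-class].
#' @export
segmentationParams <- function(sigma = 15, alpha = 0.40) {
  new("SegmentationParams", sigma = sigma, alpha = alpha)
}

.gaussSmooth <- function(img, sigmaMM, spacing) {
  if (sigmaMM <= 0) return(img)
  cppGaussBlur3D(img, as.integer(dim(img)), sigmaMM / spacing)
}

#' Smoothed-maximum threshold segmentation
#'
#' Thresholds an image at a percentage alpha of the maximum of its
#' 3D-Gaussian-smoothed version; the threshold is applied back to the
#' original, un-smoothed image (comparison is inclusive, \code{>=}).
#' Smoothing the maximum removes the dependence on a single noisy voxel.
#' Gaussian filtering uses reflective boundaries; sigma in mm is converted
#' per axis to voxel units.
#'
#' @param image a [SpectImage-class] or 3D array (then supply
#'   \code{spacing}).
#' @param params a [SegmentationParams-class].
#' @param spacing voxel spacing in mm when \code{image} is a plain array.
#' @return a [SegmentationResult-class].
#' @export
segmentLiver <- function(image, params = segmentationParams(),
                         spacing = NULL) {
  if (is(image, "SpectImage") && is.null(spacing)) spacing <- image@spacing
  img <- .asVolume(image)
  if (min(img) < 0) stop("image must be nonnegative")
  if (max(img) <= 0) stop("cannot segment an all-zero image")
  sm <- .gaussSmooth(img, params@sigma, spacing)
  thr <- params@alpha * max(sm)
  mask <- array(as.integer(img >= thr), dim(img))
  new("SegmentationResult", mask = mask, threshold = thr, params = params,
      spacing = as.numeric(spacing), coldSpheres = list())
}

#' Calibrate the threshold percentage against a known volume
#'
#' Finds the alpha in (0.01, 0.99) whose segmented volume best matches the
#' nominal volume. The segmented volume is non-increasing in alpha, so the
#' optimum is located by a monotone search over the distinct achievable
#' thresholds; when several alphas give the same (optimal) voxel count the
#' midpoint of that plateau is returned.
#'
#' @param image a [SpectImage-class] or 3D array.
#' @param nominalVolume target volume in mL.
#' @param sigma smoothing sigma in mm.
#' @param spacing voxel spacing in mm for plain arrays.
#' @return the calibrated alpha.
#' @export
calibrateAlpha <- function(image, nominalVolume, sigma = 15,
                           spacing = NULL) {
  if (nominalVolume <= 0) stop("nominal volume must be positive")
  if (is(image, "SpectImage") && is.null(spacing)) spacing <- image@spacing
  img <- .asVolume(image)
  if (max(img) <= 0) stop("cannot calibrate on an all-zero image")
  sm <- .gaussSmooth(img, sigma, spacing)
  M <- max(sm)
  u <- prod(spacing) / 1000
  vs <- sort(as.vector(img))
  loT <- 0.01 * M; hiT <- 0.99 * M
  # the segmented volume is a step function of the threshold, constant on
  # the intervals between consecutive distinct image values: evaluate each
  # plateau at its midpoint
  brk <- sort(unique(vs[vs > loT & vs < hiT]))
  edges <- c(loT, brk, hiT)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cnts <- length(vs) - findInterval(mids, vs)
  vols <- cnts * u
  if (nominalVolume > max(vols) + u / 2 || nominalVolume < min(vols) - u / 2)
    stop(sprintf(
      "nominal volume %.1f mL outside the achievable range [%.1f, %.1f] mL",
      nominalVolume, min(vols), max(vols)))
  i <- which.min(abs(vols - nominalVolume))
  min(max(mids[i] / M, 0.011), 0.989)
}

#' Average calibrated thresholds across scans
#'
#' A single alpha applied to every scan of a series is defined as the
#' arithmetic mean of the per-scan optimal values.
#'
#' @param alphas numeric vector of per-scan calibrated alphas.
#' @return the mean alpha.
#' @export
averageAlpha <- function(alphas) {
  if (!length(alphas)) stop("empty alpha list")
  mean(alphas)
}

#' Select the smoothing width minimising segmented-volume variance
#'
#' For each candidate sigma, calibrates alpha on every image, applies the
#' series-averaged alpha back to all images and records the variance of the
#' segmented volumes; returns the sigma with the smallest variance (ties go
#' to the smaller sigma).
#'
#' @param images list of [SpectImage-class] objects.
#' @param nominalVolume target volume in mL.
#' @param sigmaGrid candidate sigmas in mm.
#' @return list with \code{sigma} (the selection), and a data.frame
#'   \code{table} of per-sigma averaged alpha and volume variance.
#' @export
selectSigma <- function(images, nominalVolume, sigmaGrid) {
  if (!length(sigmaGrid)) stop("empty sigma grid")
  if (length(images) < 2) stop("need at least 2 images")
  rows <- lapply(sigmaGrid, function(s) {
    al <- vapply(images, calibrateAlpha, numeric(1),
                 nominalVolume = nominalVolume, sigma = s)
    ab <- averageAlpha(al)
    vols <- vapply(images, function(im) {
      r <- segmentLiver(im, segmentationParams(sigma = s, alpha = ab))
      sum(r@mask) * prod(voxelSpacing(im)) / 1000
    }, numeric(1))
    data.frame(sigma = s, alpha = ab, varVolume = stats::var(vols))
  })
  tab <- do.call(rbind, rows)
  best <- tab$sigma[order(tab$varVolume, tab$sigma)][1]
  list(sigma = best, table = tab)
}

#' Extract cold spheres (tumour holes) from a segmentation mask
#'
#' Takes the largest 26-connected component of the mask, fills its internal
#' cavities, and returns the filled-minus-component holes as labelled
#' masks, sorted by volume (largest first). When nominal sphere centres are
#' given, each hole is matched to the nearest centre; a centre with no
#' matching hole (e.g. a cavity that touches the component boundary and so
#' cannot be closed by filling) is flagged as not recovered.
#'
#' @param mask binary 3D array or [SegmentationResult-class].
#' @param spacing voxel spacing in mm for plain arrays.
#' @param centers optional matrix (n x 3) of nominal sphere centres in
#'   world mm (grid centred on the origin), rownames as labels.
#' @return list with \code{masks} (list of binary arrays), \code{table}
#'   (data.frame of volume in mL and centroid in mm per hole, with matched
#'   labels when centres were given) and \code{unmatched} (labels of nominal
#'   centres with no recovered hole).
#' @export
extractColdSpheres <- function(mask, spacing = NULL, centers = NULL) {
  if (is(mask, "SegmentationResult")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@mask
  }
  m <- array(as.integer(mask >= 0.5), dim(mask))
  d <- dim(m)
  lab <- cppLabelComponents(m, as.integer(d), 26L)
  if (max(lab) == 0)
    return(list(masks = list(), table = data.frame(), unmatched = character(0)))
  sizes <- tabulate(lab[lab > 0])
  comp <- array(as.integer(lab == which.max(sizes)), d)
  filled <- cppFillHoles(comp, as.integer(d))
  holes <- array(as.integer(filled == 1L & comp == 0L), d)
  hlab <- cppLabelComponents(holes, as.integer(d), 26L)
  nh <- max(hlab)
  u <- prod(spacing) / 1000
  if (nh == 0) {
    tab <- data.frame()
    masks <- list()
  } else {
    origin <- -(d - 1) / 2 * spacing
    info <- lapply(seq_len(nh), function(i) {
      w <- which(hlab == i)
      ijk <- arrayInd(w, d) - 1
      ctr <- colMeans(ijk) * spacing + origin
      list(vol = length(w) * u, centroid = ctr, voxels = w)
    })
    ord <- order(vapply(info, function(x) x$vol, numeric(1)),
                 decreasing = TRUE)
    info <- info[ord]
    masks <- lapply(info, function(x) {
      a <- array(0L, d); a[x$voxels] <- 1L; a
    })
    tab <- data.frame(
      hole = seq_along(info),
      volumeML = vapply(info, function(x) x$vol, numeric(1)),
      cx = vapply(info, function(x) x$centroid[1], numeric(1)),
      cy = vapply(info, function(x) x$centroid[2], numeric(1)),
      cz = vapply(info, function(x) x$centroid[3], numeric(1)))
  }
  unmatched <- character(0)
  if (!is.null(centers) && nrow(tab)) {
    labels <- rownames(centers)
    if (is.null(labels)) labels <- paste0("sphere", seq_len(nrow(centers)))
    tab$matched <- NA_character_
    for (j in seq_len(nrow(centers))) {
      dists <- sqrt((tab$cx - centers[j, 1])^2 +
                    (tab$cy - centers[j, 2])^2 +
                    (tab$cz - centers[j, 3])^2)
      free <- which(is.na(tab$matched))
      if (!length(free)) { unmatched <- c(unmatched, labels[j]); next }
      i <- free[which.min(dists[free])]
      tab$matched[i] <- labels[j]
    }
    names(masks) <- tab$matched
  } else if (!is.null(centers)) {
    labels <- rownames(centers)
    if (is.null(labels)) labels <- paste0("sphere", seq_len(nrow(centers)))
    unmatched <- labels
  }
  list(masks = masks, table = tab, unmatched = unmatched)
}
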
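#' k-factor grid
#'
#' The clinical sweep: k from 0.65 to 1.30 in steps of 0.05, both endpoints
#' included. The grid is built by integer stepping to avoid floating-point
#' drift (14 points for the defaults).
#'
#' @param start first k (default 0.65).
#' @param stop last k (default 1.30).
#' @param step increment (default 0.05).
#' @return numeric vector of k values.
#' @export
kFactorGrid <- function(start = 0.65, stop = 1.30, step = 0.05) {
  if (start >= stop) stop("start must be below stop")
  if (step <= 0) stop("step must be positive")
  scale <- 1000
  g <- seq(round(start * scale), round(stop * scale),
           by = round(step * scale)) / scale
  if (abs(g[length(g)] - stop) > 1e-9) g <- c(g, stop)
  g
}

#' Phantom-mode k-factor sweep
#'
#' Reconstructs the Ho image of every scan in a series (fixed Ho activity,
#' varying Tc activity) for each k on the grid, measures the healthy-liver
#' count density, and expresses it as a percent change relative to the
#' minimum-Tc reference scan. Each k is summarised two ways: the
#' least-squares slope of the percent change versus Tc activity, and the
#' percent error interpolated at a reference activity (default 50 MBq, the
#' clinical protocol amount). Under-correction (k below the generative
#' crosstalk ratio) inflates the healthy-liver Ho count density,
#' over-correction deflates it.
#'
#' @param series list of [ProjectionSet-class] objects with varying Tc
#'   activity (recorded in their provenance) and a common Ho activity.
#' @param healthyVoi healthy-liver VOI (fractional or binary).
#' @param labels [LabelVolume-class] for the attenuation maps.
#' @param grid k values from [kFactorGrid()].
#' @param params a [ReconParams-class].
#' @param psfSigma PSF sigma in mm.
#' @param refActivity reference Tc activity in MBq for the interpolated
#'   percent error.
#' @return a [KFactorSweep-class].
#' @export
sweepPhantom <- function(series, healthyVoi, labels, grid = kFactorGrid(),
                         params = reconParams(), psfSigma = 5,
                         refActivity = 50) {
  tc <- vapply(series, function(p) unname(p@provenance$activities["tc"]),
               numeric(1))
  if (length(unique(tc)) < 2)
    stop("need at least 2 distinct Tc activities in the series")
  refIdx <- which.min(tc)
  perScan <- list()
  summary <- list()
  for (k in grid) {
    dens <- vapply(seq_along(series), function(i) {
      r <- reconstructPair(series[[i]], labels, k = k, params = params,
                           psfSigma = psfSigma, which = "ho")
      countDensity(r$ho, healthyVoi)
    }, numeric(1))
    pct <- 100 * (dens - dens[refIdx]) / dens[refIdx]
    fit <- stats::lm(pct ~ tc)
    refErr <- unname(stats::predict(fit,
                                    newdata = data.frame(tc = refActivity)))
    perScan[[length(perScan) + 1]] <-
      data.frame(k = k, scan = seq_along(series), tcMBq = tc,
                 density = dens, pctChange = pct)
    summary[[length(summary) + 1]] <-
      data.frame(k = k, slope = unname(stats::coef(fit)[2]),
                 refActivityError = refErr)
  }
  new("KFactorSweep", mode = "phantom",
      perScan = do.call(rbind, perScan),
      summary = do.call(rbind, summary), grid = grid,
      refActivity = refActivity)
}

#' Paired-mode k-factor sweep
#'
#' For each (dual, single) acquisition pair the healthy-liver VOI is
#' obtained by thresholding the Tc image of the dual scan; both Ho images
#' are reconstructed with the same k and the percent difference of their
#' healthy-liver count densities is recorded. Each k is summarised by the
#' median, interquartile range and median absolute value of the per-pair
#' differences. A pair whose Tc segmentation comes out empty is skipped
#' with a warning.
#'
#' @param pairs list of lists with elements \code{dual} and \code{single}
#'   ([ProjectionSet-class] each, sharing geometry).
#' @param labels [LabelVolume-class] for the attenuation maps.
#' @param grid k values.
#' @param params a [ReconParams-class].
#' @param seg a [SegmentationParams-class] for the Tc thresholding.
#' @param psfSigma PSF sigma in mm.
#' @return a [KFactorSweep-class].
#' @export
sweepPaired <- function(pairs, labels, grid = kFactorGrid(),
                        params = reconParams(),
                        seg = segmentationParams(), psfSigma = 5) {
  vois <- list()
  keep <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    tcimg <- reconstructPair(pairs[[i]]$dual, labels, params = params,
                             psfSigma = psfSigma, which = "tc")$tc
    res <- tryCatch(segmentLiver(tcimg, seg), error = function(e) NULL)
    if (is.null(res) || sum(res@mask) == 0) {
      warning(sprintf("pair %d: empty Tc segmentation, pair skipped", i))
      next
    }
    vois[[i]] <- res@mask
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no pair yielded a usable Tc segmentation")
  perPair <- list()
  summary <- list()
  for (k in grid) {
    diffs <- c()
    for (i in which(keep)) {
      hd <- reconstructPair(pairs[[i]]$dual, labels, k = k, params = params,
                            psfSigma = psfSigma, which = "ho")$ho
      hs <- reconstructPair(pairs[[i]]$single, labels, k = k,
                            params = params, psfSigma = psfSigma,
                            which = "ho")$ho
      d <- percentDifference(countDensity(hd, vois[[i]]),
                             countDensity(hs, vois[[i]]))
      diffs <- c(diffs, d)
      perPair[[length(perPair) + 1]] <-
        data.frame(k = k, pair = i, pctDifference = d)
    }
    summary[[length(summary) + 1]] <-
      data.frame(k = k, median = stats::median(diffs),
                 iqr = stats::IQR(diffs),
                 medianAbsDiff = stats::median(abs(diffs)))
  }
  new("KFactorSweep", mode = "paired",
      perScan = do.call(rbind, perPair),
      summary = do.call(rbind, summary), grid = grid,
      refActivity = NA_real_)
}

#' Select the optimal k-factor from a sweep
#'
#' Returns the k minimising the absolute value of the chosen criterion
#' (ties go to the smaller k): the percent error at the reference activity
#' (default), the slope of the percent change versus Tc activity, or the
#' median absolute per-pair difference for paired sweeps.
#'
#' @param sweep a [KFactorSweep-class].
#' @param criterion \code{"ref_activity_error"}, \code{"slope"} or
#'   \code{"median_abs_pair_diff"}.
#' @return the selected k.
#' @export
selectK <- function(sweep,
                    criterion = c("ref_activity_error", "slope",
                                  "median_abs_pair_diff")) {
  criterion <- match.arg(criterion)
  s <- sweep@summary
  if (!nrow(s)) stop("empty sweep")
  vals <- switch(criterion,
                 ref_activity_error = s$refActivityError,
                 slope = s$slope,
                 median_abs_pair_diff = s$medianAbsDiff)
  if (is.null(vals))
    stop(sprintf("criterion '%s' not available for a %s-mode sweep",
                 criterion, sweep@mode))
  ord <- order(abs(vals), s$k)
  s$k[ord[1]]
}
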
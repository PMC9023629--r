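.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483629)
}

#' Generate a synthetic measurement series
#'
#' Reproduces the study conditions of the phantom experiments at a chosen
#' scale: the dual-isotope series holds Ho at 250 MBq-equivalent while the
#' effective Tc activity is log-spaced from 25 to 126 MBq; the Tc-only
#' series spans 8 to 240 MBq without Ho; the paired series mimics scout
#' procedures with a dual (Ho 250 + Tc 50 MBq) and a single (Ho-only)
#' acquisition per pair, drawn with independent seeds. The "small" scale
#' uses a 64^3 grid at 4.8 mm with 48 angles and reduced count levels; the
#' "paper" scale uses the clinical 128 x 128 matrix with 120 angles.
#'
#' @param kind \code{"dual"}, \code{"tc_only"} or \code{"paired"}.
#' @param nScans number of scans (or pairs); at least 2 for series kinds.
#' @param seed top-level seed; per-scan seeds are derived deterministically.
#' @param scale \code{"small"} or \code{"paper"}.
#' @param noise add Poisson noise (TRUE) or keep the noiseless expectations.
#' @param detector,scatter optional model overrides.
#' @return list with \code{kind}, \code{spec} ([PhantomSpec-class]),
#'   \code{labels} ([LabelVolume-class]), \code{scans} (list of
#'   [ProjectionSet-class], or of \code{dual}/\code{single} pairs),
#'   \code{tcActivities} and \code{config} (the parameters used).
#' @export
generateFixtureSeries <- function(kind = c("dual", "tc_only", "paired"),
                                  nScans = 8L, seed = 1L,
                                  scale = c("small", "paper"),
                                  noise = TRUE, detector = detectorModel(),
                                  scatter = scatterModel()) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (nScans < 2) stop("series need at least 2 scans")
  grid <- if (scale == "small") gridGeometry(64L, 4.8)
          else gridGeometry(128L, 4.8)
  geom <- if (scale == "small") acquisitionGeometry(48L)
          else acquisitionGeometry(120L)
  spec <- defaultPhantom(grid)
  labels <- buildPhantom(spec, supersample = 4L)
  tcAct <- switch(kind,
                  dual = exp(seq(log(25), log(126), length.out = nScans)),
                  tc_only = exp(seq(log(8), log(240), length.out = nScans)),
                  paired = rep(50, nScans))
  one <- function(ho, tc, sd) {
    ps <- simulateAcquisition(labels, detector, scatter, geom,
                              activities = c(ho = ho, tc = tc))
    if (noise) addPoissonNoise(ps, sd) else ps
  }
  if (kind == "paired") {
    scans <- lapply(seq_len(nScans), function(i)
      list(dual = one(250, 50, .deriveSeed(seed, 2 * i - 1)),
           single = one(250, 0, .deriveSeed(seed, 2 * i))))
  } else {
    ho <- if (kind == "dual") 250 else 0
    scans <- lapply(seq_len(nScans), function(i)
      one(ho, tcAct[i], .deriveSeed(seed, i)))
  }
  list(kind = kind, spec = spec, labels = labels, scans = scans,
       tcActivities = tcAct,
       config = list(kind = kind, nScans = nScans, seed = seed,
                     scale = scale, noise = noise,
                     grid = list(dim = grid@dim, spacing = grid@spacing),
                     nAngles = geom@nAngles, dwell = geom@dwell))
}

#' Experiment configuration
#'
#' Bundles every parameter of an end-to-end run; serialisable to YAML via
#' [yaml::write_yaml()]. All randomness flows from the single top-level
#' seed, expanded deterministically per scan.
#'
#' @param kind series kind (see [generateFixtureSeries()]).
#' @param nScans number of scans or pairs.
#' @param seed top-level seed.
#' @param scale \code{"small"} or \code{"paper"}.
#' @param noise simulate Poisson noise.
#' @param k DEW k-factor for the reported reconstructions.
#' @param iterations,subsets OSEM settings.
#' @param segSigma,segAlpha segmentation settings; \code{segAlpha = NA}
#'   calibrates alpha on the series instead of using a fixed value.
#' @param kGrid k sweep grid (NULL disables the sweep).
#' @param refActivity reference Tc activity for the sweep summary.
#' @return a named list.
#' @export
experimentConfig <- function(kind = "dual", nScans = 8L, seed = 1L,
                             scale = "small", noise = TRUE, k = 1.0,
                             iterations = 10L, subsets = 8L, segSigma = 15,
                             segAlpha = NA, kGrid = kFactorGrid(),
                             refActivity = 50) {
  list(kind = kind, nScans = nScans, seed = seed, scale = scale,
       noise = noise, k = k, iterations = iterations, subsets = subsets,
       segSigma = segSigma, segAlpha = segAlpha, kGrid = kGrid,
       refActivity = refActivity)
}

.manifestRow <- function(file, operation, params, seed = NA) {
  data.frame(file = file, operation = operation,
             params = jsonlite::toJSON(params, auto_unbox = TRUE,
                                       digits = NA),
             seed = as.character(seed), timestamp = format(Sys.time()),
             stringsAsFactors = FALSE)
}

#' Run an end-to-end phantom experiment
#'
#' Executes simulate, reconstruct, segment, metrics and (for dual series)
#' the k-factor sweep, writing every artefact under \code{outDir} together
#' with a manifest listing each file with its producing operation,
#' parameters and seed. Reruns with the same configuration are
#' deterministic.
#'
#' @param config list from [experimentConfig()].
#' @param outDir output directory (created if needed).
#' @return list with \code{metrics} (per-scan data.frame), \code{sweep}
#'   ([KFactorSweep-class] or NULL), \code{alpha} (the applied threshold
#'   percentage) and \code{manifest} (data.frame).
#' @export
runExperiment <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage <- "simulate"
  result <- tryCatch({
    fx <- generateFixtureSeries(config$kind, config$nScans, config$seed,
                                config$scale, config$noise)
    labels <- fx$labels
    vv <- voxelVolumeML(labels)
    spacing <- labels@grid@spacing
    healthyNominal <- unname(labels@nominalVolumes["liver"])
    truthHealthy <- labels@fractions$liver
    params <- reconParams(config$iterations, config$subsets)
    isPaired <- config$kind == "paired"
    scans <- if (isPaired) lapply(fx$scans, `[[`, "dual") else fx$scans
    for (i in seq_along(scans)) {
      f <- file.path(outDir, sprintf("proj_scan%02d.nii.gz", i))
      writeProjectionSet(scans[[i]], f)
      manifest[[length(manifest) + 1]] <- .manifestRow(
        basename(f), "simulateAcquisition", fx$config,
        scans[[i]]@provenance$seed)
      manifest[[length(manifest) + 1]] <- .manifestRow(
        sub("\\.nii\\.gz$", ".json", basename(f)), "simulateAcquisition",
        fx$config, scans[[i]]@provenance$seed)
    }

    stage <- "reconstruct"
    which <- if (config$kind == "tc_only") "tc" else "both"
    recons <- lapply(seq_along(scans), function(i) {
      r <- reconstructPair(scans[[i]], labels, k = config$k,
                           params = params, which = which)
      for (iso in names(r)) {
        f <- file.path(outDir, sprintf("%s_scan%02d.nii.gz", iso, i))
        writeSpectImage(r[[iso]], f)
        manifest[[length(manifest) + 1]] <<- .manifestRow(
          basename(f), "reconstructPair",
          list(k = config$k, iterations = config$iterations,
               subsets = config$subsets), scans[[i]]@provenance$seed)
        manifest[[length(manifest) + 1]] <<- .manifestRow(
          sub("\\.nii\\.gz$", ".json", basename(f)), "reconstructPair",
          list(k = config$k), scans[[i]]@provenance$seed)
      }
      r
    })

    stage <- "segment"
    tcImages <- lapply(recons, `[[`, "tc")
    haveTc <- config$kind %in% c("dual", "tc_only")
    alpha <- config$segAlpha
    segs <- NULL
    if (haveTc) {
      if (is.na(alpha)) {
        alphas <- vapply(tcImages, calibrateAlpha, numeric(1),
                         nominalVolume = healthyNominal,
                         sigma = config$segSigma)
        alpha <- averageAlpha(alphas)
      }
      sp <- segmentationParams(sigma = config$segSigma, alpha = alpha)
      segs <- lapply(tcImages, segmentLiver, params = sp)
      for (i in seq_along(segs)) {
        f <- file.path(outDir, sprintf("healthy_mask_scan%02d.nii.gz", i))
        writeMask(segs[[i]], f)
        manifest[[length(manifest) + 1]] <- .manifestRow(
          basename(f), "segmentLiver",
          list(sigma = config$segSigma, alpha = alpha), NA)
      }
    }

    stage <- "metrics"
    erHealthy <- erodeVoi(truthHealthy, 10, spacing)
    rows <- lapply(seq_along(scans), function(i) {
      act <- scans[[i]]@provenance$activities
      row <- data.frame(scan = i, hoMBq = unname(act["ho"]),
                        tcMBq = unname(act["tc"]))
      for (iso in c("ho", "tc")) {
        img <- recons[[i]][[iso]]
        if (is.null(img) || is.na(act[iso]) || act[iso] <= 0) next
        R <- if (iso == "ho") 10 else 0
        row[[paste0("cov_", iso)]] <- imageCOV(img, erHealthy)
        row[[paste0("q_s1_", iso)]] <-
          contrastRecovery(img, labels@fractions$S1, truthHealthy, R)$Q
        row[[paste0("q_s2_", iso)]] <-
          contrastRecovery(img, labels@fractions$S2, truthHealthy, R)$Q
        row[[paste0("density_", iso)]] <- countDensity(img, truthHealthy)
      }
      if (!is.null(segs)) {
        row$volumeRecovery <- volumeRecovery(segs[[i]], healthyNominal,
                                             spacing)
        row$dice <- diceIndex(segs[[i]]@mask, truthHealthy)
      }
      row
    })
    metrics <- do.call(rbind, lapply(rows, function(r) {
      miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
      for (m in miss) r[[m]] <- NA
      r
    }))
    f <- file.path(outDir, "metrics.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    manifest[[length(manifest) + 1]] <- .manifestRow(
      basename(f), "runExperiment", config, config$seed)

    stage <- "calibrate"
    sweep <- NULL
    if (!is.null(config$kGrid) && config$kind == "dual") {
      sweep <- sweepPhantom(scans, truthHealthy, labels,
                            grid = config$kGrid, params = params,
                            refActivity = config$refActivity)
      f <- file.path(outDir, "ksweep.csv")
      utils::write.csv(sweep@summary, f, row.names = FALSE)
      manifest[[length(manifest) + 1]] <- .manifestRow(
        basename(f), "sweepPhantom", list(grid = config$kGrid), NA)
      f <- file.path(outDir, "ksweep_selected.json")
      jsonlite::write_json(list(selectedK = selectK(sweep)), f,
                           auto_unbox = TRUE, digits = NA)
      manifest[[length(manifest) + 1]] <- .manifestRow(
        basename(f), "selectK", list(criterion = "ref_activity_error"), NA)
    }
    if (config$kind == "paired" && !is.null(config$kGrid)) {
      sweep <- sweepPaired(fx$scans, labels, grid = config$kGrid,
                           params = params,
                           seg = segmentationParams(config$segSigma,
                                                    if (is.na(alpha)) 0.4
                                                    else alpha))
      f <- file.path(outDir, "ksweep_paired.csv")
      utils::write.csv(sweep@summary, f, row.names = FALSE)
      manifest[[length(manifest) + 1]] <- .manifestRow(
        basename(f), "sweepPaired", list(grid = config$kGrid), NA)
    }
    list(metrics = metrics, sweep = sweep, alpha = alpha)
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  mf <- do.call(rbind, manifest)
  f <- file.path(outDir, "manifest.csv")
  utils::write.csv(mf, f, row.names = FALSE)
  result$manifest <- rbind(mf, .manifestRow(basename(f), "runExperiment",
                                            list(), config$seed))
  result
}
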
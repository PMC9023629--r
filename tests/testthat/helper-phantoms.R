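# Shared fixtures. The mini phantom keeps the full default geometry (all
# compartment shapes in mm) on a coarse 32 x 32 x 24 grid at 9.6 mm with a
# 16-angle orbit, which makes whole-pipeline tests cheap; the acceptance
# tests use the 64^3 desk-scale grid from generateFixtureSeries().

miniGrid <- function() gridGeometry(c(32L, 32L, 24L), 9.6)

miniGeom <- function(nAngles = 16L) acquisitionGeometry(nAngles)

miniLabels <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- buildPhantom(defaultPhantom(miniGrid()), supersample = 4L)
    cache
  }
})

miniAcquisition <- function(ho = 250, tc = 50, seed = NULL,
                            nAngles = 16L, scatter = scatterModel()) {
  ps <- simulateAcquisition(miniLabels(), detectorModel(), scatter,
                            miniGeom(nAngles),
                            activities = c(ho = ho, tc = tc))
  if (!is.null(seed)) ps <- addPoissonNoise(ps, seed)
  ps
}

miniRecon <- function(ps, k = 1.0, iterations = 5L, subsets = 4L,
                      which = "both") {
  reconstructPair(ps, miniLabels(), k = k,
                  params = reconParams(iterations, subsets), which = which)
}

# deterministic per-scan seed expansion, mirroring generateFixtureSeries
scanSeed <- function(seed, i) duospect:::.deriveSeed(seed, i)
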
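test_that("the TEW estimate matches the window-width arithmetic", {
  # hand-computed from the widths 14.16, 20.4 and 21 keV
  expect_equal(tewScatterEstimate(100, 50),
               21 / (2 * 14.16) * 100 + 21 / (2 * 20.4) * 50,
               tolerance = 1e-12)
  expect_equal(tewScatterEstimate(0, 0), 0)
  # equal flanking widths reduce to (W_PP / 2W) * (C_L + C_U)
  w <- list(sc118 = energyWindow("sc118", 100, 0.2),
            tc140 = energyWindow("tc140", 140, 0.15),
            sc170 = energyWindow("sc170", 200, 0.1))
  expect_equal(tewScatterEstimate(30, 70, w), 21 / (2 * 20) * 100,
               tolerance = 1e-12)
  expect_error(tewScatterEstimate(array(0, c(2, 2)), array(0, c(3, 2))),
               "shape")
})

test_that("the DEW estimate scales the 118 keV window by k", {
  x <- array(runif(64), c(4, 4, 4))
  expect_equal(dewScatterEstimate(x, 1), x)
  expect_equal(dewScatterEstimate(200, 0.95), 190)
  expect_error(dewScatterEstimate(x, 0), "positive")
  expect_error(dewScatterEstimate(x, -1), "positive")
})

test_that("DEW at the generative k removes the constructed crosstalk", {
  ps <- miniAcquisition(ho = 0, tc = 50)
  sc <- dewScatterEstimate(counts(ps)[, , , "sc118"], scatterModel()@kTrue)
  expect_equal(sc, counts(ps)[, , , "ho81"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("MLEM fixed points are reached on scalar systems", {
  # one voxel seen identically by 4 angles, A = 1, no attenuation
  y <- array(10, c(1, 1, 4))
  geom <- c(0, pi / 2, pi, 3 * pi / 2)
  r <- osemReconstruct(y, NULL, NULL, geom, spacing = c(1, 1, 1),
                       params = reconParams(iterations = 1, subsets = 1))
  expect_equal(as.numeric(imageData(r)), 10, tolerance = 1e-9)
  # additive scatter: converges to the x solving A x + s = y
  s <- array(5, c(1, 1, 4))
  r <- osemReconstruct(y, s, NULL, geom, spacing = c(1, 1, 1),
                       params = reconParams(iterations = 60, subsets = 1))
  expect_equal(as.numeric(imageData(r)), 5, tolerance = 1e-6)
})

test_that("OSEM with one subset matches dense-matrix MLEM", {
  # tiny instance: 8 x 8 single-slice grid, 4 angles, no PSF
  d <- c(8L, 8L, 1L)
  angles <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  sp <- c(4.8, 4.8, 4.8)
  mu <- array(0.12, d)
  set.seed(5)
  xtrue <- array(runif(prod(d), 0.5, 2), d)
  y <- forwardProject(xtrue, mu, angles, spacing = sp)
  # dense system matrix, column by column
  A <- vapply(seq_len(prod(d)), function(j) {
    e <- array(0, d); e[j] <- 1
    as.vector(forwardProject(e, mu, angles, spacing = sp))
  }, numeric(8 * 1 * 4))
  yv <- as.vector(y)
  x <- rep(1, prod(d))
  sens <- colSums(A)
  for (it in 1:10)
    x <- x * as.vector(crossprod(A, yv / (A %*% x + 1e-12))) / sens
  r <- osemReconstruct(y, NULL, mu, angles, spacing = sp,
                       params = reconParams(iterations = 10, subsets = 1))
  expect_lt(max(abs(as.vector(imageData(r)) - x)) / max(x), 1e-8)
})

test_that("the Poisson log-likelihood is non-decreasing under MLEM", {
  lab <- miniLabels()
  ps <- miniAcquisition(ho = 0, tc = 40, seed = 31L, nAngles = 8L)
  y <- counts(ps)[, , , "tc140"]
  mu <- attenuationMap(lab, 140)
  ang <- orbitAngles(miniGeom(8L))
  r <- osemReconstruct(y, NULL, mu, ang, spacing = voxelSpacing(lab),
                       params = reconParams(iterations = 8, subsets = 1),
                       psfSigma = 5, keepIterates = TRUE)
  ll <- vapply(r@provenance$iterates, function(x) {
    f <- forwardProject(x, mu, ang, spacing = voxelSpacing(lab),
                        psfSigma = 5) + 1e-12
    sum(y * log(f) - f)
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-7 * abs(ll[-1])))
  # nonnegativity at every iterate
  expect_true(all(vapply(r@provenance$iterates,
                         function(x) min(x) >= 0, logical(1))))
})

test_that("a matched reconstruction is a fixed point of further updates", {
  # noiseless projections of a known map with exact scatter: starting OSEM
  # from the truth changes nothing
  d <- c(16L, 16L, 4L)
  sp <- c(6, 6, 6)
  set.seed(8)
  xtrue <- array(0, d)
  xtrue[5:12, 5:12, 2:3] <- runif(8 * 8 * 2, 1, 3)
  mu <- array(0, d); mu[3:14, 3:14, ] <- 0.1
  angles <- seq(0, 2 * pi, length.out = 9)[1:8]
  y <- forwardProject(xtrue, mu, angles, spacing = sp)
  s <- 0.2 * y
  # data y + s equal A x + s exactly, so the MLEM update at the truth is
  # the identity (checked in dense form)
  A <- vapply(seq_len(prod(d)), function(j) {
    e <- array(0, d); e[j] <- 1
    as.vector(forwardProject(e, mu, angles, spacing = sp))
  }, numeric(16 * 4 * 8))
  xv <- as.vector(xtrue)
  sens <- colSums(A)
  upd <- xv * as.vector(crossprod(A, as.vector(y + s) /
                                      (A %*% xv + as.vector(s) + 1e-12)))
  upd[sens > 0] <- upd[sens > 0] / sens[sens > 0]
  expect_equal(upd[sens > 0], xv[sens > 0], tolerance = 1e-9)
})

test_that("reconstructPair applies DEW to Ho and TEW to Tc", {
  lab <- miniLabels()
  params <- reconParams(iterations = 5, subsets = 4)
  # Tc-only data reconstructed with k = k_true leaves a Ho image that is
  # a small fraction of what an uncorrected reconstruction retains
  ps <- miniAcquisition(ho = 0, tc = 80)
  r <- miniRecon(ps, k = scatterModel()@kTrue)
  uncorr <- osemReconstruct(counts(ps)[, , , "ho81"], NULL,
                            attenuationMap(lab, 81), ps@geometry,
                            voxelSpacing(lab), params, psfSigma = 5)
  expect_lt(sum(imageData(r$ho)), 0.05 * sum(imageData(uncorr)))
  # Ho-only data with TEW-consistent coefficients leaves a near-zero Tc
  # image (the default continuum is built to be TEW-exact at 140 keV)
  ps <- miniAcquisition(ho = 250, tc = 0)
  r <- miniRecon(ps)
  uncorr <- osemReconstruct(counts(ps)[, , , "tc140"], NULL,
                            attenuationMap(lab, 140), ps@geometry,
                            voxelSpacing(lab), params, psfSigma = 5)
  expect_lt(sum(imageData(r$tc)), 0.05 * sum(imageData(uncorr)))
  # dual input: both images populated and nonnegative
  ps <- miniAcquisition(ho = 250, tc = 50, seed = 77L)
  r <- miniRecon(ps)
  expect_gt(sum(imageData(r$ho)), 0)
  expect_gt(sum(imageData(r$tc)), 0)
  expect_gte(min(imageData(r$ho)), 0)
  expect_gte(min(imageData(r$tc)), 0)
  # missing windows are reported by name
  broken <- ps
  dimnames(broken@counts)[[4]][2] <- "other"
  expect_error(reconstructPair(broken, miniLabels()), "sc118")
})

test_that("the healthy-liver Ho value is non-increasing in k", {
  ps <- miniAcquisition(ho = 250, tc = 100, seed = 13L)
  lab <- miniLabels()
  vals <- vapply(c(0.65, 0.9, 1.15, 1.30), function(k) {
    r <- miniRecon(ps, k = k, which = "ho")
    countDensity(r$ho, lab@fractions$liver)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("reconstruction parameter validation catches bad settings", {
  expect_error(reconParams(iterations = 0), "iterations")
  expect_error(reconParams(scatterMode = "dew", k = 0), "k-factor")
  ps <- miniAcquisition(ho = 0, tc = 10)
  y <- counts(ps)[, , , "tc140"]
  expect_error(osemReconstruct(y, NULL, NULL, miniGeom(16L),
                               spacing = rep(9.6, 3),
                               params = reconParams(subsets = 5)),
               "divide")
  yneg <- y; yneg[1] <- -1
  expect_error(osemReconstruct(yneg, NULL, NULL, miniGeom(16L),
                               spacing = rep(9.6, 3)), "negative")
})
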
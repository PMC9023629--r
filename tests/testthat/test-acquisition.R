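test_that("energy window bounds and widths follow the centre/width rule", {
  w <- defaultEnergyWindows()
  expect_equal(unname(windowBounds(w$tc140)), c(129.5, 150.5))
  expect_equal(unname(windowBounds(w$sc118)), c(110.92, 125.08))
  expect_equal(windowWidthKeV(w$sc118), 14.16)
  expect_equal(windowWidthKeV(w$sc170), 20.4)
  expect_equal(windowWidthKeV(w$tc140), 21)
  expect_error(energyWindow("bad", 100, 0), "width")
  expect_error(energyWindow("bad", 100, 2), "width")
})

test_that("the projector conserves counts, is linear and attenuates", {
  # uniform cube, no attenuation, no PSF: every angle sums to the total
  vol <- array(0, c(24, 24, 8))
  vol[9:16, 9:16, 3:6] <- 2.5
  angles <- seq(0, 2 * pi, length.out = 13)[1:12]
  p <- forwardProject(vol, NULL, angles, spacing = c(4, 4, 4))
  sums <- apply(p, 3, sum)
  expect_lt(max(abs(sums / sum(vol) - 1)), 0.003)
  # linearity
  p2 <- forwardProject(2 * vol, NULL, angles, spacing = c(4, 4, 4))
  expect_equal(p2, 2 * p, tolerance = 1e-12)
  # Beer-Lambert: point source behind a uniform slab, angle 0
  vol <- array(0, c(24, 24, 8))
  vol[12, 6, 4] <- 10
  mu <- array(0, c(24, 24, 8))
  mu[12, 7:12, 4] <- 0.1                      # 6 voxels of 4 mm = 2.4 cm
  p <- forwardProject(vol, mu, 0, spacing = c(4, 4, 4))
  expect_equal(sum(p), 10 * exp(-0.1 * 2.4), tolerance = 1e-12)
  expect_error(forwardProject(array(NaN, c(16, 16, 4)), NULL, 0,
                              spacing = c(4, 4, 4)), "NaN")
})

test_that("the back projector is the exact adjoint of the projector", {
  set.seed(99)
  d <- c(20L, 20L, 6L)
  angles <- c(0.3, 1.1, 2.5, 4.0)
  mu <- array(runif(prod(d), 0, 0.02), d)
  x <- array(runif(prod(d)), d)
  p <- array(runif(20 * 6 * 4), c(20, 6, 4))
  for (psf in c(0, 6)) {
    Ax <- forwardProject(x, mu, angles, spacing = c(5, 5, 5), psfSigma = psf)
    Atp <- backProject(p, mu, angles, dim = d, spacing = c(5, 5, 5),
                       psfSigma = psf)
    expect_equal(sum(Ax * p), sum(x * Atp), tolerance = 1e-12)
  }
})

test_that("window crosstalk is generated as constructed", {
  sc <- scatterModel()
  # Tc-only: the Ho windows hold only crosstalk with the k_true ratio,
  # and nothing reaches the 170 keV window
  ps <- miniAcquisition(ho = 0, tc = 50)
  cnt <- counts(ps)
  expect_equal(cnt[, , , "ho81"], sc@kTrue * cnt[, , , "sc118"],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(cnt[, , , "sc170"]), 0)
  # Ho-only: window ratios follow the contamination coefficients
  ps <- miniAcquisition(ho = 250, tc = 0)
  cnt <- counts(ps)
  expect_equal(sum(cnt[, , , "sc118"]) / sum(cnt[, , , "sc170"]),
               unname(sc@cHo["118"] / sc@cHo["170"]), tolerance = 1e-9)
  # dual: all four windows populated, 170 keV independent of Tc
  dual <- miniAcquisition(ho = 250, tc = 50)
  expect_true(all(apply(counts(dual), 4, sum) > 0))
  expect_equal(counts(dual)[, , , "sc170"], cnt[, , , "sc170"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("expected counts are additive and linear across isotopes", {
  both <- counts(miniAcquisition(ho = 250, tc = 50))
  hoOnly <- counts(miniAcquisition(ho = 250, tc = 0))
  tcOnly <- counts(miniAcquisition(ho = 0, tc = 50))
  expect_equal(both, hoOnly + tcOnly, tolerance = 1e-9)
  twice <- counts(miniAcquisition(ho = 0, tc = 100))
  expect_equal(twice, 2 * tcOnly, tolerance = 1e-9)
  expect_error(simulateAcquisition(miniLabels(),
                                   activities = c(xe = 1)), "isotope")
})

test_that("Poisson noise is reproducible and has the right moments", {
  ps <- miniAcquisition(ho = 0, tc = 30)
  a <- addPoissonNoise(ps, 123L)
  b <- addPoissonNoise(ps, 123L)
  expect_identical(counts(a), counts(b))
  expect_false(identical(counts(a), counts(addPoissonNoise(ps, 124L))))
  expect_true(all(counts(a) == round(counts(a))))
  expect_identical(a@provenance$seed, 123L)
  # zero expectation stays zero
  expect_equal(sum(counts(a)[, , , "sc170"]), 0)
  # 1000 independent draws of a bin with expectation 100: the sample mean
  # stays within 3 sigma of 100
  lam <- ps
  lam@counts[] <- 100
  draws <- as.vector(counts(addPoissonNoise(lam, 555L)))[1:1000]
  expect_lt(abs(mean(draws) - 100), 3 * 10 / sqrt(1000))
})

test_that("noiseless sets round-trip the container format exactly", {
  ps <- miniAcquisition(ho = 250, tc = 50)
  psn <- addPoissonNoise(ps, 7L)
  f <- tempfile(fileext = ".nii.gz")
  writeProjectionSet(psn, f)
  back <- readProjectionSet(f)
  expect_identical(counts(back), counts(psn))
  expect_equal(back@geometry@nAngles, psn@geometry@nAngles)
  expect_equal(back@provenance$activities, psn@provenance$activities)
  expect_equal(vapply(back@windows, windowWidthKeV, numeric(1)),
               vapply(psn@windows, windowWidthKeV, numeric(1)))
  unlink(c(f, sub("\\.nii\\.gz$", ".json", f)))
})
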
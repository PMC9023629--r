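test_that("the threshold is a fraction of the smoothed maximum", {
  sp <- c(4, 4, 4)
  # constant image: threshold = alpha * c, mask covers everything
  img <- array(3, c(16, 16, 16))
  r <- segmentLiver(img, segmentationParams(sigma = 10, alpha = 0.4),
                    spacing = sp)
  expect_equal(r@threshold, 0.4 * 3, tolerance = 1e-9)
  expect_equal(sum(r@mask), 16^3)
  # sigma 0 reduces to a plain maximum threshold
  img <- array(runif(16^3), c(16, 16, 16))
  r <- segmentLiver(img, segmentationParams(sigma = 0, alpha = 0.5),
                    spacing = sp)
  expect_equal(r@threshold, 0.5 * max(img))
  expect_equal(sum(r@mask), sum(img >= 0.5 * max(img)))
  expect_error(segmentLiver(array(0, c(8, 8, 8)), spacing = sp), "zero")
})

test_that("a noiseless liver step image is recovered within 5 percent", {
  lab <- miniLabels()
  img <- (lab@fractions$liver >= 0.5) * 1.0
  nominal <- sum(img) * voxelVolumeML(lab)
  r <- segmentLiver(img, segmentationParams(sigma = 8, alpha = 0.4),
                    spacing = voxelSpacing(lab))
  vol <- sum(r@mask) * voxelVolumeML(lab)
  expect_lt(abs(vol - nominal) / nominal, 0.05)
})

test_that("segmented volume is non-increasing in alpha and scale-free", {
  set.seed(21)
  img <- array(rexp(16^3), c(16, 16, 16))
  sp <- c(5, 5, 5)
  vols <- vapply(seq(0.05, 0.95, by = 0.06), function(a)
    sum(segmentLiver(img, segmentationParams(10, a), spacing = sp)@mask),
    numeric(1))
  expect_true(all(diff(vols) <= 0))
  # multiplying the image by a positive constant leaves the mask unchanged
  r1 <- segmentLiver(img, segmentationParams(10, 0.4), spacing = sp)
  r2 <- segmentLiver(img * 37.5, segmentationParams(10, 0.4), spacing = sp)
  expect_identical(r1@mask, r2@mask)
})

test_that("alpha calibration hits the nominal volume where achievable", {
  lab <- miniLabels()
  sp <- voxelSpacing(lab)
  img <- (lab@fractions$liver >= 0.5) * 1.0
  trueVol <- sum(img) * voxelVolumeML(lab)
  # binary image: any alpha on the plateau works, the midpoint is returned
  a <- calibrateAlpha(img, trueVol, sigma = 0, spacing = sp)
  expect_equal(a, 0.5, tolerance = 0.01)
  seg <- segmentLiver(img, segmentationParams(0, a), spacing = sp)
  expect_equal(sum(seg@mask) * voxelVolumeML(lab), trueVol)
  # nominal beyond the support volume is rejected with the range
  expect_error(calibrateAlpha(img, 1e6, sigma = 0, spacing = sp),
               "achievable range")
  expect_error(calibrateAlpha(img, -5, sigma = 0, spacing = sp), "positive")
})

test_that("calibration is noise-stable on reconstructed Tc images", {
  ps0 <- miniAcquisition(ho = 0, tc = 126)
  noiseless <- miniRecon(ps0, which = "tc")$tc
  noisy <- miniRecon(addPoissonNoise(ps0, 400L), which = "tc")$tc
  a0 <- calibrateAlpha(noiseless, 1205, sigma = 15)
  a1 <- calibrateAlpha(noisy, 1205, sigma = 15)
  expect_lt(abs(a1 - a0), 0.10)
})

test_that("alpha averaging is the arithmetic mean", {
  expect_equal(averageAlpha(c(0.38, 0.42)), 0.40)
  expect_equal(averageAlpha(0.55), 0.55)
  expect_error(averageAlpha(numeric(0)), "empty")
})

test_that("sigma selection minimises the volume variance", {
  lab <- miniLabels()
  sp <- voxelSpacing(lab)
  img <- (lab@fractions$liver >= 0.5) * 1.0
  nominal <- sum(img) * voxelVolumeML(lab)
  # identical images: zero variance everywhere, smallest sigma wins
  out <- selectSigma(list(
    new("SpectImage", data = img, spacing = sp, isotope = "tc",
        provenance = list()),
    new("SpectImage", data = img, spacing = sp, isotope = "tc",
        provenance = list())), nominal, sigmaGrid = c(20, 10, 15))
  expect_equal(out$sigma, 10)
  expect_true(all(out$table$varVolume == 0))
  # grid of one element returns that element
  expect_equal(selectSigma(list(
    new("SpectImage", data = img, spacing = sp, isotope = "tc",
        provenance = list()),
    new("SpectImage", data = img, spacing = sp, isotope = "tc",
        provenance = list())), nominal, sigmaGrid = 12)$sigma, 12)
  expect_error(selectSigma(list(), nominal, c(10, 15)), "2 images")
})

test_that("smoothing reduces the volume variance of noisy segmentations", {
  imgs <- lapply(1:3, function(i)
    miniRecon(miniAcquisition(ho = 0, tc = 80, seed = 600L + i),
              which = "tc")$tc)
  out <- selectSigma(imgs, 1205, sigmaGrid = c(0, 15))
  tab <- out$table
  expect_lt(tab$varVolume[tab$sigma == 15], tab$varVolume[tab$sigma == 0])
})

test_that("cold spheres are recovered as holes of the liver component", {
  lab <- buildPhantom(defaultPhantom(), 4L)   # 4.8 mm grid
  healthy <- (lab@fractions$liver >= 0.5) * 1L
  centers <- rbind(S1 = c(0, 20, 0), S2 = c(55, 38, 0))
  out <- extractColdSpheres(healthy, voxelSpacing(lab), centers)
  expect_equal(nrow(out$table), 2)
  expect_equal(out$table$matched, c("S1", "S2"))
  # voxelization tolerance on a 4.8 mm grid
  expect_lt(abs(out$table$volumeML[1] - 24.2) / 24.2, 0.08)
  expect_lt(abs(out$table$volumeML[2] - 15.7) / 15.7, 0.08)
  expect_lt(max(abs(out$table[1, c("cx", "cy", "cz")] - centers[1, ])), 4.8)
  expect_length(out$unmatched, 0)
  # a solid ellipsoid has no holes
  sp <- voxelSpacing(miniLabels())
  solid <- array(0L, dim(miniLabels()))
  solid[8:24, 8:24, 8:16] <- 1L
  out <- extractColdSpheres(solid, sp)
  expect_equal(nrow(out$table), 0)
  # a cavity cut open to the boundary cannot be recovered and is flagged
  opened <- solid
  opened[14:18, 14:18, 8:16] <- 0L
  out <- extractColdSpheres(opened, sp, centers = rbind(c1 = c(0, 0, 0)))
  expect_true("c1" %in% out$unmatched)
})
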
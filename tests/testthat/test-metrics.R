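test_that("ball erosion shrinks a sphere by its radius", {
  sp <- c(4, 4, 4)
  grid <- gridGeometry(32L, 4)
  lab <- buildPhantom(phantomSpec(grid, list(
    sphereCompartment("s", c(0, 0, 0), 30))), 4L)
  m <- lab@fractions$s >= 0.5
  er <- erodeVoi(m, 10, sp)
  vol <- sum(er) * prod(sp) / 1000
  expect_lt(abs(vol - 4 / 3 * pi * 2^3) / (4 / 3 * pi * 2^3), 0.15)
  # radius 0 is the identity
  expect_identical(erodeVoi(m, 0, sp), array(as.integer(m), dim(m)))
  # erosion larger than the object empties it
  expect_error(erodeVoi(m, 40, sp), "empties")
})

test_that("COV uses the population standard deviation in percent", {
  img <- array(0, c(16, 16, 4))
  voi <- array(0, c(16, 16, 4))
  voi[1:2, 1, 1] <- 1
  img[1, 1, 1] <- 90; img[2, 1, 1] <- 110
  expect_equal(imageCOV(img, voi), 10)
  expect_equal(imageCOV(array(7, c(16, 16, 4)), array(1, c(16, 16, 4))), 0)
  expect_error(imageCOV(img, array(0, c(16, 16, 4))), "empty")
})

test_that("contrast recovery follows the Q definition", {
  img <- array(1, c(8, 8, 8))
  s <- array(0, c(8, 8, 8)); s[3:4, 3:4, 3:4] <- 1
  b <- array(0, c(8, 8, 8)); b[6:8, 6:8, 6:8] <- 1
  # cold sphere measured empty: Q = 100
  cold <- img; cold[s == 1] <- 0
  expect_equal(contrastRecovery(cold, s, b, 0)$Q, 100)
  # no contrast at all: Q = 0
  expect_equal(contrastRecovery(img, s, b, 0)$Q, 0)
  # hot sphere at the nominal ratio: Q = 100
  hot <- img; hot[s == 1] <- 10
  expect_equal(contrastRecovery(hot, s, b, 10)$Q, 100)
  # invariant under global intensity scaling
  expect_equal(contrastRecovery(hot * 123, s, b, 10)$Q,
               contrastRecovery(hot, s, b, 10)$Q)
  expect_error(contrastRecovery(img, s, b, 1), "R = 1")
})

test_that("Dice handles identity, disjointness and partial overlap", {
  a <- array(0, c(8, 8, 2)); a[1:4, , ] <- 1
  expect_equal(diceIndex(a, a), 1)
  b <- array(0, c(8, 8, 2)); b[5:8, , ] <- 1
  expect_equal(diceIndex(a, b), 0)
  # equal-volume masks sharing half their voxels
  c1 <- array(0, c(8, 8, 2)); c1[3:6, , ] <- 1
  expect_equal(diceIndex(a, c1), 0.5)
  expect_equal(diceIndex(array(0, c(4, 4, 1)), array(0, c(4, 4, 1))), 1)
  expect_error(diceIndex(a, array(0, c(4, 4, 1))), "grid")
  # intensity changes do not matter, only the binarized masks do
  expect_equal(diceIndex(a * 0.7 + 0.3, a), 1)
})

test_that("volume recovery relates mask volume to the nominal volume", {
  sp <- c(4.8, 4.8, 4.8)
  m <- array(0, c(16, 16, 16)); m[1:10, 1:10, 1:10] <- 1
  vol <- 1000 * prod(sp) / 1000
  expect_equal(volumeRecovery(m, vol, sp), 100)
  expect_equal(volumeRecovery(array(0, c(8, 8, 8)), 100, sp), 0)
  expect_error(volumeRecovery(m, 0, sp), "positive")
  lab <- miniLabels()
  expect_lt(abs(volumeRecovery(lab@fractions$liver, 1205,
                               voxelSpacing(lab)) - 100), 2)
})

test_that("count density is the weighted mean per mL and is linear", {
  sp <- c(4.8, 4.8, 4.8)
  u <- prod(sp) / 1000
  img <- array(3, c(8, 8, 8))
  voi <- array(0, c(8, 8, 8)); voi[2:5, 2:5, 2:5] <- 1
  expect_equal(countDensity(img, voi, sp), 3 / u)
  expect_equal(countDensity(img * 2, voi, sp), 2 * countDensity(img, voi, sp))
  expect_equal(countDensity(array(0, c(8, 8, 8)), voi, sp), 0)
  expect_error(countDensity(img, array(0, c(8, 8, 8)), sp), "empty")
})

test_that("percent difference keeps the paired sign convention", {
  expect_equal(percentDifference(100, 100), 0)
  expect_equal(percentDifference(101, 100), 1)
  expect_equal(percentDifference(87.1, 100), -12.9)
  expect_error(percentDifference(5, 0), "nonzero")
})

test_that("the COV offset fit inverts noiseless data exactly", {
  A <- c(8, 16, 30, 60, 120, 240)
  covs <- sqrt(400 / A + 3.8^2)
  fit <- fitCovOffset(A, covs)
  expect_equal(fit$a, 400, tolerance = 1e-3)
  expect_equal(fit$b, 3.8, tolerance = 1e-3)
  expect_lt(fit$rms, 1e-6)
  # constant data: pure offset
  fit <- fitCovOffset(A, rep(5, 6))
  expect_lt(fit$a, 1e-4)
  expect_equal(fit$b, 5, tolerance = 1e-4)
  expect_error(fitCovOffset(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fitCovOffset(c(1, 2), c(1, 2)), "3 points")
})

test_that("the Welch test matches its textbook behaviour", {
  out <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  out <- welchTest(c(1, 2, 3), c(101, 102, 103))
  expect_lt(out$p, 0.01)
  # swapping the groups negates t and keeps p
  a <- c(4.2, 5.1, 4.8, 5.6); b <- c(5.0, 5.9, 6.1, 5.4)
  o1 <- welchTest(a, b); o2 <- welchTest(b, a)
  expect_equal(o1$t, -o2$t)
  expect_equal(o1$p, o2$p)
  # agreement with the stats implementation it wraps
  ref <- t.test(a, b)
  expect_equal(o1$t, unname(ref$statistic))
  expect_equal(o1$p, ref$p.value)
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})
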
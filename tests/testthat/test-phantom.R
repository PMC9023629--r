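test_that("supersampled voxelization recovers analytic sphere volumes", {
  grid <- gridGeometry(32L, 2.4)
  spec <- phantomSpec(grid, list(
    sphereCompartment("s", c(0, 0, 0), 17.9, activity = c(ho = 1))))
  lab <- buildPhantom(spec, supersample = 4L)
  analytic <- 4 / 3 * pi * 1.79^3   # mL
  recovered <- sum(lab@fractions$s) * voxelVolumeML(lab)
  expect_lt(abs(recovered - analytic) / analytic, 0.01)

  # volume error shrinks (non-strictly) as the supersampling grows
  errs <- vapply(c(2L, 4L, 8L), function(ss) {
    l <- buildPhantom(spec, ss)
    abs(sum(l@fractions$s) * voxelVolumeML(l) - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("an empty compartment list yields all-zero volumes", {
  lab <- buildPhantom(phantomSpec(gridGeometry(16L, 4.8), list()), 2L)
  expect_length(lab@fractions, 0)
})

test_that("the default phantom carves the spheres out of the liver", {
  lab <- miniLabels()
  vv <- voxelVolumeML(lab)
  healthy <- sum(lab@fractions$liver) * vv
  expect_lt(abs(healthy - 1205) / 1205, 0.01)
  expect_lt(abs(sum(lab@fractions$S1) * vv - 24.2) / 24.2, 0.01)
  expect_lt(abs(sum(lab@fractions$S2) * vv - 15.7) / 15.7, 0.02)
  # occupancies sum to <= 1 everywhere, = 1 inside the body
  tot <- Reduce(`+`, lab@fractions)
  expect_lte(max(tot), 1 + 1e-9)
  inside <- lab@fractions$torso == 1
  expect_equal(max(abs(tot[inside] - 1)), 0)
})

test_that("a compartment reaching outside the grid is rejected by name", {
  spec <- phantomSpec(gridGeometry(16L, 4.8), list(
    sphereCompartment("huge", c(0, 0, 0), 60)))
  expect_error(buildPhantom(spec), "huge")
})

test_that("activity maps spread compartment activity uniformly", {
  grid <- miniGrid()
  liver <- ellipsoidCompartment("liver", c(0, 0, 0), c(82, 66, 54.91),
                                activity = c(ho = 250))
  lab <- buildPhantom(phantomSpec(grid, list(liver)), 4L)
  am <- activityMap(lab, "ho")
  full <- imageData(am)[lab@fractions$liver == 1]
  expect_equal(max(full), min(full))
  expect_equal(mean(full), 250 / (4 / 3 * pi * prod(c(82, 66, 54.91)) / 1000),
               tolerance = 1e-6)
  # total integrated activity is conserved
  expect_equal(sum(imageData(am)) * voxelVolumeML(am), 250, tolerance = 0.01)
  # absent isotope: zero map
  expect_equal(sum(imageData(activityMap(lab, "tc"))), 0)
})

test_that("the sphere concentration is tenfold the healthy-liver one", {
  lab <- miniLabels()
  am <- imageData(activityMap(lab, "ho"))
  cLiver <- mean(am[lab@fractions$liver == 1])
  cS1 <- mean(am[lab@fractions$S1 == 1])
  expect_equal(cS1 / cLiver, 10, tolerance = 1e-3)
})

test_that("activity fractions follow the printed volumes and 10:1 ratio", {
  spec <- defaultPhantom()
  fr <- activityFractions(spec, "ho")
  expect_equal(sum(fr), 100)
  expect_equal(unname(fr["S1"]), 100 * 242 / (1205 + 242 + 157),
               tolerance = 1e-10)
  # single compartment holds everything
  one <- phantomSpec(miniGrid(), list(
    sphereCompartment("s", c(0, 0, 0), 20, activity = c(ho = 5))))
  expect_equal(unname(activityFractions(one, "ho")), 100)
  # two equal compartments at equal concentration split evenly
  two <- phantomSpec(miniGrid(), list(
    sphereCompartment("a", c(-40, 0, 0), 20, activity = c(ho = 5)),
    sphereCompartment("b", c(40, 0, 0), 20, activity = c(ho = 5))))
  expect_equal(unname(activityFractions(two, "ho")), c(50, 50))
  expect_error(activityFractions(one, "tc"), "zero")
})

test_that("attenuation maps mix class coefficients and fall with energy", {
  lab <- miniLabels()
  mu140 <- imageData(attenuationMap(lab, 140))
  expect_equal(max(mu140), 0.153, tolerance = 1e-9)
  mu81 <- imageData(attenuationMap(lab, 81))
  expect_gt(max(mu81), max(mu140))
  # lungs are 0.3 x water
  lungIdx <- lab@fractions$lung_l == 1
  expect_equal(unique(round(mu140[lungIdx], 6)), round(0.3 * 0.153, 6))
  # air outside the torso
  outside <- Reduce(`+`, lab@fractions) == 0
  expect_equal(max(mu140[outside]), 0)
  expect_error(attenuationMap(lab, 500), "range")
  # an all-air phantom attenuates nothing
  airLab <- buildPhantom(phantomSpec(miniGrid(), list(
    sphereCompartment("void", c(0, 0, 0), 30,
                      attenuationClass = "air"))), 2L)
  expect_equal(max(imageData(attenuationMap(airLab, 140))), 0)
})

test_that("grid and compartment validity is enforced", {
  expect_error(gridGeometry(8L, 4.8), "16")
  expect_error(gridGeometry(64L, -1), "positive")
  expect_error(sphereCompartment("s", c(0, 0, 0), -5), "positive")
  expect_error(sphereCompartment("s", c(0, 0, 0), 5, activity = c(ho = -1)),
               ">= 0")
  expect_error(ellipsoidCompartment("e", c(0, 0, 0), c(10, 10, 10),
                                    attenuationClass = "bone"),
               "attenuation class")
})
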
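test_that("OOF response is zero on constant images and linear in contrast", {
  expect_lt(max(abs(oofResponse(matrix(4.2, 40, 40), 10, 2.5))), 1e-12)
  set.seed(21)
  img <- matrix(rnorm(900), 30, 30)
  r1 <- oofResponse(img, 8, 2.5)
  r3 <- oofResponse(3 * img, 8, 2.5)
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("the argmax radius tracks the band half-width", {
  px <- 2.5
  tc <- threeClassPhantom(px)
  img <- tc$phantom@vesselMask * 1
  oof <- oofMultiscale(img, oofScaleSet(seq(4, 40, 2), px))
  centerRows <- round(c(0.08, 0.22, 0.36) * 1e3 / px)
  trueR <- c(6, 15, 24)
  for (i in 1:3) {
    got <- median(oof$radius[centerRows[i], 40:215])
    expect_lte(abs(got - trueR[i]), 2)   # within one 2-um scale step
  }
  # 30-um band: centreline argmax in [13, 17]
  got30 <- oof$radius[centerRows[2], 40:215]
  expect_true(all(got30 >= 13 & got30 <= 17))
})

test_that("two disjoint bands give distinct argmax plateaus", {
  px <- 2.5
  ph <- buildPhantom(list(straightVessel(0.10, 12, 1),
                          straightVessel(0.30, 60, 1)), px, c(180, 256))
  oof <- oofMultiscale(ph@vesselMask * 1, oofScaleSet(seq(4, 40, 2), px))
  r12 <- median(oof$radius[round(100 / px), 40:215])
  r60 <- median(oof$radius[round(300 / px), 40:215])
  expect_lte(abs(r12 - 6), 2)
  expect_lte(abs(r60 - 30), 2)
})

test_that("doubling the tube width doubles the argmax radius", {
  px <- 2.5
  for (w in c(16, 32)) {
    ph <- buildPhantom(list(straightVessel(0.2, w, 1)), px, c(160, 256))
    oof <- oofMultiscale(ph@vesselMask * 1, oofScaleSet(seq(4, 40, 2), px))
    got <- median(oof$radius[round(200 / px), 40:215])
    expect_lte(abs(got - w / 2), 2)
  }
})

test_that("inverted-contrast bands score non-positive on the centreline", {
  px <- 2.5
  ph <- buildPhantom(list(straightVessel(0.2, 30, 1)), px, c(160, 256))
  dark <- 1 - ph@vesselMask
  resp <- oofResponse(dark, 15, px)
  expect_true(all(resp[round(200 / px), 40:215] <= 0))
})

test_that("the FFT response equals direct circle-flux integration", {
  set.seed(22)
  img <- matrix(rnorm(64 * 64), 64, 64)
  img[20:28, ] <- img[20:28, ] + 4          # a band plus noise
  for (r in c(6, 12, 25)) {
    fast <- oofResponse(img, r, 2.5)
    slow <- oofResponseOracle(img, r, 2.5)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-6)
  }
})

test_that("a single-scale set returns that scale everywhere", {
  set.seed(23)
  img <- matrix(rnorm(400), 20, 20)
  expect_warning(oof <- oofMultiscale(img, oofScaleSet(c(1, 7), 2.5)),
                 "below one pixel")
  expect_true(all(oof$radius == 7))
})

test_that("segmentation covers phantom vessels and stays off background", {
  px <- 2.5
  tc <- threeClassPhantom(px)
  m <- tc$phantom@vesselMask
  oof <- oofMultiscale(m * 1, oofScaleSet(seq(4, 40, 2), px))
  seg <- segmentVessels(oof$response, px, globalQ = 0.8)
  # all centrelines inside the mask
  for (y in c(0.08, 0.22, 0.36))
    expect_true(all(seg@mask[round(y * 1e3 / px), 40:215]))
  # few false positives far from the vessels
  far <- matrix(FALSE, 180, 256); far[165:180, ] <- TRUE
  expect_lt(mean(seg@mask[far]), 0.02)
})

test_that("degenerate responses yield empty masks", {
  expect_warning(seg <- segmentVessels(matrix(1, 30, 30), 5), "constant")
  expect_false(any(seg@mask))
  set.seed(24)
  noise <- matrix(rnorm(200 * 200), 200, 200)
  oof <- oofMultiscale(noise, oofScaleSet(seq(6, 20, 2), 5))
  seg <- segmentVessels(oof$response, 5, globalQ = 0.8, minArea = 1)
  # global stage alone keeps 20%; the AND with the local stage cannot grow it
  expect_lte(mean(seg@mask), 0.2 + 0.01)
})

test_that("PSF calibration subtracts in quadrature with a floor", {
  cal <- calibrateDiameter(20.73, 5.5)
  expect_equal(round(as.numeric(cal), 2), 19.99)
  expect_false(attr(cal, "floored"))
  expect_equal(as.numeric(calibrateDiameter(17, 0)), 17)
  low <- calibrateDiameter(4, 5.5, minFloor = 2.5)
  expect_equal(as.numeric(low), 2.5)
  expect_true(attr(low, "floored"))
})

test_that("diameter classes follow the half-open 20/40 um boundaries", {
  expect_equal(as.character(classifyDiameter(19.9)), "capillary")
  expect_equal(as.character(classifyDiameter(20.0)), "medium")
  expect_equal(as.character(classifyDiameter(39.999)), "medium")
  expect_equal(as.character(classifyDiameter(40.0)), "major")
  expect_equal(as.character(classifyDiameter(c(12, 30, 48))),
               c("capillary", "medium", "major"))
  expect_error(classifyDiameter(0), "positive")
  expect_error(classifyDiameter(-3), "positive")
})

test_that("diameter maps assign twice the argmax radius on mask pixels", {
  px <- 2.5
  ph <- buildPhantom(list(straightVessel(0.2, 30, 1)), px, c(160, 256))
  oof <- oofMultiscale(ph@vesselMask * 1, oofScaleSet(seq(4, 40, 2), px))
  seg <- segmentVessels(oof$response, px)
  dm <- diameterFromOOF(oof, seg)
  d <- diameterMatrix(dm$diameterMap)
  expect_true(all(is.na(d[!seg@mask])))
  expect_true(all(d[seg@mask] == 2 * oof$radius[seg@mask]))
  expect_false(dm$diameterMap@calibrated)
  row <- round(200 / px)
  expect_true(all(classMatrix(dm$classMap)[row, 40:215] ==
                    diameterClassLevels()[["medium"]]))
})
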
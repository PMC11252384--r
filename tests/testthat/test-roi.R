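test_that("a 5-mm circular ROI has the canonical 19.63 mm^2 area", {
  roi <- circularROI(c(2.6, 2.6), 5, c(520, 520), 10)
  expect_equal(roiArea(roi), pi * 2.5^2, tolerance = 0.005)
  expect_equal(round(roiArea(roi), 2), 19.63, tolerance = 0.005 * 19.63)
})

test_that("pixelized area converges to pi r^2 as pixels shrink", {
  pxs <- c(20, 10, 5)
  errs <- vapply(pxs, function(px) {
    n <- ceiling(5.2e3 / px)
    roi <- circularROI(c(2.6, 2.6), 5, c(n, n), px)
    abs(roiArea(roi) - pi * 2.5^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))       # error never grows
  # pixelization error is confined to the boundary band of width ~px
  expect_true(all(errs <= pi * 5 * pxs * 1e-3 / 2))
  expect_lt(errs[3] / (pi * 2.5^2), 2e-3)
})

test_that("degenerate circular ROIs are rejected", {
  expect_error(circularROI(c(1, 1), 0, c(100, 100), 10), "diameter > 0")
  expect_error(circularROI(c(0.5, 0.5), 5, c(100, 100), 10), "exceeds")
})

test_that("manual ROI masks load from PNG with area arithmetic", {
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 100, 100), f)
  roi <- loadManualROI(f, pixelSize = 10, shape = c(100, 100))
  expect_equal(roiArea(roi), 1.0)           # 100 x 100 x (0.01 mm)^2
  expect_error(loadManualROI(f, 10, shape = c(50, 100)), "shape")
  g <- tempfile(fileext = ".png")
  png::writePNG(matrix(seq(0, 1, length.out = 64), 8, 8), g)
  expect_error(loadManualROI(g, 10), "not binary")
  roi2 <- loadManualROI(g, 10, threshold = 0.5)
  expect_equal(sum(roi2@mask), sum(matrix(seq(0, 1, length.out = 64), 8, 8)
                                   > 0.5))
})

# A small fully synthetic scene with hand-placed labels for exact counting.
quantFixture <- function() {
  ny <- 40; nx <- 50
  mask <- matrix(FALSE, ny, nx)
  lab <- matrix(0L, ny, nx)
  mask[5:16, 1:50] <- TRUE;  lab[5:16, 1:50] <- 1L    # 600 capillary px
  mask[20:25, 1:50] <- TRUE; lab[20:25, 1:50] <- 2L   # 300 medium px
  mask[30:31, 1:50] <- TRUE; lab[30:31, 1:50] <- 3L   # 100 major px
  flow <- matrix(NA_real_, ny, nx)
  flow[lab == 1L] <- 1.0; flow[lab == 2L] <- 1.8; flow[lab == 3L] <- 2.3
  valid <- !is.na(flow)
  tau <- 1 / flow
  fit <- new("VistaFitResult", DMap = flow * 0 + 0.9, tauMap = tau,
             flowMap = flow, validMask = valid, rssMap = flow * 0)
  list(mask = VesselMask(mask, 10),
       classes = new("DiameterClassMap", labels = lab), fit = fit,
       roi = ROIMask(matrix(TRUE, ny, nx), 10, "all"))
}

test_that("class area percentages and mean flows are exact pixel counts", {
  fx <- quantFixture()
  rec <- quantifyROI(fx$mask, fx$classes, fx$fit, fx$roi)
  expect_equal(rec$n_pixels, 1000)
  expect_equal(c(rec$pct_capillary, rec$pct_medium, rec$pct_major),
               c(60, 30, 10))
  expect_equal(rec$pct_capillary + rec$pct_medium + rec$pct_major, 100)
  expect_equal(c(rec$flow_capillary, rec$flow_medium, rec$flow_major),
               c(1.0, 1.8, 2.3))
  # overall mean equals the class-area-weighted mean when all fits are valid
  expect_equal(rec$flow_mean,
               0.60 * 1.0 + 0.30 * 1.8 + 0.10 * 2.3)
  expect_equal(rec$pct_invalid, 0)
})

test_that("single-class ROIs report 100% and undetected classes are NA", {
  fx <- quantFixture()
  roiCap <- ROIMask(rbind(matrix(TRUE, 18, 50), matrix(FALSE, 22, 50)), 10,
                    "cap-only")
  rec <- quantifyROI(fx$mask, fx$classes, fx$fit, roiCap)
  expect_equal(rec$pct_capillary, 100)
  expect_true(is.na(rec$pct_medium) && is.na(rec$pct_major))
  expect_true(is.na(rec$flow_medium))
  expect_equal(rec$flow_mean, 1.0)
})

test_that("restricting the ROI never increases the vessel pixel count", {
  fx <- quantFixture()
  full <- quantifyROI(fx$mask, fx$classes, fx$fit, fx$roi)
  sub <- ROIMask(fx$roi@mask & matrix(rep(c(TRUE, FALSE), 25), 40, 50,
                                      byrow = TRUE), 10, "sub")
  rec <- quantifyROI(fx$mask, fx$classes, fx$fit, sub)
  expect_lte(rec$n_pixels, full$n_pixels)
})

test_that("an ROI without vessels warns and returns an empty record", {
  fx <- quantFixture()
  empty <- ROIMask(rbind(matrix(FALSE, 34, 50), matrix(TRUE, 6, 50)), 10,
                   "background")
  expect_warning(rec <- quantifyROI(fx$mask, fx$classes, fx$fit, empty),
                 "no vessel pixels")
  expect_equal(rec$n_pixels, 0)
  expect_true(is.na(rec$flow_mean))
})

test_that("diameter-binned flow profiles follow a constructed trend", {
  # tau decreasing linearly with diameter -> flow increasing with diameter
  taus <- c(1.4, 1.0, 0.6)
  tc <- threeClassPhantom(2.5, taus = taus)
  ph <- tc$phantom
  st <- simulateDecorrelationStack(ph, nativeLags(), noiseSd = 0)
  fit <- fitVistaMap(st, VesselMask(ph@vesselMask, 2.5))
  dmap <- new("DiameterMap", diameter = ph@diameterMap, calibrated = FALSE)
  roi <- ROIMask(matrix(TRUE, nrow(ph@vesselMask), ncol(ph@vesselMask)),
                 2.5, "all")
  prof <- diameterFlowProfile(dmap, fit, roi, binWidth = 10)
  expect_equal(nrow(prof), 3)                      # bins 10-20, 30-40, 40-50
  expect_true(all(diff(prof$mean_flow) > 0))
  expect_true(all(prof$sd_flow < 1e-6))            # noiseless fits
  expect_true(all(prof$n > 0))
  # bins cover only observed diameters
  expect_setequal(prof$bin_center_um, c(15, 35, 45))
})
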
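test_that("image stacks round-trip through float TIFF within float32 eps", {
  set.seed(41)
  pages <- list(a = matrix(rnorm(600, sd = 10), 20, 30),
                b = matrix(runif(600, -5, 5), 20, 30))
  f <- tempfile(fileext = ".tif")
  writeImageStack(pages, f)
  back <- readImageStack(f)
  for (nm in names(pages))
    expect_equal(back$pages[[nm]], pages[[nm]], tolerance = 1e-6)
})

test_that("decorrelation stacks and masks round-trip", {
  ph <- buildPhantom(list(straightVessel(0.2, 30, 0.8)), 5, c(60, 100))
  st <- simulateDecorrelationStack(ph, nativeLags(), noiseSd = 0.02, seed = 2)
  f <- tempfile(fileext = ".tif")
  writeDecorrelationStack(st, f)
  st2 <- readDecorrelationStack(f)
  expect_equal(st2@lags, st@lags)
  expect_equal(st2@nPairsPerLag, st@nPairsPerLag)
  expect_equal(st2@pixelSize, st@pixelSize)
  for (k in seq_along(st@lags))
    expect_equal(st2@images[[k]], st@images[[k]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  m <- tempfile(fileext = ".png")
  writeMaskPNG(ph@vesselMask, m)
  expect_identical(readMaskPNG(m), ph@vesselMask)
  b <- tempfile(fileext = ".tif")
  bd <- boundarySurfaces(matrix(10, 6, 8), matrix(44.2, 6, 8), 3.9)
  writeBoundarySurfaces(bd, b)
  bd2 <- readBoundarySurfaces(b, 3.9)
  expect_equal(bd2@inl, bd@inl, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("diameter-class rendering uses the gray/green/magenta palette", {
  tc <- threeClassPhantom()
  ph <- tc$phantom
  classes <- new("DiameterClassMap", labels = ph@classMap)
  base <- ph@vesselMask * 1
  rgb <- renderDiameterMap(classes, base)
  pick <- function(d) {
    idx <- which(truthPixels(ph, d), arr.ind = TRUE)[5, ]
    rgb[idx[1], idx[2], ]
  }
  expect_equal(pick(12), c(1, 1, 1))            # capillary: gray
  expect_equal(pick(30), c(0, 1, 0))            # medium: green
  expect_equal(pick(48), c(1, 0, 1))            # major: magenta
  # exactly three hue families on vessels
  hues <- unique(apply(rgb, c(1, 2), paste, collapse = "/")[ph@vesselMask])
  expect_length(hues, 3)
})

test_that("all-capillary scenes render pure grayscale", {
  ph <- buildPhantom(list(straightVessel(0.2, 12, 1)), 2.5, c(160, 256))
  rgb <- renderDiameterMap(new("DiameterClassMap", labels = ph@classMap),
                           ph@vesselMask * 1)
  expect_equal(rgb[, , 1], rgb[, , 2])
  expect_equal(rgb[, , 2], rgb[, , 3])
})

test_that("an empty class map leaves the base image unchanged", {
  set.seed(42)
  base <- matrix(runif(200), 10, 20)
  rgb <- renderDiameterMap(new("DiameterClassMap",
                               labels = matrix(0L, 10, 20)), base)
  norm <- (base - min(base)) / (max(base) - min(base))
  for (ch in 1:3) expect_equal(rgb[, , ch], norm)
})

test_that("VISTA rendering maps slow flow blue and fast flow red", {
  ny <- 8; nx <- 8
  mk <- function(value) {
    flow <- matrix(value, ny, nx)
    new("VistaFitResult", DMap = matrix(0.9, ny, nx), tauMap = 1 / flow,
        flowMap = flow, validMask = matrix(TRUE, ny, nx),
        rssMap = matrix(0, ny, nx))
  }
  base <- matrix(0.5, ny, nx)
  spec <- renderSpec(flowRange = c(0, 2.5))
  lowImg <- renderVista(mk(1e-4), base, spec, alpha = 1)
  expect_true(all(lowImg[, , 3] > lowImg[, , 1]))   # blue dominates
  hiImg <- renderVista(mk(2.5), base, spec, alpha = 1)
  expect_true(all(hiImg[, , 1] > hiImg[, , 3]))     # red dominates
  expect_true(is.array(attr(hiImg, "colorbar")))
  # two-tau scene: the faster cluster is redder
  flow <- matrix(c(rep(0.5, 32), rep(2.2, 32)), ny, nx)
  img <- renderVista(mk(1) |> (\(f) { f@flowMap <- flow; f@tauMap <- 1 /
    flow; f })(), base, spec, alpha = 1)
  redness <- img[, , 1] - img[, , 3]
  expect_gt(min(redness[flow == 2.2]), max(redness[flow == 0.5]))
  # invalid pixels show the base
  inv <- mk(2.5); inv@validMask[1, 1] <- FALSE
  img2 <- renderVista(inv, base, spec)
  expect_equal(img2[1, 1, ], rep(0, 3))   # constant base normalizes to 0
  expect_error(renderSpec(flowRange = c(2, 1)), "min < max")
})

test_that("the pipeline writes its artifacts deterministically", {
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  res <- suppressWarnings(runPipeline(outDir = out1, seed = 13))
  expect_true(file.exists(file.path(out1, "quant.csv")))
  pngs <- c("vessel_mask.png", "diameter_map.png", "vista.png",
            "vista_valid.png")
  expect_true(all(file.exists(file.path(out1, pngs))))
  expect_s4_class(res$fit, "VistaFitResult")
  expect_equal(res$record$pct_capillary + res$record$pct_medium +
                 res$record$pct_major, 100, tolerance = 1e-9)
  suppressWarnings(runPipeline(outDir = out2, seed = 13))
  expect_identical(readBin(file.path(out1, "quant.csv"), "raw", 1e5),
                   readBin(file.path(out2, "quant.csv"), "raw", 1e5))
})

test_that("unknown configuration keys are rejected by name", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("vessels:", "  global_quantile: 0.9"), f)
  err <- tryCatch(loadPipelineConfig(f), error = identity)
  expect_s3_class(err, "octavista_config_error")
  expect_match(conditionMessage(err), "vessels.global_quantile")
  g <- tempfile(fileext = ".yaml")
  writeLines(c("simulate:", "  mode: warp"), g)
  expect_error(loadPipelineConfig(g), "frames.*stack")
})
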
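# Synthetic vessel phantoms: tubes of known diameter and decay constant tau
# embedded in a static background, with forward simulation of multi-lag
# decorrelation stacks and of repeated complex speckle frames.  These supply
# exact ground truth for segmentation, diameter estimation and VISTA fitting.

#' VesselSpec: one synthetic vessel
#'
#' @slot centerline two-column matrix of (x, y) positions in mm.
#' @slot diameter vessel diameter, um.
#' @slot tau decorrelation time constant, ms.
#' @slot layer slab label (`superficial`, `deep` or `outer`).
#' @slot D decorrelation saturation level in \[0, 1\].
#' @export
setClass("VesselSpec", representation(centerline = "matrix",
                                      diameter = "numeric",
                                      tau = "numeric", layer = "character",
                                      D = "numeric"))

setValidity("VesselSpec", function(object) {
  if (ncol(object@centerline) != 2 || nrow(object@centerline) < 2)
    return("centerline must be a >= 2 row matrix of (x, y) in mm")
  if (object@diameter <= 0) return("diameter must be > 0")
  if (object@tau <= 0) return("tau must be > 0")
  if (object@D < 0 || object@D > 1) return("D must be in [0, 1]")
  if (!object@layer %in% c("superficial", "deep", "outer"))
    return("layer must be superficial, deep or outer")
  TRUE
})

#' @param centerline two-column matrix (x, y) in mm.
#' @param diameter diameter, um.
#' @param tau decay constant, ms.
#' @param layer slab label.
#' @param D saturation level.
#' @rdname VesselSpec-class
#' @export
vesselSpec <- function(centerline, diameter, tau, layer = "superficial",
                       D = 1) {
  new("VesselSpec", centerline = centerline, diameter = diameter, tau = tau,
      layer = layer, D = D)
}

#' Phantom: ground-truth maps of a synthetic vascular scene
#'
#' @slot pixelSize en-face pixel size, um.
#' @slot vesselMask logical truth mask.
#' @slot diameterMap diameter in um on vessel pixels, `NA` elsewhere.
#' @slot tauMap decay constant in ms on vessel pixels, `NA` elsewhere.
#' @slot classMap integer labels as in [diameterClassLevels()].
#' @slot DMap saturation level on vessel pixels, `NA` elsewhere.
#' @export
setClass("Phantom", representation(pixelSize = "numeric",
                                   vesselMask = "matrix",
                                   diameterMap = "matrix", tauMap = "matrix",
                                   classMap = "matrix", DMap = "matrix"))

setValidity("Phantom", function(object) {
  dims <- vapply(list(object@vesselMask, object@diameterMap, object@tauMap,
                      object@classMap, object@DMap),
                 function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) return("truth maps must share one shape")
  m <- object@vesselMask
  if (any(is.na(object@diameterMap[m])) || any(object@diameterMap[m] <= 0))
    return("diameters must be defined and positive on vessel pixels")
  if (any(is.na(object@tauMap[m])) || any(object@tauMap[m] <= 0))
    return("tau must be defined and positive on vessel pixels")
  TRUE
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom", nrow(object@vesselMask), "x", ncol(object@vesselMask), "@",
      object@pixelSize, "um/px;", sum(object@vesselMask), "vessel pixels\n")
  tab <- table(factor(object@classMap[object@vesselMask],
                      levels = 1:3, labels = c("capillary", "medium",
                                               "major")))
  print(tab)
})

# Distance from pixel centres to a polyline (um coordinates), computed per
# segment on its padded bounding box only.
rasterizeTube <- function(ny, nx, pixelSize, centerUm, radiusUm) {
  mask <- matrix(FALSE, ny, nx)
  xs <- (seq_len(nx) - 0.5) * pixelSize
  ys <- (seq_len(ny) - 0.5) * pixelSize
  for (s in seq_len(nrow(centerUm) - 1)) {
    p <- centerUm[s, ]; q <- centerUm[s + 1, ]
    pad <- radiusUm + pixelSize
    cmin <- max(1L, findInterval(min(p[1], q[1]) - pad, xs))
    cmax <- min(nx, findInterval(max(p[1], q[1]) + pad, xs) + 1L)
    rmin <- max(1L, findInterval(min(p[2], q[2]) - pad, ys))
    rmax <- min(ny, findInterval(max(p[2], q[2]) + pad, ys) + 1L)
    if (cmin > cmax || rmin > rmax) next
    gx <- xs[cmin:cmax]; gy <- ys[rmin:rmax]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    len2 <- vx^2 + vy^2
    X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
    Y <- matrix(gy, length(gy), length(gx))
    tt <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((X - p[1]) * vx + (Y - p[2]) * vy) / len2))
    d2 <- (X - (p[1] + tt * vx))^2 + (Y - (p[2] + tt * vy))^2
    mask[rmin:rmax, cmin:cmax] <- mask[rmin:rmax, cmin:cmax] |
      (d2 <= radiusUm^2)
  }
  mask
}

#' Build a vessel phantom from vessel specifications
#'
#' Rasterizes each vessel as a tube of its diameter around its centerline on
#' a grid of `shape` pixels of `pixelSize` um (pixel centres at
#' `(i - 0.5) * pixelSize`); where vessels overlap, later specifications
#' overwrite earlier ones.  Class labels follow the standard thresholds
#' (< 20 um capillary, 20-40 um medium, >= 40 um major).  Vessels entirely
#' outside the image are skipped with a warning; if nothing remains an error
#' is raised.
#'
#' @param specs list of [VesselSpec-class] objects.
#' @param pixelSize pixel size, um.
#' @param shape `c(ny, nx)` image shape.
#' @param background unused intensity placeholder kept for symmetry with the
#'   simulators (default 0).
#' @return a [Phantom-class].
#' @export
buildPhantom <- function(specs, pixelSize, shape, background = 0) {
  stopifnot(length(specs) >= 1, pixelSize > 0, length(shape) == 2)
  ny <- shape[1]; nx <- shape[2]
  blank <- matrix(NA_real_, ny, nx)
  ph <- new("Phantom", pixelSize = pixelSize,
            vesselMask = matrix(FALSE, ny, nx), diameterMap = blank,
            tauMap = blank, classMap = matrix(0L, ny, nx), DMap = blank)
  placed <- 0L
  for (sp in specs) {
    stopifnot(is(sp, "VesselSpec")); validObject(sp)
    m <- rasterizeTube(ny, nx, pixelSize, sp@centerline * 1e3,
                       sp@diameter / 2)
    if (!any(m)) {
      warning("vessel entirely outside the image; skipped")
      next
    }
    placed <- placed + 1L
    ph@vesselMask[m] <- TRUE
    ph@diameterMap[m] <- sp@diameter
    ph@tauMap[m] <- sp@tau
    ph@DMap[m] <- sp@D
    ph@classMap[m] <- as.integer(classifyDiameter(sp@diameter))
  }
  if (placed == 0L) stop("all vessels fell outside the image")
  validObject(ph)
  ph
}

#' Simulate a multi-lag decorrelation stack from a phantom
#'
#' Evaluates the saturating exponential forward model
#' `D * (1 - exp(-t / tau))` at each lag on vessel pixels, adds Gaussian
#' noise of standard deviation `noiseSd`, and clamps to \[0, 1\].
#' Background pixels receive pure noise around `backgroundFloor`.
#' Deterministic for a given `seed`.
#'
#' @param phantom a [Phantom-class].
#' @param lags ascending positive lag times, ms.
#' @param noiseSd Gaussian noise SD (>= 0); default 0.
#' @param seed integer RNG seed; default 1.
#' @param backgroundFloor static-tissue decorrelation floor; default 0.
#' @return a [DecorrelationStack-class].
#' @export
simulateDecorrelationStack <- function(phantom, lags, noiseSd = 0, seed = 1L,
                                       backgroundFloor = 0) {
  stopifnot(is(phantom, "Phantom"), all(lags > 0),
            !is.unsorted(lags, strictly = TRUE), noiseSd >= 0)
  set.seed(seed)
  m <- phantom@vesselMask
  imgs <- lapply(lags, function(t) {
    img <- matrix(backgroundFloor, nrow(m), ncol(m))
    img[m] <- phantom@DMap[m] * (1 - exp(-t / phantom@tauMap[m]))
    if (noiseSd > 0)
      img <- img + matrix(rnorm(length(img), 0, noiseSd), nrow(m), ncol(m))
    clamp01(img)
  })
  decorrelationStack(lags = lags, images = imgs,
                     pixelSize = phantom@pixelSize,
                     nPairsPerLag = rep(1L, length(lags)))
}

#' Simulate repeated complex speckle frames from a phantom
#'
#' Generates `repeats` thin-slab complex frames.  Each vessel pixel carries a
#' zero-mean circular complex Gaussian AR(1) process with lag-t
#' autocorrelation `exp(-t / tau)`; static pixels keep an identical complex
#' value across repeats (autocorrelation 1).  Frame spacing equals the plan's
#' fundamental interscan time.  Deterministic for a given `seed`.
#'
#' @param phantom a [Phantom-class].
#' @param plan a [ScanPlan-class] (supplies `repeats` and the interscan
#'   time).
#' @param seed integer RNG seed; default 1.
#' @return a [RepeatedFrameSet-class].
#' @export
simulateComplexFrames <- function(phantom, plan, seed = 1L) {
  stopifnot(is(phantom, "Phantom"), is(plan, "ScanPlan"))
  if (plan@repeats < 2) stop("plan must have at least 2 repeats")
  set.seed(seed)
  dtMs <- interscanTime(plan)
  nRep <- as.integer(plan@repeats)
  m <- phantom@vesselMask
  ny <- nrow(m); nx <- ncol(m)
  cgauss <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) /
    sqrt(2)
  base <- matrix(cgauss(ny * nx), ny, nx)
  rho <- matrix(1, ny, nx)
  rho[m] <- exp(-dtMs / phantom@tauMap[m])
  frames <- vector("list", nRep)
  frames[[1]] <- base
  prev <- base
  for (k in 2:nRep) {
    innov <- matrix(cgauss(ny * nx), ny, nx)
    cur <- rho * prev + sqrt(1 - rho^2) * innov
    frames[[k]] <- cur
    prev <- cur
  }
  repeatedFrameSet(frames = frames,
                   timestamps = (seq_len(nRep) - 1) * dtMs / 1e3,
                   pixelSize = phantom@pixelSize)
}

#' Write phantom truth maps to disk
#'
#' Truth maps go to a multi-page float TIFF (pages: mask, diameter, tau,
#' class, D; `NA` stored as 0 with the mask page defining validity) with a
#' JSON sidecar recording pixel size, page names, per-page affine scaling and
#' the class legend.
#'
#' @param phantom a [Phantom-class].
#' @param path output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @export
writePhantom <- function(phantom, path) {
  stopifnot(is(phantom, "Phantom"))
  pages <- list(mask = phantom@vesselMask * 1,
                diameter_um = phantom@diameterMap,
                tau_ms = phantom@tauMap,
                class = phantom@classMap + 0,
                D = phantom@DMap)
  pages <- lapply(pages, function(p) { p[is.na(p)] <- 0; p })
  writeImageStack(pages, path,
                  meta = list(pixel_size_um = phantom@pixelSize,
                              pages = names(pages),
                              class_legend = as.list(diameterClassLevels())))
  invisible(path)
}
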
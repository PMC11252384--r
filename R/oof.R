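# Multi-scale optimally oriented flux (OOF) vessel detection on en-face OCTA
# images.  At each pixel and radius r the outward flux of the smoothed image
# gradient through a circle of radius r is assembled into a 2x2 matrix; for a
# bright tube the eigenvalue along the cross-section direction is strongly
# negative when r matches the tube radius, so the sign-rectified dominant
# eigenvalue peaks at radius ~ half the vessel diameter.

#' OOFScaleSet: radii probed by the multi-scale OOF filter
#'
#' @slot radii ascending probe radii, micrometres.  The default set spans
#'   4-40 um (vessel diameters 8-80 um) in 2 um steps.
#' @slot pixelSize en-face pixel size, micrometres.
#' @export
setClass("OOFScaleSet", representation(radii = "numeric",
                                       pixelSize = "numeric"))

setValidity("OOFScaleSet", function(object) {
  if (length(object@radii) < 1 || any(object@radii <= 0))
    return("radii must be positive")
  if (is.unsorted(object@radii, strictly = TRUE))
    return("radii must be strictly ascending")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' @param radii ascending probe radii, um.
#' @param pixelSize pixel size, um.
#' @rdname OOFScaleSet-class
#' @export
oofScaleSet <- function(radii = seq(4, 40, by = 2), pixelSize) {
  new("OOFScaleSet", radii = radii, pixelSize = pixelSize)
}

#' VesselMask: binary vessel segmentation
#'
#' @slot mask logical matrix, same shape as the source image.
#' @slot pixelSize pixel size, um.
#' @export
setClass("VesselMask", representation(mask = "matrix", pixelSize = "numeric"))

#' @param mask logical matrix.
#' @param pixelSize pixel size, um.
#' @rdname VesselMask-class
#' @export
VesselMask <- function(mask, pixelSize) {
  new("VesselMask", mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
      pixelSize = pixelSize)
}

setMethod("show", "VesselMask", function(object) {
  cat("VesselMask", nrow(object@mask), "x", ncol(object@mask), "@",
      object@pixelSize, "um/px;", sum(object@mask), "vessel pixels\n")
})

#' DiameterMap: per-pixel vessel diameter
#'
#' @slot diameter numeric matrix of diameters in um, `NA` outside the vessel
#'   mask.
#' @slot calibrated whether PSF calibration has been applied.
#' @export
setClass("DiameterMap", representation(diameter = "matrix",
                                       calibrated = "logical"))

#' DiameterClassMap: three-class vessel diameter labels
#'
#' Integer matrix with levels 0 = background, 1 = capillary (< 20 um),
#' 2 = medium (>= 20 and < 40 um), 3 = major (>= 40 um).
#'
#' @slot labels integer matrix.
#' @export
setClass("DiameterClassMap", representation(labels = "matrix"))

#' Diameter class levels
#' @return named integer vector mapping class names to label codes.
#' @export
diameterClassLevels <- function() {
  c(background = 0L, capillary = 1L, medium = 2L, major = 3L)
}

#' Mask, diameter-map and class-map accessors
#'
#' @param x a [VesselMask-class], [DiameterMap-class],
#'   [DiameterClassMap-class] or [ROIMask-class].
#' @return the underlying matrix.
#' @export
maskMatrix <- function(x) {
  if (is(x, "VesselMask") || is(x, "ROIMask")) return(x@mask)
  stop("no mask in object of class ", class(x))
}

#' @rdname maskMatrix
#' @export
diameterMatrix <- function(x) {
  stopifnot(is(x, "DiameterMap")); x@diameter
}

#' @rdname maskMatrix
#' @export
classMatrix <- function(x) {
  stopifnot(is(x, "DiameterClassMap")); x@labels
}

# Circle-flux kernels at radius r (pixels): boundary points spread
# bilinearly, weighted by the outward normal components and arc element,
# normalized by the circumference so responses are comparable across radii.
oofFluxKernels <- function(rPx) {
  h <- as.integer(ceiling(rPx) + 1L)
  M <- max(16L, 4L * as.integer(ceiling(2 * pi * rPx)))
  phi <- 2 * pi * (seq_len(M) - 0.5) / M
  dl <- 2 * pi * rPx / M
  kx <- matrix(0, 2L * h + 1L, 2L * h + 1L)
  ky <- matrix(0, 2L * h + 1L, 2L * h + 1L)
  w <- dl / (2 * pi * rPx)          # arc element / circumference
  for (m in seq_len(M)) {
    dx <- rPx * cos(phi[m]); dy <- rPx * sin(phi[m])
    kx <- spreadBilinear(kx, dy, dx, w * cos(phi[m]), h)
    ky <- spreadBilinear(ky, dy, dx, w * sin(phi[m]), h)
  }
  list(kx = kx, ky = ky, h = h, phi = phi, dl = dl)
}

#' Single-scale OOF response
#'
#' Smooths the image with a Gaussian (`sigmaPx` pixels), computes its
#' gradient, and integrates the outward flux of the gradient through a circle
#' of the given radius around every pixel, normalized by the circle
#' circumference.  The 2x2 flux matrix is symmetrized and eigen-decomposed;
#' the response is minus its largest-magnitude eigenvalue, so vessels
#' brighter than the background score positive and inverted-contrast tubes
#' score negative.  A constant image yields an identically zero response, and
#' the response is linear in image contrast.
#'
#' @param image numeric en-face matrix.
#' @param radius probe radius, um.
#' @param pixelSize pixel size, um.
#' @param sigmaPx pre-smoothing Gaussian sigma in pixels (default 1).
#' @return response matrix, same shape as `image`.
#' @export
oofResponse <- function(image, radius, pixelSize, sigmaPx = 1) {
  if (radius < pixelSize)
    stop("OOF radius (", radius, " um) is below one pixel (", pixelSize,
         " um)")
  rPx <- radius / pixelSize
  g <- imageGradient(gaussianSmooth(image, sigmaPx))
  k <- oofFluxKernels(rPx)
  # filter2 convolves (reflects the kernel); the flux kernels are odd under
  # point reflection and the circle point set maps onto itself, so the
  # correlation Q_ij(x) = sum_h g_i(x+h) n_j(h) dl is minus the convolution.
  q11 <- -EBImage::filter2(g$gx, k$kx, boundary = 0)
  q22 <- -EBImage::filter2(g$gy, k$ky, boundary = 0)
  q12 <- -(EBImage::filter2(g$gx, k$ky, boundary = 0) +
           EBImage::filter2(g$gy, k$kx, boundary = 0)) / 2
  tr2 <- (q11 + q22) / 2
  disc <- sqrt(((q11 - q22) / 2)^2 + q12^2)
  lo <- tr2 - disc
  hi <- tr2 + disc
  lam <- ifelse(abs(lo) >= abs(hi), lo, hi)  # largest-magnitude eigenvalue
  -lam
}

#' Multi-scale OOF response and per-pixel best radius
#'
#' Evaluates [oofResponse()] at every radius of the scale set and records,
#' per pixel, the maximum response and the radius attaining it (ties broken
#' toward the smaller radius).  Radii below one pixel are skipped with a
#' warning.
#'
#' @param image numeric en-face matrix.
#' @param scales an [OOFScaleSet-class].
#' @param sigmaPx pre-smoothing sigma in pixels.
#' @return list with `response` (max response matrix) and `radius`
#'   (argmax radius matrix, um).
#' @export
oofMultiscale <- function(image, scales, sigmaPx = 1) {
  stopifnot(is(scales, "OOFScaleSet"))
  validObject(scales)
  radii <- scales@radii
  usable <- radii >= scales@pixelSize
  if (any(!usable)) {
    warning("skipping OOF radii below one pixel: ",
            paste(radii[!usable], collapse = ", "), " um")
    radii <- radii[usable]
  }
  if (length(radii) < 1) stop("no usable OOF scale")
  best <- matrix(-Inf, nrow(image), ncol(image))
  argR <- matrix(radii[1], nrow(image), ncol(image))
  for (r in radii) {
    resp <- oofResponse(image, r, scales@pixelSize, sigmaPx)
    better <- resp > best            # strict: ties keep the smaller radius
    argR[better] <- r
    best[better] <- resp[better]
  }
  list(response = best, radius = argR)
}

#' Segment vessels from an OOF response image
#'
#' Combines a global quantile threshold with a local sliding-window threshold
#' (window mean plus `localOffset` window standard deviations over a
#' `localWindow`-um square, edge windows truncated) by AND, then removes
#' connected components smaller than `minArea` pixels.
#'
#' @param response OOF response matrix.
#' @param pixelSize pixel size, um.
#' @param globalQ global quantile in (0, 1); default 0.80.
#' @param localWindow local window side, um; default 200.
#' @param localOffset local threshold offset in window SDs; default 0.5.
#' @param minArea minimum connected-component area in pixels; default 5.
#' @return a [VesselMask-class].
#' @export
segmentVessels <- function(response, pixelSize, globalQ = 0.80,
                           localWindow = 200, localOffset = 0.5,
                           minArea = 5) {
  stopifnot(all(is.finite(response)), globalQ > 0, globalQ < 1)
  if (max(response) - min(response) == 0) {
    warning("constant OOF response; returning an empty vessel mask")
    return(VesselMask(matrix(FALSE, nrow(response), ncol(response)),
                      pixelSize))
  }
  gThr <- quantile(response, globalQ, names = FALSE)
  win <- max(3L, 2L * as.integer(round(localWindow / pixelSize / 2)) + 1L)
  n <- boxCount(nrow(response), ncol(response), win, win)
  mu <- boxSum(response, win, win) / n
  m2 <- boxSum(response^2, win, win) / n
  sdl <- sqrt(pmax(0, m2 - mu^2))
  mask <- response > gThr & response > mu + localOffset * sdl
  if (minArea > 1 && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minArea)
    mask <- matrix(lab %in% keep, nrow(response), ncol(response))
  }
  VesselMask(mask, pixelSize)
}

#' PSF calibration of a measured vessel diameter
#'
#' Deconvolves the transverse point-spread function in quadrature:
#' `sqrt(max(raw^2 - psfFwhm^2, minFloor^2))`.  With `psfFwhm = 0` this is
#' the identity.  Raw diameters at or below the PSF width are floored to
#' `minFloor` and flagged via the `"floored"` attribute.
#'
#' @param raw raw diameter(s), um.
#' @param psfFwhm transverse PSF full width at half maximum, um (the imaging
#'   system described here has ~5.5 um).
#' @param minFloor lower floor for the calibrated diameter, um; default 1.
#' @return calibrated diameter(s), um, with attribute `floored`.
#' @export
calibrateDiameter <- function(raw, psfFwhm, minFloor = 1) {
  stopifnot(all(raw > 0, na.rm = TRUE), psfFwhm >= 0, minFloor > 0)
  sq <- raw^2 - psfFwhm^2
  floored <- !is.na(sq) & sq < minFloor^2
  out <- sqrt(pmax(sq, minFloor^2))
  attr(out, "floored") <- floored
  out
}

#' Classify vessel diameters into capillary / medium / major
#'
#' Capillaries are vessels of diameter < 20 um, medium vessels >= 20 and
#' < 40 um, and major vessels >= 40 um (half-open intervals; 20 um is
#' medium and 40 um is major).
#'
#' @param d diameter(s), um; must be positive.
#' @return factor with levels `capillary`, `medium`, `major` (`NA` in maps to
#'   `NA` out).
#' @export
classifyDiameter <- function(d) {
  if (any(!is.na(d) & d <= 0)) stop("diameters must be positive")
  cut(d, breaks = c(0, 20, 40, Inf), right = FALSE,
      labels = c("capillary", "medium", "major"))
}

#' Build diameter and class maps from the multi-scale OOF radius
#'
#' Vessel diameter is twice the response-maximizing OOF radius, optionally
#' PSF-calibrated, assigned on every vessel-mask pixel.
#'
#' @param oof result of [oofMultiscale()].
#' @param mask a [VesselMask-class].
#' @param psfFwhm transverse PSF FWHM, um; `0` disables calibration.
#' @param minFloor calibration floor, um (defaults to the mask pixel size).
#' @return list with `diameterMap` ([DiameterMap-class]) and `classMap`
#'   ([DiameterClassMap-class]).
#' @export
diameterFromOOF <- function(oof, mask, psfFwhm = 0,
                            minFloor = mask@pixelSize) {
  stopifnot(is(mask, "VesselMask"))
  m <- mask@mask
  d <- matrix(NA_real_, nrow(m), ncol(m))
  raw <- 2 * oof$radius[m]
  d[m] <- if (psfFwhm > 0) as.numeric(calibrateDiameter(raw, psfFwhm,
                                                        minFloor)) else raw
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m] <- as.integer(classifyDiameter(d[m]))
  list(diameterMap = new("DiameterMap", diameter = d,
                         calibrated = psfFwhm > 0),
       classMap = new("DiameterClassMap", labels = lab))
}
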
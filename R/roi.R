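# ROI statistics: vessel-area percentage per diameter class (shares of the
# vessel area inside the ROI, which sum to 100 over detected classes), mean
# flow parameter per class and overall (pixel-weighted over valid fits), and
# diameter-binned flow profiles.

#' ROIMask: region-of-interest mask
#'
#' @slot mask logical matrix.
#' @slot pixelSize pixel size, um.
#' @slot name ROI label.
#' @export
setClass("ROIMask", representation(mask = "matrix", pixelSize = "numeric",
                                   name = "character"))

#' @param mask logical matrix.
#' @param pixelSize pixel size, um.
#' @param name ROI label.
#' @rdname ROIMask-class
#' @export
ROIMask <- function(mask, pixelSize, name = "roi") {
  new("ROIMask", mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
      pixelSize = pixelSize, name = name)
}

setMethod("show", "ROIMask", function(object) {
  cat("ROIMask '", object@name, "' ", nrow(object@mask), "x",
      ncol(object@mask), "; area ", signif(roiArea(object), 4), " mm^2\n",
      sep = "")
})

#' Area of an ROI in mm^2
#' @param roi a [ROIMask-class].
#' @return area, mm^2 (pixel count times pixel area).
#' @export
roiArea <- function(roi) {
  stopifnot(is(roi, "ROIMask"))
  sum(roi@mask) * (roi@pixelSize / 1e3)^2
}

#' Circular region of interest
#'
#' Selects the pixels whose centres lie inside a circle (the standard
#' retinal ROI is 5 mm in diameter centred on the fovea).  Pixel centres sit
#' at `(i - 0.5) * pixelSize`.
#'
#' @param center `c(x, y)` circle centre, mm.
#' @param diameter circle diameter, mm.
#' @param shape `c(ny, nx)` grid shape.
#' @param pixelSize pixel size, um.
#' @param name ROI label.
#' @return a [ROIMask-class].
#' @export
circularROI <- function(center, diameter, shape, pixelSize, name = "fovea") {
  stopifnot(diameter > 0, length(center) == 2, length(shape) == 2)
  pxMm <- pixelSize / 1e3
  if (center[1] - diameter / 2 < 0 || center[2] - diameter / 2 < 0 ||
      center[1] + diameter / 2 > shape[2] * pxMm ||
      center[2] + diameter / 2 > shape[1] * pxMm)
    stop("circle exceeds the image grid")
  xs <- (seq_len(shape[2]) - 0.5) * pxMm
  ys <- (seq_len(shape[1]) - 0.5) * pxMm
  d2 <- outer((ys - center[2])^2, (xs - center[1])^2, `+`)
  mask <- d2 <= (diameter / 2)^2
  if (!any(mask)) stop("circular ROI contains no pixel centres")
  ROIMask(mask, pixelSize, name)
}

#' Load a manually drawn ROI mask
#'
#' Reads a binary PNG or TIFF image.  Strictly binary content is required
#' unless `threshold` is given, in which case grey values above it are taken
#' as ROI.
#'
#' @param path PNG or TIFF file.
#' @param pixelSize pixel size, um.
#' @param shape optional expected `c(ny, nx)`; mismatch is an error.
#' @param threshold optional grey-level threshold in \[0, 1).
#' @param name ROI label.
#' @return a [ROIMask-class].
#' @export
loadManualROI <- function(path, pixelSize, shape = NULL, threshold = NULL,
                          name = "manual") {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!is.null(shape) && !all(dim(img) == shape))
    stop("ROI mask shape ", paste(dim(img), collapse = "x"),
         " does not match expected ", paste(shape, collapse = "x"))
  if (is.null(threshold)) {
    if (!all(img %in% c(0, 1)))
      stop("ROI mask is not binary; pass a threshold to binarize")
    mask <- img == 1
  } else mask <- img > threshold
  if (!any(mask)) stop("ROI mask is empty")
  ROIMask(mask, pixelSize, name)
}

#' Quantify vessel structure and flow inside an ROI
#'
#' Per diameter class, the vessel-area percentage is the class share of the
#' vessel pixels inside the ROI (the three shares sum to 100 over detected
#' classes); the class mean flow parameter averages the flow map over valid
#' vessel pixels of that class; the overall mean is pixel-weighted over all
#' valid vessel pixels inside the ROI.  Undetected classes report `NA`.
#'
#' @param mask a [VesselMask-class].
#' @param classes a [DiameterClassMap-class].
#' @param fit a [VistaFitResult-class].
#' @param roi an [ROIMask-class].
#' @param layer optional layer label recorded in the output.
#' @return one-row `data.frame` with columns `roi`, `layer`, `area_mm2`,
#'   `pct_capillary`, `pct_medium`, `pct_major`, `flow_capillary`,
#'   `flow_medium`, `flow_major`, `flow_mean`, `n_pixels`, `pct_invalid`,
#'   `density_pct` (vessel area as % of ROI area).
#' @export
quantifyROI <- function(mask, classes, fit, roi, layer = NA_character_) {
  stopifnot(is(mask, "VesselMask"), is(classes, "DiameterClassMap"),
            is(fit, "VistaFitResult"), is(roi, "ROIMask"))
  dims <- dim(mask@mask)
  stopifnot(all(dim(classes@labels) == dims), all(dim(fit@flowMap) == dims),
            all(dim(roi@mask) == dims), any(roi@mask))
  inRoi <- mask@mask & roi@mask
  n <- sum(inRoi)
  rec <- data.frame(roi = roi@name, layer = layer, area_mm2 = roiArea(roi),
                    pct_capillary = NA_real_, pct_medium = NA_real_,
                    pct_major = NA_real_, flow_capillary = NA_real_,
                    flow_medium = NA_real_, flow_major = NA_real_,
                    flow_mean = NA_real_, n_pixels = n,
                    pct_invalid = NA_real_, density_pct = NA_real_,
                    stringsAsFactors = FALSE)
  if (n == 0) {
    warning("no vessel pixels inside ROI '", roi@name, "'")
    return(rec)
  }
  lab <- classes@labels[inRoi]
  fl <- fit@flowMap[inRoi]
  ok <- fit@validMask[inRoi]
  for (cls in c("capillary", "medium", "major")) {
    code <- diameterClassLevels()[[cls]]
    inCls <- lab == code
    if (any(inCls)) {
      rec[[paste0("pct_", cls)]] <- 100 * sum(inCls) / n
      if (any(inCls & ok))
        rec[[paste0("flow_", cls)]] <- mean(fl[inCls & ok])
    }
  }
  if (any(ok)) rec$flow_mean <- mean(fl[ok])
  rec$pct_invalid <- 100 * sum(!ok) / n
  rec$density_pct <- 100 * n / sum(roi@mask)
  rec
}

#' Diameter-binned flow profile
#'
#' Bins the vessel pixels inside the ROI by diameter and reports mean and
#' standard deviation of the flow parameter per bin (valid fits only).
#' Empty bins are omitted.
#'
#' @param diameters a [DiameterMap-class].
#' @param fit a [VistaFitResult-class].
#' @param roi an [ROIMask-class].
#' @param binWidth bin width, um; default 10.
#' @return `data.frame` with columns `bin_center_um`, `mean_flow`, `sd_flow`,
#'   `n`.
#' @export
diameterFlowProfile <- function(diameters, fit, roi, binWidth = 10) {
  stopifnot(is(diameters, "DiameterMap"), is(fit, "VistaFitResult"),
            is(roi, "ROIMask"), binWidth > 0)
  sel <- roi@mask & !is.na(diameters@diameter) & fit@validMask
  if (!any(sel))
    return(data.frame(bin_center_um = numeric(0), mean_flow = numeric(0),
                      sd_flow = numeric(0), n = integer(0)))
  d <- diameters@diameter[sel]
  fl <- fit@flowMap[sel]
  bin <- floor(d / binWidth)
  agg <- lapply(sort(unique(bin)), function(b) {
    v <- fl[bin == b]
    data.frame(bin_center_um = (b + 0.5) * binWidth, mean_flow = mean(v),
               sd_flow = if (length(v) > 1) sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, agg)
}

#' Append quantification records to a CSV file
#'
#' @param records data.frame of [quantifyROI()] rows.
#' @param path CSV path; created with a header if absent, appended to
#'   otherwise.
#' @export
writeQuantRecords <- function(records, path) {
  fresh <- !file.exists(path)
  suppressWarnings(write.table(records, path, sep = ",", row.names = FALSE,
                               col.names = fresh, append = !fresh,
                               quote = FALSE))
  invisible(path)
}
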
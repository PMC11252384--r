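# Readers and writers for the pipeline artifacts.  Float maps travel as
# multi-page 32-bit TIFF; because the TIFF writer stores values in [0, 1],
# each page is affinely rescaled and the (offset, scale) pair recorded in a
# JSON sidecar so reads restore the original values to float32 precision.
# Masks travel as PNG, records as CSV/JSON, configuration as YAML.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a list of float images as a multi-page TIFF with JSON sidecar
#'
#' @param pages named list of numeric matrices (`NA` not allowed; replace
#'   before writing).
#' @param path TIFF output path; the sidecar goes to `paste0(path, ".json")`.
#' @param meta extra metadata stored in the sidecar.
#' @export
writeImageStack <- function(pages, path, meta = list()) {
  stopifnot(is.list(pages), length(pages) >= 1)
  enc <- lapply(pages, function(p) {
    stopifnot(all(is.finite(p)))
    lo <- min(p); hi <- max(p)
    scale <- if (hi > lo) hi - lo else 1
    list(data = (p - lo) / scale, offset = lo, scale = scale)
  })
  tiff::writeTIFF(lapply(enc, `[[`, "data"), path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta$pages <- if (is.null(meta$pages)) names(pages) else meta$pages
  meta$encoding <- lapply(enc, function(e) list(offset = e$offset,
                                                scale = e$scale))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [writeImageStack()]
#'
#' @param path TIFF path (sidecar expected alongside).
#' @return named list with `pages` (list of matrices, original scale) and
#'   `meta` (sidecar contents).
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  enc <- meta$encoding
  out <- lapply(seq_along(pages), function(i) {
    e <- if (is.data.frame(enc)) as.list(enc[i, ]) else enc[[i]]
    pages[[i]] * e$scale + e$offset
  })
  names(out) <- meta$pages
  list(pages = out, meta = meta)
}

#' Write and read a decorrelation stack (TIFF + JSON lags)
#'
#' @param stack a [DecorrelationStack-class].
#' @param path TIFF path.
#' @export
writeDecorrelationStack <- function(stack, path) {
  stopifnot(is(stack, "DecorrelationStack"))
  pages <- stack@images
  names(pages) <- paste0("lag_", seq_along(pages))
  writeImageStack(pages, path,
                  meta = list(lags_ms = stack@lags,
                              pixel_size_um = stack@pixelSize,
                              n_pairs_per_lag = stack@nPairsPerLag))
  invisible(path)
}

#' @rdname writeDecorrelationStack
#' @return `readDecorrelationStack` returns a [DecorrelationStack-class].
#' @export
readDecorrelationStack <- function(path) {
  x <- readImageStack(path)
  decorrelationStack(lags = as.numeric(x$meta$lags_ms),
                     images = lapply(x$pages, clamp01),
                     pixelSize = as.numeric(x$meta$pixel_size_um),
                     nPairsPerLag = as.integer(x$meta$n_pairs_per_lag))
}

#' Write a binary mask as PNG
#'
#' @param mask logical matrix, or a [VesselMask-class] / [ROIMask-class].
#' @param path PNG path.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "VesselMask") || is(mask, "ROIMask")) mask@mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Read a binary PNG mask as a logical matrix
#' @param path PNG path.
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Read boundary surfaces from a two-page TIFF or a CSV pair
#'
#' The TIFF must have been written by [writeBoundarySurfaces()] (pages `ilm`
#' and `inl`, depths in um).
#'
#' @param path TIFF path.
#' @param axialPixel axial voxel size, um.
#' @return a [BoundarySurfaces-class].
#' @export
readBoundarySurfaces <- function(path, axialPixel) {
  x <- readImageStack(path)
  boundarySurfaces(ilm = x$pages$ilm, inl = x$pages$inl,
                   axialPixel = axialPixel)
}

#' @param boundaries a [BoundarySurfaces-class].
#' @rdname readBoundarySurfaces
#' @export
writeBoundarySurfaces <- function(boundaries, path) {
  stopifnot(is(boundaries, "BoundarySurfaces"))
  writeImageStack(list(ilm = boundaries@ilm, inl = boundaries@inl), path,
                  meta = list(axial_pixel_um = boundaries@axialPixel))
  invisible(path)
}
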
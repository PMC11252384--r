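# False-colour rendering: diameter-class maps (gray capillaries, green
# medium vessels, magenta major vessels over the OCTA base image) and VISTA
# images (flow parameter on a blue-green-yellow-red scale blended onto the
# OCTA base; invalid pixels keep the base).

#' RenderSpec: rendering parameters
#'
#' @slot mode `"diameter"`, `"vista"` or `"overlay"`.
#' @slot flowRange `c(min, max)` flow-parameter range for the colour scale,
#'   ms^-1.  The default 0-2.5 matches the ceiling flow parameters reach in
#'   large retinal vessels.
#' @slot palette palette name (only `"vista"` is built in).
#' @export
setClass("RenderSpec", representation(mode = "character",
                                      flowRange = "numeric",
                                      palette = "character"))

setValidity("RenderSpec", function(object) {
  if (!object@mode %in% c("diameter", "vista", "overlay"))
    return("mode must be diameter, vista or overlay")
  if (length(object@flowRange) != 2 ||
      object@flowRange[1] >= object@flowRange[2])
    return("flowRange must satisfy min < max")
  TRUE
})

#' @param mode render mode.
#' @param flowRange flow colour range, ms^-1.
#' @param palette palette name.
#' @rdname RenderSpec-class
#' @export
renderSpec <- function(mode = "vista", flowRange = c(0, 2.5),
                       palette = "vista") {
  new("RenderSpec", mode = mode, flowRange = flowRange, palette = palette)
}

normalizeBase <- function(base) {
  rng <- range(base, finite = TRUE)
  if (rng[2] > rng[1]) (base - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(base), ncol(base))
}

#' Render a diameter-class map
#'
#' Capillaries render gray, medium vessels green, major vessels magenta,
#' each modulated by the (normalized) base OCTA intensity; background pixels
#' keep the base as grayscale.
#'
#' @param classes a [DiameterClassMap-class].
#' @param base numeric base (OCTA) image, same shape.
#' @return `(ny, nx, 3)` RGB array in \[0, 1\].
#' @export
renderDiameterMap <- function(classes, base) {
  stopifnot(is(classes, "DiameterClassMap"),
            all(dim(classes@labels) == dim(base)))
  b <- normalizeBase(base)
  lab <- classes@labels
  hues <- rbind(background = c(1, 1, 1), capillary = c(1, 1, 1),
                medium = c(0, 1, 0), major = c(1, 0, 1))
  rgb <- array(0, c(nrow(b), ncol(b), 3))
  for (ch in 1:3) {
    plane <- b * hues[lab + 1L, ch]
    rgb[, , ch] <- matrix(plane, nrow(b), ncol(b))
  }
  rgb
}

vistaPalette <- function() colorRamp(c("blue", "green", "yellow", "red"))

#' Render a VISTA image
#'
#' Maps the flow parameter through a blue-green-yellow-red ramp over
#' `spec@flowRange` (clipped at the ends) and alpha-blends it with the base
#' OCTA image; invalid pixels show the base only.  A vertical colour-bar
#' strip is attached as the `"colorbar"` attribute.
#'
#' @param fit a [VistaFitResult-class].
#' @param base numeric base (OCTA) image, same shape.
#' @param spec a [RenderSpec-class].
#' @param alpha blend weight of the flow colour on valid pixels.
#' @return `(ny, nx, 3)` RGB array with attribute `colorbar`.
#' @export
renderVista <- function(fit, base, spec = renderSpec(), alpha = 0.7) {
  stopifnot(is(fit, "VistaFitResult"), is(spec, "RenderSpec"),
            all(dim(fit@flowMap) == dim(base)))
  validObject(spec)
  pal <- vistaPalette()
  b <- normalizeBase(base)
  u <- (fit@flowMap - spec@flowRange[1]) /
    (spec@flowRange[2] - spec@flowRange[1])
  u <- clamp01(u)
  rgb <- array(rep(b, 3), c(nrow(b), ncol(b), 3))
  ok <- fit@validMask & !is.na(u)
  if (any(ok)) {
    cols <- pal(u[ok]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ok] <- (1 - alpha) * b[ok] + alpha * cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  ramp <- pal(seq(1, 0, length.out = 64)) / 255   # fast flow on top
  bar <- array(0, c(64, 8, 3))
  for (ch in 1:3) bar[, , ch] <- matrix(ramp[, ch], 64, 8)
  attr(rgb, "colorbar") <- bar
  rgb
}

#' Write an RGB array as PNG
#' @param rgb `(ny, nx, 3)` array in \[0, 1\].
#' @param path output path.
#' @export
writeRenderPNG <- function(rgb, path) {
  png::writePNG(clamp01(rgb), path)
  invisible(path)
}
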
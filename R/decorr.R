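# Multi-lag decorrelation from repeated complex frames.  The estimator is
# the magnitude of the windowed complex correlation coefficient (the cmOCA
# statistic): |sum a*conj(b)| / sqrt(sum|a|^2 sum|b|^2) over a small spatial
# kernel, which is invariant to per-frame complex gain and bounded by
# Cauchy-Schwarz to [0, 1].

#' RepeatedFrameSet: repeated complex frames of one scene
#'
#' @slot frames list of equally shaped complex matrices in repeat order.
#' @slot timestamps acquisition times in seconds, strictly increasing.
#' @slot pixelSize pixel size, um.
#' @export
setClass("RepeatedFrameSet", representation(frames = "list",
                                            timestamps = "numeric",
                                            pixelSize = "numeric"))

setValidity("RepeatedFrameSet", function(object) {
  if (length(object@frames) < 2) return("need at least 2 frames")
  if (length(object@frames) != length(object@timestamps))
    return("one timestamp per frame required")
  dims <- vapply(object@frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) != 1) return("frames must share one shape")
  if (is.unsorted(object@timestamps, strictly = TRUE))
    return("timestamps must be strictly increasing")
  TRUE
})

#' @param frames list of complex matrices.
#' @param timestamps times in seconds.
#' @param pixelSize pixel size, um.
#' @rdname RepeatedFrameSet-class
#' @export
repeatedFrameSet <- function(frames, timestamps, pixelSize) {
  new("RepeatedFrameSet", frames = frames, timestamps = timestamps,
      pixelSize = pixelSize)
}

setMethod("show", "RepeatedFrameSet", function(object) {
  d <- dim(object@frames[[1]])
  cat("RepeatedFrameSet:", length(object@frames), "frames of", d[1], "x",
      d[2], "@", object@pixelSize, "um/px\n")
})

#' DecorrelationStack: per-lag decorrelation images
#'
#' @slot lags ascending lag times, ms.
#' @slot images list of decorrelation matrices with values in \[0, 1\].
#' @slot pixelSize pixel size, um.
#' @slot nPairsPerLag number of frame pairs averaged per lag.
#' @export
setClass("DecorrelationStack", representation(lags = "numeric",
                                              images = "list",
                                              pixelSize = "numeric",
                                              nPairsPerLag = "integer"))

setValidity("DecorrelationStack", function(object) {
  if (length(object@lags) != length(object@images))
    return("one image per lag required")
  if (length(object@lags) > 1 &&
      is.unsorted(object@lags, strictly = TRUE))
    return("lags must be strictly ascending")
  rng <- range(vapply(object@images, function(m) range(m), numeric(2)))
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    return("decorrelation values must lie in [0, 1]")
  TRUE
})

#' @param lags lag times, ms.
#' @param images list of matrices.
#' @param pixelSize pixel size, um.
#' @param nPairsPerLag pairs averaged per lag.
#' @rdname DecorrelationStack-class
#' @export
decorrelationStack <- function(lags, images, pixelSize,
                               nPairsPerLag = rep(1L, length(lags))) {
  new("DecorrelationStack", lags = lags, images = images,
      pixelSize = pixelSize, nPairsPerLag = as.integer(nPairsPerLag))
}

setMethod("show", "DecorrelationStack", function(object) {
  d <- dim(object@images[[1]])
  cat("DecorrelationStack:", length(object@lags), "lags (",
      paste(signif(object@lags, 4), collapse = ", "), "ms ) of", d[1], "x",
      d[2], "@", object@pixelSize, "um/px\n")
})

#' Lags of a decorrelation stack
#' @param stack a [DecorrelationStack-class].
#' @return lag times in ms.
#' @export
stackLags <- function(stack) {
  stopifnot(is(stack, "DecorrelationStack")); stack@lags
}

#' Images of a decorrelation stack
#' @param stack a [DecorrelationStack-class].
#' @return list of matrices.
#' @export
stackImages <- function(stack) {
  stopifnot(is(stack, "DecorrelationStack")); stack@images
}

#' Windowed complex correlation of two frames
#'
#' Per pixel, `|sum_K a conj(b)| / sqrt(sum_K |a|^2 sum_K |b|^2)` over a
#' centred window `K` of `kernel = c(kx, kz)` samples along the fast (x,
#' columns) and depth (z, rows) axes; edge windows are truncated.  Windows
#' with zero energy in either frame yield 0 and are flagged in the
#' `"zeroEnergy"` attribute.  If the effective window holds a single sample
#' the magnitude is identically 1 and a warning is raised.
#'
#' @param frameA,frameB complex matrices of equal shape.
#' @param kernel `c(kx, kz)` odd window sizes; default `c(1, 3)`.
#' @return correlation matrix in \[0, 1\] with attribute `zeroEnergy`.
#' @export
complexCorrelation <- function(frameA, frameB, kernel = c(1, 3)) {
  stopifnot(all(dim(frameA) == dim(frameB)), length(kernel) == 2,
            all(kernel >= 1), all(kernel %% 2 == 1))
  kx <- as.integer(kernel[1]); kz <- as.integer(kernel[2])
  if (min(nrow(frameA), kz) * min(ncol(frameA), kx) < 2)
    warning("correlation window degrades to a single sample; ",
            "the correlation magnitude is identically 1")
  num <- Mod(boxSum(frameA * Conj(frameB), rows = kz, cols = kx))
  ea <- boxSum(Mod(frameA)^2, rows = kz, cols = kx)
  eb <- boxSum(Mod(frameB)^2, rows = kz, cols = kx)
  den <- sqrt(ea * eb)
  zero <- den == 0
  den[zero] <- 1
  out <- clamp01(num / den)
  out[zero] <- 0
  attr(out, "zeroEnergy") <- zero
  out
}

#' Multi-lag decorrelation of a repeated frame set
#'
#' For each lag index `k = 1 .. n-1`, averages `1 - complexCorrelation` over
#' all `n - k` frame pairs `(i, i + k)` (or only the first such pair with
#' `adjacentOnly = TRUE`).  Lag times come from the timestamp differences,
#' which must be uniform to within 1 ns.
#'
#' An optional additive noise-floor subtraction (`noiseFloorSubtract`, off by
#' default) removes a constant estimator bias from every decorrelation image
#' before re-clamping to \[0, 1\].
#'
#' @param frames a [RepeatedFrameSet-class].
#' @param kernel correlation window, see [complexCorrelation()].
#' @param adjacentOnly average only the pair `(1, 1 + k)` per lag.
#' @param noiseFloorSubtract constant subtracted from every decorrelation
#'   image (default 0 = plain estimator).
#' @return a [DecorrelationStack-class].
#' @export
decorrelationMultilag <- function(frames, kernel = c(1, 3),
                                  adjacentOnly = FALSE,
                                  noiseFloorSubtract = 0) {
  stopifnot(is(frames, "RepeatedFrameSet"))
  validObject(frames)
  n <- length(frames@frames)
  dts <- diff(frames@timestamps)
  if (max(dts) - min(dts) > 1e-9)
    stop("mixed-lag error: frame timestamps are not uniformly spaced")
  dtMs <- mean(dts) * 1e3
  lags <- seq_len(n - 1) * dtMs
  nPairs <- integer(n - 1)
  imgs <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    idx <- if (adjacentOnly) 1L else seq_len(n - k)
    acc <- 0
    for (i in idx)
      acc <- acc + (1 - complexCorrelation(frames@frames[[i]],
                                           frames@frames[[i + k]], kernel))
    imgs[[k]] <- clamp01(acc / length(idx) - noiseFloorSubtract)
    nPairs[k] <- length(idx)
  }
  decorrelationStack(lags = lags, images = imgs,
                     pixelSize = frames@pixelSize, nPairsPerLag = nPairs)
}
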
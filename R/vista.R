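# VISTA: per-pixel fit of the saturating exponential decorrelation model
# Decorrelation(t) = D * (1 - exp(-t/tau)).  D is the OCTA signal saturation
# level; 1/tau (ms^-1) is the flow parameter, a blood-flow-velocity
# surrogate.  The least-squares problem is solved by profiling: for fixed
# tau the optimal D is closed-form (clamped to [0,1]), leaving a 1-D search
# over tau done on a log grid with golden-section refinement, vectorized
# over all pixels.

#' VistaFitResult: per-pixel VISTA model fit
#'
#' @slot DMap saturation level in \[0, 1\]; `NA` where invalid.
#' @slot tauMap time constant, ms; `NA` where invalid.
#' @slot flowMap flow parameter `1/tau`, ms^-1; `NA` where invalid.
#' @slot validMask logical matrix of successful fits.
#' @slot rssMap residual sum of squares; `NA` where invalid.
#' @export
setClass("VistaFitResult", representation(DMap = "matrix", tauMap = "matrix",
                                          flowMap = "matrix",
                                          validMask = "matrix",
                                          rssMap = "matrix"))

setValidity("VistaFitResult", function(object) {
  v <- object@validMask
  if (any(is.na(object@flowMap[v])) || any(is.na(object@tauMap[v])))
    return("valid pixels must carry flow and tau values")
  if (any(abs(object@flowMap[v] * object@tauMap[v] - 1) > 1e-9))
    return("flowMap must equal 1/tauMap on valid pixels")
  if (any(!is.na(object@DMap) & (object@DMap < 0 | object@DMap > 1)))
    return("DMap must lie in [0, 1]")
  TRUE
})

setMethod("show", "VistaFitResult", function(object) {
  nv <- sum(object@validMask)
  cat("VistaFitResult", nrow(object@flowMap), "x", ncol(object@flowMap),
      ";", nv, "valid pixels\n")
  if (nv > 0)
    cat("  flow parameter median",
        signif(median(object@flowMap[object@validMask]), 4), "ms^-1\n")
})

#' Flow-parameter, tau and validity accessors
#' @param fit a [VistaFitResult-class].
#' @return the corresponding matrix.
#' @export
flowMap <- function(fit) { stopifnot(is(fit, "VistaFitResult")); fit@flowMap }

#' @rdname flowMap
#' @export
tauMap <- function(fit) { stopifnot(is(fit, "VistaFitResult")); fit@tauMap }

#' @rdname flowMap
#' @export
validMask <- function(fit) {
  stopifnot(is(fit, "VistaFitResult")); fit@validMask
}

#' Saturating exponential decorrelation model
#'
#' `D * (1 - exp(-t / tau))`: zero at `t = 0`, saturating at `D`.
#'
#' @param t lag time(s), ms.
#' @param D saturation level.
#' @param tau time constant, ms; must be > 0.
#' @return model decorrelation value(s).
#' @export
vistaModel <- function(t, D, tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  D * (1 - exp(-t / tau))
}

# Profiled objective pieces, vectorized over pixels.  V: npix x nlag matrix.
# Returns D-hat (clamped) and RSS for a per-pixel tau vector.
vistaProfileRss <- function(V, lags, tau, sumV2) {
  G <- 1 - exp(-outer(1 / tau, lags))
  vg <- rowSums(V * G)
  gg <- rowSums(G * G)
  D <- clamp01(vg / gg)
  list(D = D, rss = sumV2 - 2 * D * vg + D^2 * gg)
}

# Core fitter on a value matrix (npix x nlag).  Returns D, tau, rss, valid,
# boundHit vectors.
vistaFitCore <- function(V, lags, tauRange, noiseFloor, nGrid = 60L,
                         refineIter = 60L) {
  npix <- nrow(V)
  sumV2 <- rowSums(V * V)
  grid <- exp(seq(log(tauRange[1]), log(tauRange[2]), length.out = nGrid))
  best <- rep(Inf, npix)
  bestIdx <- rep(1L, npix)
  for (j in seq_len(nGrid)) {
    r <- vistaProfileRss(V, lags, rep(grid[j], npix), sumV2)$rss
    better <- r < best
    best[better] <- r[better]
    bestIdx[better] <- j
  }
  lo <- log(grid[pmax(1L, bestIdx - 1L)])
  hi <- log(grid[pmin(nGrid, bestIdx + 1L)])
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- vistaProfileRss(V, lags, exp(x1), sumV2)$rss
  f2 <- vistaProfileRss(V, lags, exp(x2), sumV2)$rss
  for (it in seq_len(refineIter)) {
    take1 <- f1 <= f2
    hi[take1] <- x2[take1]; x2[take1] <- x1[take1]; f2[take1] <- f1[take1]
    x1[take1] <- hi[take1] - gr * (hi[take1] - lo[take1])
    lo[!take1] <- x1[!take1]; x1[!take1] <- x2[!take1]
    f1[!take1] <- f2[!take1]
    x2[!take1] <- lo[!take1] + gr * (hi[!take1] - lo[!take1])
    n1 <- which(take1); n2 <- which(!take1)
    if (length(n1))
      f1[n1] <- vistaProfileRss(V[n1, , drop = FALSE], lags, exp(x1[n1]),
                                sumV2[n1])$rss
    if (length(n2))
      f2[n2] <- vistaProfileRss(V[n2, , drop = FALSE], lags, exp(x2[n2]),
                                sumV2[n2])$rss
  }
  tau <- exp((lo + hi) / 2)
  fin <- vistaProfileRss(V, lags, tau, sumV2)
  static <- apply(V <= noiseFloor, 1, all)
  boundHit <- tau <= tauRange[1] * (1 + 1e-3) |
    tau >= tauRange[2] / (1 + 1e-3)
  list(D = fin$D, tau = tau, rss = fin$rss,
       valid = !static & !boundHit, boundHit = boundHit)
}

#' Fit the VISTA model at a single pixel
#'
#' Bounded least squares of `D * (1 - exp(-t/tau))` with `D` in \[0, 1\] and
#' `tau` in `tauRange`, via the same profiled solver as [fitVistaMap()].
#' The fit is marked invalid when all values sit at or below `noiseFloor`
#' (static tissue) or when `tau` lands on a range bound.  As a special case,
#' a single (lag, value) pair with a fixed saturation level `DFixed` is
#' inverted in closed form: `tau = -t / log(1 - v / D)`.
#'
#' @param values decorrelation values.
#' @param lags lag times, ms, ascending, same length as `values`.
#' @param tauRange `c(min, max)` bounds on tau, ms.
#' @param noiseFloor static-tissue decorrelation floor; default 0.05.
#' @param DFixed optional fixed saturation level (enables the single-lag
#'   closed form).
#' @return list with `D`, `tau`, `flow`, `rss`, `valid`.
#' @export
fitVistaPixel <- function(values, lags, tauRange = c(0.05, 100),
                          noiseFloor = 0.05, DFixed = NULL) {
  keep <- is.finite(values) & is.finite(lags)
  values <- values[keep]; lags <- lags[keep]
  if (!is.null(DFixed) && length(values) == 1) {
    if (values <= 0 || values >= DFixed)
      return(list(D = DFixed, tau = NA_real_, flow = NA_real_,
                  rss = NA_real_, valid = FALSE))
    tau <- -lags / log(1 - values / DFixed)
    return(list(D = DFixed, tau = tau, flow = 1 / tau, rss = 0,
                valid = TRUE))
  }
  if (length(values) < 2)
    return(list(D = NA_real_, tau = NA_real_, flow = NA_real_,
                rss = NA_real_, valid = FALSE))
  ord <- order(lags)
  V <- matrix(values[ord], nrow = 1)
  fit <- vistaFitCore(V, lags[ord], tauRange, noiseFloor)
  list(D = fit$D, tau = fit$tau, flow = 1 / fit$tau, rss = fit$rss,
       valid = fit$valid)
}

#' Fit the VISTA model over a decorrelation stack
#'
#' Applies the profiled bounded least-squares fit at every pixel of `mask`
#' (all pixels when `mask` is `NULL`).  Pixels whose values never exceed
#' `noiseFloor`, or whose fitted `tau` hits a bound, are marked invalid and
#' carry no values.  Deterministic given its inputs.
#'
#' @param stack a [DecorrelationStack-class] with at least 2 lags.
#' @param mask optional [VesselMask-class] restricting the fit.
#' @param tauRange `c(min, max)` tau bounds, ms; the default \[0.05, 100\]
#'   (flow 0.01-20 ms^-1) comfortably covers retinal flow parameters.
#' @param noiseFloor static-tissue floor; default 0.05.
#' @return a [VistaFitResult-class].
#' @export
fitVistaMap <- function(stack, mask = NULL, tauRange = c(0.05, 100),
                        noiseFloor = 0.05) {
  stopifnot(is(stack, "DecorrelationStack"))
  validObject(stack)
  if (length(stack@lags) < 2)
    stop("at least 2 lags are required to fit the VISTA model")
  dims <- dim(stack@images[[1]])
  sel <- if (is.null(mask)) matrix(TRUE, dims[1], dims[2]) else {
    stopifnot(is(mask, "VesselMask"))
    if (!all(dim(mask@mask) == dims))
      stop("mask shape does not match the stack")
    mask@mask
  }
  blank <- matrix(NA_real_, dims[1], dims[2])
  res <- new("VistaFitResult", DMap = blank, tauMap = blank,
             flowMap = blank, validMask = matrix(FALSE, dims[1], dims[2]),
             rssMap = blank)
  idx <- which(sel)
  if (length(idx) == 0) return(res)
  V <- vapply(stack@images, function(im) im[idx], numeric(length(idx)))
  V <- matrix(V, nrow = length(idx))
  fit <- vistaFitCore(V, stack@lags, tauRange, noiseFloor)
  ok <- fit$valid
  res@validMask[idx] <- ok
  res@DMap[idx[ok]] <- fit$D[ok]
  res@tauMap[idx[ok]] <- fit$tau[ok]
  res@flowMap[idx[ok]] <- 1 / fit$tau[ok]
  res@rssMap[idx[ok]] <- fit$rss[ok]
  validObject(res)
  res
}
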
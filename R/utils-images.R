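# Shared image primitives: Gaussian smoothing, finite-difference gradients,
# truncated-window box statistics.  All operate on plain numeric matrices
# (row = y, col = x) with zero padding outside the image.

#' Gaussian smoothing of a 2D image
#'
#' Convolves with a normalized, truncated (3 sigma) Gaussian kernel using
#' replicate padding at the borders, so a constant image stays exactly
#' constant.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns the input.
#' @return smoothed matrix of the same shape.
#' @keywords internal
gaussianSmooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  u <- seq(-h, h)
  g <- exp(-u^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  ri <- c(rep(1L, h), seq_len(nrow(image)), rep(nrow(image), h))
  ci <- c(rep(1L, h), seq_len(ncol(image)), rep(ncol(image), h))
  padded <- image[ri, ci, drop = FALSE]
  sm <- EBImage::filter2(padded, k, boundary = 0)
  sm[h + seq_len(nrow(image)), h + seq_len(ncol(image)), drop = FALSE]
}

#' Central-difference gradient
#'
#' @param image numeric matrix.
#' @return list with components `gx` (along columns / x) and `gy` (along
#'   rows / y), in intensity units per pixel; one-sided differences at edges.
#' @keywords internal
imageGradient <- function(image) {
  ny <- nrow(image); nx <- ncol(image)
  gx <- matrix(0, ny, nx)
  gy <- matrix(0, ny, nx)
  if (nx >= 3) gx[, 2:(nx - 1)] <- (image[, 3:nx] - image[, 1:(nx - 2)]) / 2
  if (nx >= 2) {
    gx[, 1] <- image[, 2] - image[, 1]
    gx[, nx] <- image[, nx] - image[, nx - 1]
  }
  if (ny >= 3) gy[2:(ny - 1), ] <- (image[3:ny, ] - image[1:(ny - 2), ]) / 2
  if (ny >= 2) {
    gy[1, ] <- image[2, ] - image[1, ]
    gy[ny, ] <- image[ny, ] - image[ny - 1, ]
  }
  list(gx = gx, gy = gy)
}

# Sum of `x` over a centred (rows x cols) window, edge windows truncated.
# Works for numeric and complex matrices (direct shift accumulation; windows
# used in this package are small).
boxSum <- function(x, rows, cols) {
  ny <- nrow(x); nx <- ncol(x)
  hr <- (rows - 1L) %/% 2L
  hc <- (cols - 1L) %/% 2L
  out <- matrix(if (is.complex(x)) 0 + 0i else 0, ny, nx)
  for (dr in -hr:hr) {
    r0 <- max(1L, 1L - dr); r1 <- min(ny, ny - dr)
    if (r0 > r1) next
    sr <- r0:r1
    tr <- sr + dr
    for (dc in -hc:hc) {
      c0 <- max(1L, 1L - dc); c1 <- min(nx, nx - dc)
      if (c0 > c1) next
      sc <- c0:c1
      tc <- sc + dc
      out[sr, sc] <- out[sr, sc] + x[tr, tc]
    }
  }
  out
}

# Count of in-window samples for the same truncated window.
boxCount <- function(ny, nx, rows, cols) {
  boxSum(matrix(1, ny, nx), rows, cols)
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

# Bilinear spread of weight at fractional offset (dy, dx) onto an integer
# offset grid held as a matrix indexed [dy + h + 1, dx + h + 1].
spreadBilinear <- function(kern, dy, dx, w, h) {
  iy <- floor(dy); ix <- floor(dx)
  fy <- dy - iy;  fx <- dx - ix
  for (p in 0:1) for (q in 0:1) {
    wt <- w * (if (p == 0) 1 - fy else fy) * (if (q == 0) 1 - fx else fx)
    r <- iy + p + h + 1L
    c <- ix + q + h + 1L
    kern[r, c] <- kern[r, c] + wt
  }
  kern
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions;
# zero outside the image.  Vectorized over positions.
interpBilinear <- function(m, ry, cx) {
  ny <- nrow(m); nx <- ncol(m)
  i0 <- floor(ry); j0 <- floor(cx)
  fy <- ry - i0;  fx <- cx - j0
  val <- numeric(length(ry))
  for (p in 0:1) for (q in 0:1) {
    ii <- i0 + p; jj <- j0 + q
    wt <- (if (p == 0) 1 - fy else fy) * (if (q == 0) 1 - fx else fx)
    ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx & wt > 0
    if (any(ok)) val[ok] <- val[ok] + wt[ok] * m[cbind(ii[ok], jj[ok])]
  }
  val
}
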
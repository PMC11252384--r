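# Shared fixture builders.  All phantoms are generated in code; a straight
# horizontal vessel at row position `yMm` spans most of the field width.
# nativeLags() is the lag set of the default acquisition (1.28 ms
# fundamental interscan time, 5 repeats).

straightVessel <- function(yMm, diameterUm, tauMs, widthMm = 0.64, D = 1) {
  vesselSpec(rbind(c(0.03, yMm), c(widthMm - 0.03, yMm)),
             diameter = diameterUm, tau = tauMs, D = D)
}

# Three-class phantom: 12 / 30 / 48 um tubes with distinct tau, 2.5 um
# pixels.  180 x 256 grid = 0.45 x 0.64 mm field.
threeClassPhantom <- function(pixelSize = 2.5, taus = c(1.0, 0.7, 0.4)) {
  specs <- list(straightVessel(0.08, 12, taus[1]),
                straightVessel(0.22, 30, taus[2]),
                straightVessel(0.36, 48, taus[3]))
  list(phantom = buildPhantom(specs, pixelSize, c(180, 256)), specs = specs)
}

# Per-vessel pixel selector from ground truth.
truthPixels <- function(phantom, diameterUm) {
  !is.na(phantom@diameterMap) & phantom@diameterMap == diameterUm
}

nativeLags <- function() c(1.28, 2.56, 3.84, 5.12)

# Direct per-pixel circle-flux integration: the independent oracle for the
# OOF response.  Samples the smoothed-gradient field along the circle by
# bilinear interpolation and accumulates the outward flux matrix.
oofResponseOracle <- function(image, radiusUm, pixelSizeUm, sigmaPx = 1) {
  rPx <- radiusUm / pixelSizeUm
  sm <- octavista:::gaussianSmooth(image, sigmaPx)
  g <- octavista:::imageGradient(sm)
  M <- max(16L, 4L * as.integer(ceiling(2 * pi * rPx)))
  phi <- 2 * pi * (seq_len(M) - 0.5) / M
  w <- 1 / M   # dl / circumference
  ny <- nrow(image); nx <- ncol(image)
  out <- matrix(0, ny, nx)
  for (row in seq_len(ny)) for (col in seq_len(nx)) {
    ry <- row + rPx * sin(phi)
    cx <- col + rPx * cos(phi)
    gx <- octavista:::interpBilinear(g$gx, ry, cx)
    gy <- octavista:::interpBilinear(g$gy, ry, cx)
    q11 <- sum(gx * cos(phi)) * w
    q22 <- sum(gy * sin(phi)) * w
    q12 <- (sum(gx * sin(phi)) + sum(gy * cos(phi))) / 2 * w
    tr2 <- (q11 + q22) / 2
    disc <- sqrt(((q11 - q22) / 2)^2 + q12^2)
    lo <- tr2 - disc; hi <- tr2 + disc
    out[row, col] <- -(if (abs(lo) >= abs(hi)) lo else hi)
  }
  out
}

cgauss <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)

# Brute-force slab-MIP oracle: include voxel i (covering depths
# [(i-1), i) * dz) iff its interval intersects the half-open slab
# [inner, outer); per-column scan, independent of the index arithmetic used
# by extractSlabEnface.
mipOracle <- function(volume, boundaries, slab) {
  dz <- boundaries@axialPixel
  dep <- octavista:::slabDepths(boundaries, slab)
  d <- dim(volume)
  out <- matrix(NA_real_, d[1], d[2])
  for (row in seq_len(d[1])) for (col in seq_len(d[2])) {
    lo <- dep$inner[row, col]; hi <- dep$outer[row, col]
    if (hi <= lo) next
    vals <- c()
    for (iz in seq_len(d[3])) {
      v0 <- (iz - 1) * dz; v1 <- iz * dz
      if (v1 > lo && v0 < hi) vals <- c(vals, volume[row, col, iz])
    }
    if (length(vals)) out[row, col] <- max(vals)
  }
  out
}
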
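# Ammonite-scan geometry: repeated fast circle B-scans whose centres drift
# along a spiral.  The circle perimeter (not the field size) sets the
# fundamental interscan time, so wide fields keep a short interscan time.

#' ScanPlan: ammonite-scan acquisition parameters
#'
#' Encodes the acquisition geometry of an ammonite scan: a fast circular
#' B-scan of fixed perimeter repeated several times at each of many centre
#' positions drifting along a spiral that covers a circular field.
#'
#' @slot aScanRate A-scan (sweep) rate in Hz.
#' @slot circlePerimeter perimeter of the fast circle scan, mm.
#' @slot alinesPerCircle number of A-lines acquired along one circle.
#' @slot repeats number of consecutive repetitions of each circle (>= 2 so
#'   at least one interscan lag exists).
#' @slot nPositions number of circle-centre positions along the spiral.
#' @slot spiralPerimeter total path length of the spiral drift, mm.
#' @slot fieldDiameter imaged field diameter, mm.
#'
#' @seealso [scanPlan()], [interscanTime()], [lagTimes()],
#'   [totalAcquisitionTime()], [generateTrajectory()]
#' @export
setClass("ScanPlan", representation(
  aScanRate = "numeric",
  circlePerimeter = "numeric",
  alinesPerCircle = "numeric",
  repeats = "numeric",
  nPositions = "numeric",
  spiralPerimeter = "numeric",
  fieldDiameter = "numeric"
))

setValidity("ScanPlan", function(object) {
  v <- c(object@aScanRate, object@circlePerimeter, object@alinesPerCircle,
         object@repeats, object@nPositions, object@spiralPerimeter,
         object@fieldDiameter)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all scan-plan fields must be finite and > 0")
  if (object@repeats < 2)
    return("repeats must be >= 2 (at least one interscan lag)")
  if (object@circlePerimeter / pi > object@fieldDiameter)
    return("circle diameter (perimeter/pi) exceeds the field diameter")
  TRUE
})

#' Construct a ScanPlan
#'
#' Defaults reproduce the published acquisition: 400 kHz sweep rate, 4.5 mm
#' circle perimeter sampled with 512 A-lines (1.28 ms fundamental interscan
#' time), 5 repeats at each of 2048 positions along a 54 mm spiral covering a
#' 7 mm field (about 13 s total).
#'
#' @param aScanRate A-scan rate, Hz.
#' @param circlePerimeter circle perimeter, mm.
#' @param alinesPerCircle A-lines per circle.
#' @param repeats circle repetitions per position.
#' @param nPositions circle-centre positions along the spiral.
#' @param spiralPerimeter spiral path length, mm.
#' @param fieldDiameter field diameter, mm.
#' @return a [ScanPlan-class] object.
#' @examples
#' plan <- scanPlan()
#' interscanTime(plan)        # 1.28 ms
#' totalAcquisitionTime(plan) # ~13.1 s
#' @export
scanPlan <- function(aScanRate = 4e5, circlePerimeter = 4.5,
                     alinesPerCircle = 512, repeats = 5, nPositions = 2048,
                     spiralPerimeter = 54, fieldDiameter = 7) {
  new("ScanPlan", aScanRate = aScanRate, circlePerimeter = circlePerimeter,
      alinesPerCircle = alinesPerCircle, repeats = repeats,
      nPositions = nPositions, spiralPerimeter = spiralPerimeter,
      fieldDiameter = fieldDiameter)
}

setMethod("show", "ScanPlan", function(object) {
  cat("ScanPlan:", object@alinesPerCircle, "A-lines/circle @",
      object@aScanRate / 1e3, "kHz,", object@repeats, "repeats,",
      object@nPositions, "positions\n")
  cat("  circle perimeter", object@circlePerimeter, "mm; spiral",
      object@spiralPerimeter, "mm; field", object@fieldDiameter, "mm\n")
  cat("  interscan time", format(interscanTime(object)), "ms; total",
      format(round(totalAcquisitionTime(object), 3)), "s\n")
})

#' Fundamental interscan time of a scan plan
#'
#' Time between successive passes over the same A-line position, i.e. the
#' duration of one circle: A-lines per circle divided by the A-scan rate.
#'
#' @param plan a [ScanPlan-class].
#' @return interscan time in milliseconds.
#' @export
interscanTime <- function(plan) {
  stopifnot(is(plan, "ScanPlan"))
  validObject(plan)
  plan@alinesPerCircle / plan@aScanRate * 1e3
}

#' Available interscan lag times
#'
#' With `repeats` repetitions the frame pairs span lags at every integer
#' multiple of the fundamental interscan time up to `repeats - 1`.
#'
#' @param plan a [ScanPlan-class].
#' @return ascending numeric vector of lag times, ms.
#' @export
lagTimes <- function(plan) {
  stopifnot(is(plan, "ScanPlan"))
  validObject(plan)
  if (plan@repeats < 2)
    stop("at least 2 repeats are required to form an interscan lag")
  seq_len(plan@repeats - 1) * interscanTime(plan)
}

#' Total acquisition time
#'
#' Closed form `repeats * nPositions * interscanTime` (fly-back between
#' circles is not modelled; timestamps are contiguous).
#'
#' @param plan a [ScanPlan-class].
#' @return total acquisition time in seconds.
#' @export
totalAcquisitionTime <- function(plan) {
  stopifnot(is(plan, "ScanPlan"))
  validObject(plan)
  plan@repeats * plan@nPositions * interscanTime(plan) / 1e3
}

# Arc length of the Archimedean spiral r = a*theta from 0 to theta.
spiralArcLength <- function(a, theta) {
  (a / 2) * (theta * sqrt(1 + theta^2) + asinh(theta))
}

#' Generate the sample trajectory of an ammonite scan
#'
#' Circle centres are placed at equal arc-length steps along an Archimedean
#' spiral `r = a*theta` starting at the field centre; `a` is chosen so the
#' spiral path length equals `spiralPerimeter` and its outermost centre puts
#' the circle tangent to the field boundary.  Each circle is sampled with
#' `alinesPerCircle` equally spaced points and repeated `repeats` times;
#' timestamps advance by one sweep period per A-line (a sample's timestamp is
#' its completion time, so the last equals [totalAcquisitionTime()]).
#'
#' @param plan a [ScanPlan-class].
#' @return a `data.frame` with columns `x_mm`, `y_mm`, `t_s`, `circle`
#'   (position index), `repeat` (repetition index) and `aline`, one row per
#'   A-line in acquisition order.
#' @export
generateTrajectory <- function(plan) {
  stopifnot(is(plan, "ScanPlan"))
  validObject(plan)
  rCircle <- plan@circlePerimeter / (2 * pi)
  rMax <- plan@fieldDiameter / 2 - rCircle
  if (rMax < 0)
    stop("geometry error: circle radius exceeds the field radius")
  n <- plan@nPositions
  if (n == 1 || rMax == 0) {
    cx <- rep(0, n); cy <- rep(0, n)
  } else {
    S <- plan@spiralPerimeter
    if (S <= rMax)
      stop("geometry error: spiral perimeter too short to reach the field edge")
    # solve for a: arc length at theta_max = rMax / a equals S
    f <- function(a) spiralArcLength(a, rMax / a) - S
    a <- uniroot(f, lower = rMax^2 / (2 * S), upper = S * 10,
                 tol = 1e-12)$root
    thetaMax <- rMax / a
    s <- seq(0, S, length.out = n)
    # invert arc length -> theta: monotone grid start then Newton polish
    grid <- seq(0, thetaMax, length.out = 4096)
    th <- approx(spiralArcLength(a, grid), grid, xout = s, rule = 2)$y
    for (i in 1:3) th <- th - (spiralArcLength(a, th) - s) / (a * sqrt(1 + th^2))
    th[1] <- 0; th[n] <- thetaMax
    cx <- a * th * cos(th)
    cy <- a * th * sin(th)
  }
  A <- as.integer(plan@alinesPerCircle)
  R <- as.integer(plan@repeats)
  phi <- 2 * pi * (seq_len(A) - 1) / A
  ringX <- rCircle * cos(phi)
  ringY <- rCircle * sin(phi)
  nPerPos <- A * R
  total <- nPerPos * n
  circleIdx <- rep(seq_len(n), each = nPerPos)
  repeatIdx <- rep(rep(seq_len(R), each = A), times = n)
  alineIdx <- rep(seq_len(A), times = R * n)
  x <- cx[circleIdx] + ringX[alineIdx]
  y <- cy[circleIdx] + ringY[alineIdx]
  t <- seq_len(total) / plan@aScanRate
  out <- data.frame(x_mm = x, y_mm = y, t_s = t, circle = circleIdx,
                    rep = repeatIdx, aline = alineIdx)
  names(out)[5] <- "repeat"
  out
}

#' Read or write a scan plan as JSON
#'
#' Keys: `a_scan_rate_hz`, `circle_perimeter_mm`, `alines_per_circle`,
#' `repeats`, `n_positions`, `spiral_perimeter_mm`, `field_diameter_mm`.
#'
#' @param path JSON file path.
#' @return `readScanPlan` returns a [ScanPlan-class]; `writeScanPlan`
#'   invisibly returns `path`.
#' @export
readScanPlan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a_scan_rate_hz", "circle_perimeter_mm", "alines_per_circle",
            "repeats", "n_positions", "spiral_perimeter_mm",
            "field_diameter_mm")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("scan-plan JSON missing keys: ", paste(miss, collapse = ", "))
  scanPlan(aScanRate = j$a_scan_rate_hz,
           circlePerimeter = j$circle_perimeter_mm,
           alinesPerCircle = j$alines_per_circle,
           repeats = j$repeats, nPositions = j$n_positions,
           spiralPerimeter = j$spiral_perimeter_mm,
           fieldDiameter = j$field_diameter_mm)
}

#' @param plan a [ScanPlan-class].
#' @rdname readScanPlan
#' @export
writeScanPlan <- function(plan, path) {
  stopifnot(is(plan, "ScanPlan"))
  jsonlite::write_json(list(
    a_scan_rate_hz = plan@aScanRate,
    circle_perimeter_mm = plan@circlePerimeter,
    alines_per_circle = plan@alinesPerCircle,
    repeats = plan@repeats,
    n_positions = plan@nPositions,
    spiral_perimeter_mm = plan@spiralPerimeter,
    field_diameter_mm = plan@fieldDiameter), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Columns `x_mm`, `y_mm`, `t_s`, `circle`, `repeat`, `aline`.
#'
#' @param trajectory data.frame from [generateTrajectory()].
#' @param path output CSV path.
#' @export
writeTrajectory <- function(trajectory, path) {
  write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
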
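---
title: "Methods: VISTA flow velocimetry, OOF vessel sizing, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VISTA flow velocimetry, OOF vessel sizing, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octavista)
```

# The model

OCTA contrasts moving blood against static tissue through the decorrelation
of repeated scans. With several repetitions of the same B-scan, decorrelation
can be observed at several interscan times (lags), and its growth with lag
carries velocity information. The package models this growth as a saturating
exponential,

$$\mathrm{Decorrelation}(t) \;=\; D\,\{1 - \exp(-t/\tau)\},$$

with $D \in [0,1]$ the OCTA signal saturation level and $\tau$ (ms) the
decay constant of the temporal autocorrelation. The fitted rate $1/\tau$
(ms$^{-1}$) is reported as the **flow parameter**, a *surrogate* of blood
flow velocity: it has physical dimensions of 1/time and increases with
velocity, but it is not an absolute velocity measurement.

Key assumptions:

* the temporal autocorrelation of the complex OCT signal at a perfused pixel
  decays exponentially with a single time constant;
* static tissue decorrelates only through estimator noise;
* the lag set spans the decay — the fundamental interscan time bounds the
  fastest measurable flow, and the longest lag the slowest (see
  *Identifiability* below).

## Acquisition geometry

The ammonite scan decouples field size from interscan time: a fast circle
B-scan (perimeter 4.5 mm, 512 A-lines at 400 kHz, hence a 1.28 ms
fundamental interscan time) is repeated 5 times, then its centre advances
along a spiral (path length 54 mm, 2048 positions) covering a 7 mm field in
$5 \times 2048 \times 1.28\,\mathrm{ms} = 13.1$ s. `generateTrajectory()`
realizes the spiral as an Archimedean $r = a\theta$ with $a$ solved so the
path length matches and the outermost circle stays tangent to the field
boundary; centres sit at equal arc-length steps (uniform areal coverage,
reproducible), fly-back between circles is not modelled (the published total
time equals the no-fly-back product), and a sample's timestamp is its
completion time so the last sample lands exactly at the total acquisition
time. The circle-overlap redundancy used for motion correction on real
devices has no role in this package (motion correction is out of scope), so
no overlap fraction is modelled.

# Decorrelation estimation

`complexCorrelation()` computes, per pixel, the magnitude of the windowed
complex correlation coefficient
$|\sum_K a\,\bar b| / \sqrt{\sum_K |a|^2 \sum_K |b|^2}$, which is invariant
to per-frame complex gain and bounded to $[0,1]$ by Cauchy–Schwarz. Edge
windows truncate; zero-energy windows return 0 and are flagged.
`decorrelationMultilag()` averages $1-$correlation over all $n-k$ frame
pairs with lag index $k$ (SNR-optimal; an adjacent-only mode exists), and
derives lag times from the timestamps, which must be uniformly spaced to
within 1 ns.

The window is a free `(kx, kz)` parameter. On real B-scans the conventional
choice is 1 × 3 along x × z. The synthetic path in this package produces
thin-slab *en-face* frames with no depth extent, where a 1-sample window
would be degenerate (the magnitude of a 1-sample complex correlation is
identically 1 — the package warns in that case). The synthetic pipeline
therefore uses a spatial 3 × 3 window: 9 samples reduce the magnitude bias
of the estimator (for few samples $E|\hat\rho|$ is substantially above
$|\rho|$, which compresses the usable decorrelation range and with it the
separation of fast flows).

# Vessel segmentation and diameter

`oofResponse()` implements 2-D optimally oriented flux: the image is
smoothed with a Gaussian ($\sigma$ = 1 pixel — enough to regularize the
gradient without displacing vessel edges at the 2.5–5 µm pixel sizes used
here), and the outward flux of the gradient through a circle of radius $r$
is assembled into a symmetric 2 × 2 matrix per pixel, normalized by the
circle circumference $2\pi r$ so responses are comparable across radii. The
response is minus the largest-magnitude eigenvalue: a bright tube whose
half-width matches $r$ pulls gradient vectors through the circle boundary
inward and scores positive; an inverted-contrast tube scores negative; a
constant image scores exactly zero, and the response is linear in contrast.
The flux integral is evaluated by FFT correlation with kernels holding the
circle-boundary weights (bilinearly spread, $\ge 4$ points per boundary
pixel); the test suite checks this against direct per-pixel numerical
integration of the same boundary samples to $10^{-6}$ relative.

`oofMultiscale()` scans radii 4–40 µm in 2 µm steps (vessel diameters
8–80 µm) and records the per-pixel argmax radius, ties broken toward the
smaller radius; radii under one pixel are skipped with a warning. Vessel
diameter is **twice the argmax radius**, assigned on every mask pixel, then
calibrated for the system point-spread function by quadrature subtraction
$\sqrt{\max(d^2 - \mathrm{PSF}^2,\ \mathrm{floor}^2)}$ with PSF FWHM
5.5 µm for the modelled instrument (0 = identity for synthetic data) and a
floor of one pixel. Classes follow half-open intervals: capillary < 20 µm,
medium [20, 40) µm, major ≥ 40 µm — 20.0 is medium and 40.0 is major.

`segmentVessels()` combines a global quantile threshold (default q = 0.80)
AND a local sliding-window threshold (mean + 0.5 SD over a 200 µm window,
truncated at edges), then removes connected components below 5 pixels. The
exact global/local recipe used on clinical data is not published; these
three knobs are exposed and their defaults chosen so that noiseless phantoms
segment to within a pixel of truth while pure-noise images keep a
false-positive area below the global quantile's complement.

# VISTA fitting

`fitVistaMap()` solves, per pixel, bounded least squares of
$D\{1-\exp(-t/\tau)\}$ with $D \in [0,1]$ and
$\tau \in [0.05, 100]$ ms (flow 0.01–20 ms$^{-1}$, a wide margin around the
0.6–2.5 ms$^{-1}$ range typical of retinal vessels). The problem is
*profiled*: for fixed $\tau$ the optimal $D$ is closed-form (clamped), so
only a 1-D search over $\tau$ remains. That search runs on a 60-point
logarithmic grid followed by golden-section refinement of the bracketing
interval, fully vectorized across pixels — deterministic, no random starts,
and accurate to well below the $10^{-4}$ relative tolerance the tests
assert. Fits are performed on the per-lag averaged decorrelation
(unweighted; four points from five repeats).

Validity rules: pixels whose values never exceed the noise floor (default
0.05 decorrelation units) are static; fits whose $\tau$ lands on a bound
are unidentifiable. Both are flagged invalid and carry no values, rather
than reporting a bound value as if it were a measurement.

**Identifiability.** With lags $1.28, \ldots, 5.12$ ms the model is
recoverable for $\tau$ roughly within $[\mathrm{lag}_{\min}/10,\,
10\,\mathrm{lag}_{\max}]$; far outside, the data are flat at $D$ (too fast)
or indistinguishable from static tissue (too slow). The test suite verifies
exact recovery inside this window and invalidity far outside it.

# The synthetic phantom

`buildPhantom()` rasterizes straight or polyline tubes of known diameter,
$\tau$, and saturation $D$ onto a pixel grid, with later vessels overwriting
earlier on overlap, and records exact truth maps (mask, diameter, $\tau$,
class, $D$). Two forward simulators feed the pipeline:

* `simulateDecorrelationStack()` evaluates the model directly per lag and
  adds clamped Gaussian noise (the literature gives no noise model for
  decorrelation values; the default SD of 0.02 is a plausible estimator
  dispersion and only a test-bed convention).
* `simulateComplexFrames()` generates repeated thin-slab complex frames as
  a circular complex Gaussian AR(1) process with autocorrelation
  $\exp(-t/\tau)$ at vessel pixels and exactly repeated values at static
  pixels — the simplest stationary process consistent with the exponential
  decay assumption.

What the phantom does *not* emulate: realistic OCT speckle statistics and
PSF blur, depth structure (a single z-plane per layer), motion and blink
artifacts, projection tails under the RPE, or flow pulsatility. Passing
tests therefore demonstrate the correctness of the estimators and fits
under the stated model, not clinical performance on real eyes.

**Study conditions for the end-to-end check.** The speckle-path
monotonicity test uses five $\tau$ levels geometrically spaced so the
simulated flow parameters span 0.4–2.5 ms$^{-1}$ — the detectable range
set by the 1.28 ms fundamental interscan time, and the range observed in
retinal vessels (flows above ~2.5 ms$^{-1}$ saturate the first lag and
cannot be ranked). Each level is a 30 µm tube of ≈ 900 pixels on a 5 µm
grid; medians per level are compared by Spearman rank correlation.

# Slab projection

`extractSlabEnface()` projects a volume between boundary surfaces by
maximum intensity. Depth increases away from the vitreous and offsets
"below" a surface add to depth; slabs are half-open $[\mathrm{inner},
\mathrm{outer})$ so adjacent slabs never double-count a voxel, and voxels
partially covered by the slab are included. The built-in slabs are
superficial (ILM to INL + 15.6 µm) and deep (INL + 15.6 to INL + 70.2 µm);
an outer-retina slab for neovascular lesions is configured per analysis
since its bounds are lesion-dependent. Columns where the slab is empty are
`NA` and flagged. Layer segmentation itself is an input, not part of the
package.

# ROI quantification

Class area percentages are shares of the *vessel area* inside the ROI (they
sum to 100 over detected classes, matching how vascular structure tables
are reported); a vessel-area/ROI-area density is provided separately. Mean
flow parameters are pixel-weighted means over valid fits — consequently the
overall mean equals the class-area-weighted mean of class means whenever
all fits are valid, an identity the tests assert. Undetected classes report
`NA`. The fovea centre for the standard 5-mm circular ROI is an input;
automatic fovea detection is out of scope.

# Numerical choices and degenerate inputs

* Tie-breaks: multi-scale argmax prefers the smaller radius; `cut()`-based
  classification uses left-closed intervals.
* Degenerate inputs: constant OOF responses give an empty mask with a
  warning; empty ROIs and maskless fits return empty records/all-invalid
  results rather than errors; fewer than two finite (lag, value) points is
  an invalid pixel.
* A single (lag, value) pair with fixed $D$ inverts in closed form,
  $\tau = -t/\log(1 - v/D)$.
* Float maps are stored in 32-bit TIFF after affine rescaling to $[0,1]$
  with offset/scale in a JSON sidecar, so round-trips are exact to float32
  precision.
* All randomness flows through explicit integer seeds; reruns are
  byte-identical.

# Known limitations

* The flow parameter is a velocity *surrogate*; no absolute calibration is
  attempted, and alternative decay models are not implemented.
* Per-pixel diameters shrink toward vessel edges (the local argmax radius
  reads the distance to the near edge), so class statistics mix in
  edge pixels of large vessels; centreline estimates are accurate to one
  scale step. A centreline-propagation variant would sharpen class
  separation at the cost of a skeletonization step.
* The decorrelation estimator's magnitude bias compresses fast flows when
  the window holds few samples; windows should hold ≥ 9 samples where the
  geometry allows.
* Noise-bias correction of the complex-correlation estimator (as in full
  cmOCA processing) is not reproduced; an additive noise-floor subtraction
  hook exists but is off by default.
* Problem sizes in the test suite (phantoms up to 180 × 256 pixels,
  $10^4$–$10^5$ Monte-Carlo draws) were chosen as the smallest that make
  the statistical assertions stable; they are stated in each test.
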
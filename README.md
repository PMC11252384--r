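# octavista

Quantitative blood-flow velocimetry for OCT angiography (OCTA) with
variable interscan time analysis (VISTA).

OCTA visualizes retinal vessels by the decorrelation of repeated scans, but
a single interscan time says nothing about how *fast* blood moves. When the
same B-scan is repeated several times, the decorrelation observed at lag
time *t* follows a saturating exponential

    Decorrelation(t) = D · (1 − exp(−t/τ))

where *D* is the OCTA signal saturation level and τ the decay constant. The
rate **1/τ (ms⁻¹) — the "flow parameter" — is a surrogate marker of blood
flow velocity**: faster flow decorrelates the speckle faster. Fitting this
model per pixel across several lags, and combining it with per-pixel vessel
diameters, yields flow statistics by vessel calibre (capillaries < 20 µm,
medium vessels 20–40 µm, major vessels ≥ 40 µm) — the kind of readout used
to characterize neovascular lesions and their response to treatment.

The package implements the full pipeline:

- **Ammonite-scan geometry** (`scanPlan`, `generateTrajectory`): repeated
  fast circle B-scans drifting along a spiral. The circle perimeter fixes
  the fundamental interscan time (512 A-lines at 400 kHz → 1.28 ms)
  independently of the field size; 5 repeats at 2048 positions take ≈ 13 s
  and provide lags of 1.28–5.12 ms.
- **Decorrelation estimation** (`complexCorrelation`,
  `decorrelationMultilag`): magnitude of the windowed complex correlation
  between repeated complex frames, averaged over all frame pairs per lag.
- **Slab en-face projection** (`builtinSlabs`, `extractSlabEnface`):
  maximum intensity projection between retinal boundary surfaces
  (superficial: ILM to INL + 15.6 µm; deep: INL + 15.6 µm to INL + 70.2 µm).
- **Vessel segmentation and diameter** (`oofMultiscale`, `segmentVessels`,
  `diameterFromOOF`): multi-scale optimally oriented flux (OOF) over radii
  4–40 µm; the response-maximizing radius estimates the vessel radius,
  PSF-calibrated in quadrature (≈ 5.5 µm transverse resolution).
- **VISTA fitting** (`fitVistaMap`): bounded per-pixel least squares of the
  saturating exponential, vectorized over the whole map.
- **ROI quantification** (`circularROI`, `quantifyROI`,
  `diameterFlowProfile`): class area shares (summing to 100%), mean flow
  per class, diameter-binned flow profiles.
- **Rendering** (`renderDiameterMap`, `renderVista`): gray/green/magenta
  diameter maps and blue→red false-colour VISTA images.
- **Synthetic phantoms** (`buildPhantom`, `simulateDecorrelationStack`,
  `simulateComplexFrames`): tubes of known diameter and τ, with forward
  simulation of decorrelation stacks and of AR(1) complex speckle frames,
  providing exact ground truth for every stage.

## Worked example

A three-vessel phantom (12/30/48 µm tubes with τ = 1.0/0.7/0.4 ms) analysed
with the full pipeline at the scanner's native lag set:

```r
library(octavista)
plan <- scanPlan()                       # published acquisition defaults
lagTimes(plan)
#> [1] 1.28 2.56 3.84 5.12

ph <- buildPhantom(list(
  vesselSpec(rbind(c(0.03, 0.08), c(0.61, 0.08)), diameter = 12, tau = 1.0),
  vesselSpec(rbind(c(0.03, 0.22), c(0.61, 0.22)), diameter = 30, tau = 0.7),
  vesselSpec(rbind(c(0.03, 0.36), c(0.61, 0.36)), diameter = 48, tau = 0.4)),
  pixelSize = 2.5, shape = c(180, 256))
stack <- simulateDecorrelationStack(ph, lagTimes(plan), noiseSd = 0)
octa  <- Reduce(`+`, stackImages(stack)) / length(stackLags(stack))

oof  <- oofMultiscale(octa, oofScaleSet(seq(4, 40, 2), 2.5))
mask <- segmentVessels(oof$response, 2.5)
mask
#> VesselMask 180 x 256 @ 2.5 um/px; 9216 vessel pixels

maps <- diameterFromOOF(oof, mask)
fit  <- fitVistaMap(stack, mask)
fit
#> VistaFitResult 180 x 256 ; 8212 valid pixels
#>   flow parameter median 2.5 ms^-1

roi <- ROIMask(matrix(TRUE, 180, 256), 2.5, "full-field")
quantifyROI(mask, maps$classMap, fit, roi)[
  , c("pct_capillary", "pct_medium", "pct_major",
      "flow_capillary", "flow_medium", "flow_major", "flow_mean")]
#>   pct_capillary pct_medium pct_major flow_capillary flow_medium flow_major
#> 1          27.5       46.5        26           1.79        1.99       2.08
#>   flow_mean
#> 1      1.96
```

The class area shares sum to 100%, and the mean flow parameter rises with
the diameter class — the behaviour the method is designed to expose (static
tissue fits are flagged invalid and excluded; class means mix in
edge-of-vessel pixels whose local diameter reads small, see the methods
vignette). The diameter-binned profile shows the same trend:

```r
diameterFlowProfile(maps$diameterMap, fit, roi, binWidth = 20)
#>   bin_center_um mean_flow sd_flow    n
#> 1            10      1.79   0.618 2524
#> 2            30      1.99   0.612 3352
#> 3            50      1.98   0.536  964
#> 4            70      2.16   0.500 1372
```

`runPipeline()` chains all stages from a YAML config and writes decorrelation
stacks (float TIFF + JSON), masks (PNG), renders (PNG), quantification
records (CSV) and a reproducibility log; `inst/cli/octavista.R` exposes the
same stages as a command-line tool.

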
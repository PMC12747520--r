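---
title: "Quantifying cerebral oxygen metabolism and mitochondrial bioenergetics with pamox"
author: "pamox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral oxygen metabolism and mitochondrial bioenergetics with pamox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamox)
```

# Scope

`pamox` implements a dual-modal quantification pipeline for studies of
neonatal brain energy metabolism:

1. **In vivo**: multi-parametric photoacoustic microscopy (PAM) of the
   cortical vasculature. Raw A-line signals are reduced to amplitude maps;
   single vessels are segmented; per-vessel diameter, oxygen saturation
   (sO~2~) and peak flow speed feed the regional read-outs — cerebral blood
   flow (CBF), oxygen extraction fraction (OEF) and the cerebral metabolic
   rate of oxygen (CMRO~2~).
2. **Ex vivo**: mitochondrial bioenergetics from instrument traces —
   Clark-electrode respirometry (state-resolved oxygen consumption rate,
   respiratory control ratio), Amplex UltraRed H~2~O~2~ emission with
   absolute calibration, MitoSOX superoxide kinetics, and rhodamine-123
   membrane-potential quenching.

Because the animal experiments themselves cannot be reproduced at the desk,
every stage is paired with a synthetic generator that emulates its input
with known ground truth. The generators are first-class, tested code: the
package's accuracy claims are *parameter-recovery* claims on those
phantoms, at stated noise levels.

# The hemodynamic model

At the single-vessel level the pipeline estimates a diameter $d$ (µm), a
peak axial flow speed $v$ (mm/s), a saturation $sO_2$ and a relative total
hemoglobin concentration $C_{Hb}$. Regional metabolism follows the
classical oxygen mass balance:

$$\mathrm{CBF} = \pi v d^2 / 8, \qquad
  \mathrm{OEF} = \frac{s_aO_2 - s_vO_2}{s_aO_2}, \qquad
  \mathrm{CMRO_2} = \xi \, C_{Hb} \, s_aO_2 \, \mathrm{OEF} \, \mathrm{CBF}.$$

$\pi v d^2/8$ is the volumetric flux of a parabolic (Poiseuille) profile
with peak speed $v$: mean speed $v/2$ times lumen area $\pi d^2/4$. The 8
is the product of those two factors of one half — implementers should not
"correct" it. `vesselFlow()` returns µL/min; `regionCbf()` sums the feeding
arteries and normalizes by the imaged region mass (default 0.002 g per
hemicortical field, configurable via `metabolismConfig()`), giving
mL/100 g/min. $s_aO_2$ and $s_vO_2$ aggregate the feeding arteries and
draining veins; the default weighting is by vessel flow (mass balance), a
uniform mean is available for sensitivity analysis. $\xi$ is the oxygen
binding capacity of hemoglobin, 0.014 L O~2~ per gram; with $C_{Hb}$ in
g/L, $\xi C_{Hb}$ is the mL O~2~ per mL of fully saturated blood, so
CMRO~2~ inherits CBF's mL/100 g/min scale. A venous saturation exceeding
the arterial one produces a *flagged*, unclipped negative OEF — silently
clipping would hide a real inconsistency. Percent-of-baseline reporting
(`baselinePercent()`) rounds half-up to integers, matching how such changes
are narrated in print.

# Stage by stage

## Envelope and amplitude maps

`envelope()` computes the magnitude of the analytic signal via the
frequency domain (positive frequencies doubled, negative zeroed) — the
standard Hilbert-transform envelope for A-lines. Values within about one
carrier period of either record end carry the usual analytic-signal edge
artifact; accuracy statements exclude them. `amplitudeMap()` projects a
raster of A-lines to 2-D by the per-line envelope peak. The
near-isosbestic 532 nm channel doubles as the concentration channel:
`chbMap()` maps its amplitude linearly to $C_{Hb}$ through a single
user-supplied calibration constant. How absolute concentration calibration
is performed on a given instrument is out of scope; the constant is a
configuration input.

## Vessel segmentation

`segmentVessel()` reimplements the single-vessel recipe: a region of
interest slightly larger than the vessel (a 1.2× padded bounding box by
default — the padding factor is a choice of this package, `pad = 0.2`),
Otsu's threshold to remove background, then removal of isolated or
spurious fragments. Numerical choices, fixed here because the method
description leaves them open:

* **Histogram**: 256 bins on min-max-normalized values; the threshold is a
  bin edge; tied maximizers of the between-class variance resolve to the
  lowest edge. Foreground is `value > threshold`.
* **Fragments**: 8-connected components smaller than `minFragmentPx`
  (default 10 px) are discarded; the largest component always survives, so
  the operation can never empty the mask.
* **Coordinates**: 0-based, row-major, half-open ROIs; diameters are
  reported in µm through the pixel spacing.

`vesselCenterline()` thins the mask (Zhang–Suen) and prunes the skeleton to
its longest geodesic path. `vesselDiameter()` averages mask chords
perpendicular to the local path direction over interior path points
(excluding two points at each end, where the direction estimate is
one-sided). A full-width-at-half-maximum profile diameter would be a
defensible alternative; the mask-chord definition was chosen because it is
determined by the segmentation itself and is exactly testable on
rectangles.

## Oximetry

`unmix()` solves the per-pixel 2×2 linear system in the oxy/deoxy
extinction coefficients at 532 and 558 nm. Negative unmixed concentrations
— possible under noise — are clipped to zero *before* forming
$sO_2 = \mathrm{HbO_2}/(\mathrm{HbO_2{+}Hb})$, so saturations always lie in
[0, 1]. Per-vessel saturation (`vesselSo2()`) is the amplitude-weighted
mean over mask pixels, weighting by the 532 nm amplitude. The shipped
extinction table (`hbExtinctionTable()`) holds approximate values in the
spirit of the standard hemoglobin compilations — near-isosbestic at 532 nm,
strongly deoxy-dominant at 558 nm; it is a replaceable configuration
object, and because phantom recovery uses one table for both render and
inversion, none of the recovery results depend on the compilation chosen.
`classifyVessels()` offers a labeled mode (preferred; phantom work uses
ground-truth labels) and a threshold mode (artery iff sO~2~ ≥ 0.8) that is
explicitly a placeholder heuristic.

## Flowmetry

The correlation channel models inter-line decorrelation as a
single-parameter Gaussian decay
$\rho(\tau) = \exp(-(\tau/\tau_c)^2)$ with $\tau_c$ inversely proportional
to speed, $v = k_{\mathrm{flow}}/\tau_c$. The calibration constant
$k_{\mathrm{flow}}$ (mm/s·s) is instrument-specific configuration
(`flowCalibration()`, default 0.002: a 2 ms decorrelation time ↔ 1 mm/s).
This family is shared between generator and fitter, making recovery an
exact closure test; it is the minimal identifiable model for a
single-parameter decay. Fitting choices:

* `fitSpeed()` fits $a \cdot \exp(-(\tau/\tau_c)^2)$ on lags within
  `maxLagS`, excluding lag 0. The free amplitude $a$ absorbs the uniform
  correlation attenuation that additive detection noise causes at all
  nonzero lags; noiseless data fit $a = 1$ exactly.
* Initialization is deterministic (log-linearized least squares; no random
  restarts).
* **No-flow floor**: a fitted $\tau_c$ beyond 10× the largest usable lag
  reports speed 0 rather than a divergent estimate.

## Synthetic data: what it emulates, and what it does not

`makeScene()`/`renderDualWavelength()` build a two-class vessel network
(defaults: six parallel vessels, three arteries at sO~2~ 0.95 and three
veins at 0.65, diameters 50–90 µm, $C_{Hb}$ 100 g/L, speeds 1–4 mm/s) in a
1200 × 800 µm field at 5 µm isotropic pixels — a hemicortical imaging field
at reduced scale, sized so the full recovery suites run in seconds. The
forward optical model is amplitude ∝ $C_{Hb}$ × extinction mixture, a
Gaussian PSF (6 µm FWHM default) and additive Gaussian noise parameterized
as SNR in dB relative to the peak amplitude. Pixels are isotropic by
default although real scanners may step anisotropically; anisotropy is
supported through `pixel_spacing_um`.

Deliberately **not** modeled: acoustic propagation, transducer bandwidth,
laser-fluence and spectral-coloring with depth, speckle statistics, motion,
and 3-D structure. Passing recovery tests therefore demonstrates that the
*analysis* is correct and well-conditioned under additive noise — not that
it is robust to every artifact of real instruments.

`renderAlineEnsemble()` constructs line ensembles whose pairwise Pearson
correlations reproduce the Gaussian decay *exactly* (a correlation-shaping
transform of an orthonormal zero-mean basis), so noiseless decorrelation
curves match the model to numerical precision rather than only in
expectation. `synthRespiroTrace()` and `synthFluoroTrace()` build
piecewise-linear and plateau/saturation traces with slope changes exactly
at the protocol events (substrate, ADP, DNP; rotenone then antimycin A;
substrate then CCCP), with defaults mirroring the published protocol
constants: 0.05 mg protein, 0.5 mL chamber, ADP at State 3 onset, 400 s
pre-rotenone recording, 300 s RH-123 baseline, MitoSOX saturation well
after the 300 s initial window.

## Bioenergetics estimators

All estimators are deterministic functions of the trace. `ocr()` converts
a least-squares O~2~ slope to nmol O~2~/mg/min via chamber volume and
protein mass; a rising-O~2~ window reports 0 with a flag. The State 3 →
State 4 boundary, which operators usually mark visually, is detected as the
least-squares two-segment changepoint between the ADP addition and the
next event (`segmentStates()`, settling buffer 10 s default); an explicit
`adp_exhausted` annotation takes precedence. `rcr()` is the State 3 /
State 4 ratio. `h2o2Calibration()` regresses response on known additions
*with* an intercept (dye background is nonzero); `h2o2Rate()` reports
nmol H~2~O~2~/mg/min — plots of such rates sometimes omit units, so the
unit convention is stated here and in the output. `mitosoxRate()` uses a
300 s initial window (configurable), well inside the ~25 min saturation.
`rh123Delta()` estimates plateaus as the mean of the last third of each
segment (robust to settling transients) and reports **both** candidate
membrane-potential read-outs — quench depth after substrate and
CCCP-released amplitude — since figure conventions differ between
laboratories.

## Statistics

The reporting layer matches common practice in this literature: pooled
variance Student t-test (`tTest2Sample()`; Welch is deliberately not the
default because the pooled test is what "Student t-test" names), classical
one-way ANOVA, two-way ANOVA with Type-II sums of squares (equal to the
classical decomposition for balanced designs), and mean ± SD summaries with
$n{-}1$ denominators. Omnibus ANOVAs are optionally followed by
Holm-adjusted pairwise t-tests (`pairwiseTTests()`), labeled as a
convenience of this package rather than a protocol prescription.
Repeated measurements on the same animal are *not* modeled as repeated
measures; no mixed-effects machinery is implied.

# Verification strategy and problem sizes

The test suite asserts, among others: Otsu equals an exhaustive
between-class-variance maximizer on random histograms; segmentation Dice
> 0.95 and 1 px diameters on the default phantom at 30 dB; noiseless
render → unmix closure to 10⁻⁹ across the saturation grid and per-vessel
sO~2~ RMSE < 0.03 at 25 dB over 100 scene seeds; machine-precision speed
closure noiseless and < 5% median error at 20 dB over 4 speeds × 50 seeds;
end-to-end CBF/OEF/CMRO~2~ recovery within 10% at 25 dB over 20 seeds;
exact noiseless bioenergetics closures with 2–3% tolerances under ~1%
trace noise; ANOVA sum-of-squares conservation, the $t^2 = F$ identity and
null type-I error within [0.035, 0.065] over 2000 replicates. These sizes
were chosen so the whole suite runs in about a minute on a single core
while leaving the Monte-Carlo margins comfortable.

At 25 dB the end-to-end CMRO~2~ error is dominated by a small systematic
effect, not by seed scatter: clipping saturations into [0, 1] biases
high-saturation (arterial) estimates slightly downward under noise, which
propagates through OEF into CMRO~2~ at the few-percent level. This is a
property of the specified per-pixel estimator itself and is documented
rather than compensated.

# Known limitations

* The phantom's noise model is additive Gaussian only; no speckle or
  motion. Real-data robustness must be established separately.
* $C_{Hb}$ is relative unless the user supplies an absolute calibration
  constant; consequently absolute CMRO~2~ values depend on that input, and
  the package verifies the formula chain, not any particular animal's
  absolute numbers.
* The decorrelation family and $k_{\mathrm{flow}}$ stand in for an
  instrument calibration that cannot be derived from first principles
  here; treat fitted speeds on real data as calibrated only as well as
  $k_{\mathrm{flow}}$ is.
* ROIs are user-provided (vessel-of-interest workflow); there is no
  automatic whole-field vessel discovery.
* No depth-resolved reconstruction; the pipeline operates on projected
  2-D maps.

# Session

```{r}
sessionInfo()
```
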
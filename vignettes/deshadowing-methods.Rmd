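---
title: "De-shadowing OCTA volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-shadowing OCTA volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octads)
```

## The problem

OCT angiography (OCTA) derives blood-flow contrast from the temporal
decorrelation of OCT signals caused by moving red blood cells. Light
crossing a large perfused vessel picks up a time-varying wavefront
distortion, so static tissue *beneath* the vessel also decorrelates
between repeated B-scans. The result is a "tail": a vertical streak of
spurious flow signal trailing below every large superficial vessel,
which shadows the true capillaries of the deeper cortex and corrupts
depth-resolved (en face) analyses of the vascular network.

`octads` removes these tails per depth profile (A-line). Throughout,
volumes are `OctaVolume` objects: non-negative linear amplitudes in
(z, x, y) order with voxel pitch in micrometres. Processing always
happens on the linear amplitude scale; logarithmic mapping
(`logScale()`) is display-only.

## The two operators

**Mean subtraction** (the method of interest). For the A-line
$A(k), k = 1 \dots N$:

$$A_{DS}(k) = A(k) - w \cdot \frac{1}{N}\sum_{j=1}^{N} A(j)$$

The subtracted offset is proportional to the *total* intensity of the
A-line, so columns carrying long bright tails are corrected more
aggressively than clean columns — the operator is adaptive per column
with a single global weight $w$. The mean deliberately runs over all
$N$ depth pixels (not a tissue mask): the offset is meant to scale with
everything the beam encountered. Negative results are clipped to zero
by default (`clipNegative`), since OCTA magnitudes are non-negative;
the signed residual is available for quantitative work
(`clipNegative = FALSE`), which is also why the `OctaVolume` class
itself only demands finite values.

**Step-down exponential filtering** (the classical baseline). Top to
bottom within each A-line:

$$A_{DS}(z) = A(z) \cdot \exp\!\Big(-\frac{1}{\gamma}
  \sum_{k<z} A_{DS}(k)\Big)$$

Each pixel is attenuated by the accumulated de-shadowed signal above
it; $\gamma$ (units of cumulative amplitude, hence scale-dependent)
controls the rate. The recursion is inherently sequential in z; the
implementation vectorises across the (x, y) columns and the test suite
checks it against a literal scalar recursion to below 1e-12 relative
error. The step-down output can never exceed its input — which is
precisely its weakness: everything below a bright vessel is attenuated,
true capillaries included. Mean subtraction instead subtracts a
constant per column, so a capillary peak standing above the tail
plateau survives with its height largely intact.

Neither operator is idempotent, and none is meant to be: they are
one-shot corrections, not projections.

### Parameters that matter

* `w` (dimensionless, default **2.0**): weight on the A-line mean.
  Too small leaves tail residue; too large erodes genuine deep signal
  (worst beneath vessels wider than ~100 µm, where the A-line mean is
  largest). The default is the value at which capillary SNR peaks.
* `gamma` (cumulative amplitude): no universal default is meaningful
  because it depends on the amplitude scale; use `matchGamma()`.
* `surfaceIndex` (voxels, default 0): pixels above the tissue surface
  pass through untouched and are excluded from the step-down
  accumulation; the mean-subtraction offset still uses all N pixels.
* `floorDb` (dB, default −40): display floor of `logScale()`.

### Matching the two methods

A fair comparison requires "equal tail attenuation". `matchGamma()`
operationalises this as: find $\gamma$ such that the mean residual
amplitude inside a tail region-of-interest equals that left by mean
subtraction at the chosen $w$. The step-down residual is continuous and
strictly increasing in $\gamma$, so the match reduces to bracketed root
finding on $\log_{10}\gamma$ (`uniroot`, tolerance 1e-7); if the target
is unreachable inside the bracket the nearer boundary is returned with
a warning (e.g. $w = 0$, whose residual no amount of step-down can
reach from below, or large $w$ where clipping drives the
mean-subtraction residual to exactly zero).

### Optional histogram equalization

`equalizeVolume()` is a volume-global equalization: intensities are
binned (`nBins`, default 256) and mapped through the empirical CDF onto
(0, 1]. It preserves the rank order of intensity levels and is off by
default; it exists to make poorly illuminated deep capillaries visible
in renderings, not to precede quantitative metrics.

## En face generation and metrics

`extractSlab()` converts micrometre depth ranges to half-open voxel
index intervals, `idx = surfaceIndex + floor(um / dz)`. Half-open
intervals plus `floor` make tiled slabs partition the depth axis with
no slice counted twice (an impulse at a shared boundary lands only in
the deeper slab). `maxAmplitudeProjection()` takes the per-(x, y)
maximum over the slab.

The evaluation metrics mirror the standard OCTA quality measures:

* `rmsContrast()`: the population standard deviation of a line
  intensity profile (no mean normalization); `meanRmsContrast()`
  averages it over all lines of an angiogram. Population rather than
  sample SD keeps tiny worked examples exact; at 100+ pixel lines the
  difference is immaterial.
* `profileSnr()`: (peak max − background mean) / background SD over
  user-chosen windows. A constant background returns `+Inf` with a
  warning rather than an error, so parameter sweeps can report the
  sentinel.
* `slabSimilarity()`: zero-lag Pearson correlation of two angiograms;
  `similarityVsDepth()` walks 20-µm slabs stepped by 5 µm (about one
  axial resolution element) and correlates adjacent pairs.

## The synthetic phantom

No public volumetric OCTA datasets with tail-artifact ground truth
exist, so the package ships a generator. `defaultCortexSpec(seed)`
emulates a mouse-cortex acquisition through a cranial window:

* **Geometry**: 256 × 128 × 128 (z-x-y) voxels at 4 µm axial / 16 µm
  lateral pitch — a ~1 mm deep, 2 × 2 mm field, i.e. the common
  200-A-line-per-millimetre sampling, kept at desk scale.
* **Pial vessels**: 2–4 balls of radius 40–100 µm centred above 100 µm
  depth, unit amplitude. Balls rather than flat discs so the tail
  start depth varies across the footprint the way it does under a
  cylindrical vessel.
* **Tails**: below the deepest vessel voxel of each column,
  `vesselValue × strength × exp(−Δz / 300 µm)` down to the bottom;
  strength 0.5. The exponential-decay tail is the model the step-down
  filter implicitly assumes, which makes the baseline's best case part
  of the test conditions.
* **Attenuation**: all true structures are multiplied by
  `exp(−z / 700 µm)`, approximating single-scattering signal loss at
  1300 nm in cortex while keeping 700 µm capillaries measurable, as
  they are in open-skull acquisitions.
* **Capillaries**: ~2000 spheres of radius 6–10 µm at 300–700 µm depth
  (≈1250 per mm³ — sparse compared with a real capillary bed but dense
  enough that every deep en face line crosses several cross-sections),
  placed outside the pial footprints, plus four placed deliberately
  beneath the largest vessel at 350–450 µm: the shadowed-capillary
  scenario the method exists for. Capillaries carry the same unit
  amplitude as vessels because OCTA decorrelation contrast saturates
  for perfused vessels of any calibre; their *measured* signal is
  nevertheless weaker through the attenuation term. Sub-voxel radii
  are rendered into at least their containing voxel (partial-volume
  rendering).
* **Noise**: Rayleigh-distributed floor (scale 0.02), the standard
  amplitude-speckle model; a folded Gaussian is available. Noise is
  added after the ground-truth masks are recorded.

Placements draw from substreams derived from the seed (vessels,
capillaries and noise separately), so e.g. adding capillaries does not
move vessels. What the phantom does **not** model: B-frame ensembles
and decorrelation statistics, wavefront physics of the tail mechanism,
curved tissue surfaces, vessel tubes with realistic topology, motion
artifacts. Passing tests on phantoms therefore demonstrate the
*mechanics* of the algorithms — suppression of an exponential tail
under speckle while preserving sub-threshold peaks — not clinical
performance on in vivo data, whose absolute contrast values are not
reproducible here.

## Choices where the design was open

* **Tail seeding**: a tail is seeded once per column from the deepest
  vessel voxel, not accumulated from every vessel voxel in the chord —
  the latter would make tails brighter than their vessels.
* **Weight sweeps score the unclipped residual**
  (`capillarySnrSweep()`): with clipping, weights ≳2.5 zero the entire
  background window, the SD collapses and the SNR saturates at the
  `+Inf` sentinel — a censoring artifact of the display convention,
  not a property of the de-shadowing. The background windows flank the
  capillary inside and at the edge of the vessel shadow, where the
  sweep exhibits its characteristic interior optimum: the subtracted
  offset `w·mean` cancels the tail texture best at an intermediate
  `w`, and overshoots beyond it.
* **Normalization**: "normalize without contrast adjustment" is a
  single division by the global maximum, never per-slice. This matters
  for the contrast comparison: mean subtraction lowers the global
  maximum (vessels lose their offset too), so renormalisation
  stretches the surviving capillary signal — the mechanism behind its
  higher deep-slab RMS contrast, with the tail-texture removal pulling
  mildly the other way.
* **Degenerate inputs** are warnings, not errors, wherever a run can
  meaningfully continue: all-zero volumes skip normalization, constant
  images write as zeros, constant backgrounds return the SNR sentinel.
  Validation failures (empty slabs, mismatched shapes, negative stored
  voxels) stop with the offending index or conversion spelled out.

## Problem sizes

The shipped test-suite and the acceptance script run the full
256 × 128 × 128 default phantom (single-seed analyses plus five-seed
replications of the contrast-ordering and weight-sweep experiments);
the unit tests use a 64 × 24 × 24 single-vessel phantom and handmade
A-lines. A full phantom generates in ~2 s and one `matchGamma()` call
costs a few seconds (some tens of full-volume step-down evaluations).

## Known limitations

* Mean subtraction can erase capillaries whose signal lies below
  `w × mean` of their column — most likely beneath very wide vessels
  or at depth. The phantom's designated shadowed capillaries sit at
  350–450 µm for this reason; deeper ones under the largest vessels
  are genuinely at risk, as the per-capillary visibility report
  (`capillaryVisibility()`) makes explicit.
* `gamma` is scale-dependent; matched values are only meaningful for
  the volume they were matched on.
* The angiogram writer rescales to the 16-bit range per image, so
  absolute amplitudes are not comparable across written angiograms;
  use the volume writer (lossless raw, or TIFF with recorded
  `data_max`) for quantitative archival.
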
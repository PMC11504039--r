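---
title: "Methods behind valvebench: hydrodynamic, mechanical and hemodynamic valve analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind valvebench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvebench)
```

valvebench implements the desk-scale computations used to characterise
bench-tested and simulated aortic valves in early-calcification studies:
pulse-duplicator hydrodynamics, Hertzian nanoindentation fitting, leaflet
wall-shear analytics, planimetric orifice-area measurement, and the
comparison statistics that tie bench and simulation results together. A
seeded synthetic-data module generates every input modality with known
ground truth, so the whole pipeline is testable without instrument data.
This vignette explains the models, the defaults, and the numerical and
design choices.

## Hydrodynamic functionality metrics

A pulse duplicator records ventricular pressure, aortic pressure and
transaortic flow; recordings are ensemble-averaged (10 cycles by
convention) and reduced to four metrics on the averaged cycle:

* **RF** (regurgitant fraction, %): retrograde (closing + leakage) volume
  over forward volume, volumes by trapezoidal integration of the flow
  split by sign.
* **ΔP** (mmHg): time-mean of the ventricular-minus-aortic differential
  over the forward-flow window. The averaging window for ΔP is a
  convention choice; the peak differential is available via
  `method = "peak"`.
* **Q~RMS~** (mL/s): root-mean-square flow over the forward-flow window.
* **EOA** (cm²): the ISO 5840 / Gorlin-type closure
  `EOA = Q_RMS / (51.6 * sqrt(ΔP / ρ))` with ρ in g/cm³. This specific
  constant is the pulse-duplicator convention: applied to published bench
  values it reproduces the tabulated EOA of the raw (0.98 cm²) and
  flow-conditioned (1.04 cm²) valve groups exactly at two decimals (the
  statically conditioned group closes to 0.85 against a printed 0.84, a
  rounding artefact of that table).

The forward-flow window is the maximal contiguous run of samples with
flow above 2% of the peak absolute flow, with dropouts of up to two
samples bridged. The threshold makes window detection robust to noise at
the crossings; it also means the detected window is very slightly
narrower than the true positive support (about 1.3% for a half-sine
pulse), which is immaterial for the mean-based metrics.

Working-fluid defaults are 0.90% w/v saline at 20 °C: density
1007 kg/m³, dynamic viscosity 1.07 cP. `compute_reynolds()` implements
the bare definition `Re = ρvD/μ`; the choice of characteristic velocity
is left to the caller because conventions (peak systolic jet vs. mean
annulus velocity) differ enough to change the answer several-fold.

## Synthetic pulse-duplicator waveforms

The generator emulates a bench run at a mean arterial pressure of
100 mmHg, 70 beats/min and a 35% systolic flow waveform. Since waveform
equations are never standardised across duplicators, the shapes are
deliberately simple closed forms with exact volume/pressure bookkeeping:

* Flow: a half-sine systolic pulse whose area equals the stroke volume;
  a brief negative closing spike (default 5% of the cycle) carrying a
  configured fraction of the stroke volume; constant diastolic leakage.
* Pressures: a half-sine aortic pulse with a linear diastolic sag whose
  discrete cycle mean is pinned exactly to the target MAP; the
  ventricular trace sits on the aortic one plus a half-sine differential
  during systole and at a low filling pressure (10 mmHg) in diastole.

Defaults (`stroke_volume = 35` mL, `delta_p_peak = 10` mmHg,
`closing_volume_fraction = 0.08`, `leakage_rate = 1` mL/s) were chosen
once so that the derived metrics land in the range bench-tested
bioprosthetic valves of this size produce: Q~RMS~ ≈ 130 mL/s, ΔP ≈
6.4 mmHg, RF ≈ 9.5%. The time grid uses
`dt = T / round(sampling_rate * T)` so each cycle spans a whole number of
samples; this makes ensemble averaging exact for noiseless cycles, and
the generator's ground truths (`attr(w, "truth")`) are exact closed
forms. Noise is additive Gaussian per channel with a mandatory seed;
real transducer noise is neither white nor Gaussian, so noise-robustness
results here show qualitative, not quantitative, behaviour.

## Hertzian nanoindentation

Load-displacement records from a flat-tip indentation protocol (40 μm
loading at 2 μm/s, mirrored unloading, 5 s retraction at 5 μm/s) are fit
on the loading segment with the Hertz contact law

$$P = \frac{4 E \sqrt{R}\,\delta^{3/2}}{3(1-\nu^2)}$$

with `R = 500` μm and `ν = 0.30` by default. `R` is treated as an opaque
configured probe dimension and the law is evaluated literally — for a
flat 500 μm punch the classical sphere-radius reading does not apply,
but the expression above is the form used with this instrument class and
it is the form the estimator inverts, so the recovered modulus is
internally consistent. Units are kPa/μm/μN throughout; the conversion
collapses to `P[μN] = 4E√R δ^{3/2} / (3(1-ν²)) × 10⁻³`.

Because the model is linear in `E` given the contact point, the fit is
an exact least-squares regression of load on `(δ-δ₀)₊^{3/2}` through the
origin. Contact-point detection (off by default; records are assumed to
start at contact, as instrument protocols trigger on contact) is a grid
search over δ₀ with the linear fit nested inside, refined by
golden-section optimisation — robust because the profile of the residual
sum over δ₀ is smooth and unimodal for Hertz-like data. Segment labels
come from backward-difference displacement rates, with the
unloading/retraction boundary placed at the midpoint of the two negative
rate levels when their ratio exceeds 1.5. Fitting the unloading segment
is rejected by contract: unloading of soft hydrated tissue is
viscoelastic and an Oliver–Pharr-style analysis is out of scope.

## Wall-shear analytics

On a triangulated leaflet surface carrying per-node WSS vector time
series over one cycle (dynes/cm² internally; 1 Pa = 10 dynes/cm² at I/O
boundaries):

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T \lVert\vec\tau_w\rVert\,dt,
\qquad
\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{\lVert\int_0^T \vec\tau_w\,dt\rVert}{T\cdot\mathrm{TAWSS}}\right)$$

The OSI numerator is the magnitude of the time-integrated WSS *vector*
(the standard oscillatory-shear form); with that reading
`0 ≤ OSI ≤ 0.5` holds analytically by the triangle inequality — no
clamping anywhere — and the tests verify it on thousands of random
fields. Nodes with zero TAWSS are assigned OSI 0 by default (no shear,
no oscillatory character); the value is configurable since some
post-processors report 0.5 there. Time quadrature is trapezoidal with
the last sample identified with the first (periodic); on smooth signals
the error is O(h²), verified by step-halving. Surface means weight each
node by one third of its incident triangle area (lumped quadrature),
which integrates piecewise-linear fields exactly and is therefore
invariant under mesh refinement.

`compute_q_criterion()` evaluates `Q = ½(‖Ω‖²_F − ‖S‖²_F)` from
central-difference velocity gradients on a uniform grid (one-sided at
boundaries, flagged by the `interior` mask). The canonical generator
fields give `Q = ω²` (solid rotation), `0` (simple shear) and `−α²`
(pure strain) exactly on interior cells because those fields are linear
in the coordinates.

The synthetic leaflet is a triangulated unit disk whose radial
coordinate stands in for belly-to-free-edge position, with a linear
amplitude ramp — real leaflets show exactly this qualitative pattern
(low shear in the belly, high at the free edge) but not a literal linear
law, so quantitative spatial statistics on the synthetic surface do not
transfer to real leaflets. The temporal basis is a sample-exact square
wave of forward duty `f`: with the package's periodic trapezoidal rule,
TAWSS equals the local amplitude and OSI equals `½(1−|2f−1|)` *exactly*
at finite sampling (the realised duty is quantised to
`round(f·n)/n`). Sharp edges were chosen over smoothed ones precisely
to make these truths exact rather than asymptotic. The
`bioreactor_preset()` reproduces an oscillatory conditioning
environment: duty 0.5 (OSI 0.5) at 3.5 dynes/cm², the midpoint of the
3–4 dynes/cm² band such bioreactors apply. Group-level leaflet fields
from full fluid-structure simulations are not desk-reproducible; their
published magnitudes serve only to keep the synthetic presets in a
realistic range.

## Orifice-area planimetry

The geometric orifice area (GOA) pipeline mirrors the usual bench
measurement: pick the frame at peak flow (nearest-in-time to the flow
maximum, earlier frame on ties), enhance it (CLAHE then Gaussian blur),
segment the orifice, and count mask pixels:
`area = count × (mm/px)² / 100` cm² — exactly, so the area obeys exact
rigid-motion invariants; the contour is derived output. Segmentation
thresholds the enhanced frame at the Otsu level computed from the
region-of-interest statistics, keeps the connected component at the ROI
centre, fills holes, and refines the boundary with an edge-based active
contour: a star-shaped radial snake whose nodes move toward the
strongest local gradient along their ray, with periodic moving-average
curvature smoothing, iterated to convergence (max radius change below
0.05 px) or an iteration cap of 50. A star-shaped contour is the right
geometry class for an open valve orifice viewed down the axis. The
CLAHE tile grid (8×8), clip limit (2), blur σ (2 px), snake search
window (±4 px) and smoothing width (5 nodes) are configuration defaults
tuned once on the synthetic fixtures.

Pixel calibration uses the valve holder: its rim has a known physical
diameter (26 mm), so `mm_per_px = 26 / rim_diameter_px`. The rim is
found as the outermost bright ring of the radial intensity profile about
the frame centre; this assumes the holder is approximately concentric
with the frame, which bench recordings (and the generator) satisfy. A
general off-centre circle fit is a known limitation.

The synthetic frame embeds a cosine-lobed star orifice
`r(θ) = r₀(1 + a·cos(kθ))` (k = 3 for a tri-leaflet valve; a disk for
k = 1) of configured physical area, a mid-gray leaflet field and the
bright rim, then blurs, adds seeded Gaussian noise and quantises to
8-bit. The truth mask is stored alongside, and its pixel-count area is
within 2% of the target by construction. Defaults target 3.24 cm², a
typical fully open orifice at this holder size. What the generator does
not emulate: specular reflections, bubbles, non-uniform illumination and
motion blur — segmentation accuracy on real footage will be lower than
the ≥95%-within-5% rate the tests demonstrate on synthetic frames.

## Comparison statistics

Groups are screened for normality with the moments-based
skewness-kurtosis omnibus test (the D'Agostino–Pearson K² statistic,
χ²₂ under the null), implemented from the standard Z-transforms because
no installed dependency provides it, and verified against an independent
implementation. The omnibus transforms are unreliable below n ≈ 8, so
smaller samples get a warning and no p-value. Group comparisons use the
unpaired pooled-variance Student's t-test (Welch by flag), with p-values
mapped to the conventional star tiers at 0.05/0.01/0.001/0.0001. No
multiple-testing correction is applied by default, matching
per-comparison reporting practice in bench studies; this inflates
family-wise error when many metrics are compared, which callers should
weigh. Bench-versus-simulation tables use the symmetric percent
difference `100·|v₁−v₂| / ((v₁+v₂)/2)`, which is symmetric,
scale-invariant and undefined when the values cancel; the absolute value
and the ×100 are required to reproduce published comparison columns,
whose quoted formula omits both.

## Problem sizes and verification scope

The test suite runs the full pipeline at deliberately modest sizes —
1 kHz waveforms of ≤10 cycles, ~150-node leaflet meshes with 64 time
steps, 256² frames, 100-seed planimetry and Hertz noise sweeps, and a
10,000-replicate null calibration of the t-test at n = 3 — sizes at
which every closed-form truth above is resolvable at its stated
tolerance. Passing tests certify the computational pipeline against the
generators' ground truths; they do not certify instrument-specific
effects (transducer drift, optical distortion, non-Gaussian noise) that
the generators do not model.
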
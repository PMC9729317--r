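---
title: "PupilKit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PupilKit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PupilKit)
```

PupilKit models a complete pupillometry rig — a ten-primary light
engine viewed through an integrating sphere, a spectrometer, a
head-mounted eye tracker with a forward-facing scene camera — and the
analysis that sits on top of it. This vignette explains the models, the
parameters that matter, and the choices made where the design was
genuinely open. Everything empirical stated here is computed by the
package's test suite or acceptance script, not asserted from memory.

## Spectra and weighted integrals

A `Spectrum` is power on a strictly increasing wavelength grid
(default 380–780 nm at 1 nm) with a units tag: spectral irradiance
(W·m⁻²·nm⁻¹), spectral radiance (adds sr⁻¹), or raw sensor counts.
All photometric reductions are rectangle-rule sums

\[ \sum_\lambda E(\lambda)\, w(\lambda)\, \Delta\lambda , \]

with Δλ the grid step and the weighting function interpolated onto the
spectrum's grid, restricted to the overlap of supports. One convention
to be aware of: the sum runs over *samples*, so a unit spectrum times a
unit weight over 400–500 nm at 1 nm gives 101, not 100. Disjoint
supports return zero with a warning rather than an error.

The weighting tables are analytic constructions of the standard
functions rather than file copies of published tabulations:

* the five α-opic action spectra use the Govardovskii A1
  visual-pigment template (α- and β-band) placed at the nominal peak
  wavelengths 448, 542, 568, 507 and 490 nm and normalised to unit
  peak;
* V(λ) and the CIE 1931 2° colour matching functions use the published
  piecewise-Gaussian analytic fits (V(555) ≈ 0.998, so 1 W·m⁻² of
  555 nm light evaluates to ≈ 682 lx against the definitional 683);
* B(λ), the blue-light-hazard function, uses its standard piecewise
  definition: the 5 nm table from 300–500 nm, 10^((450−λ)/50) from
  500–600 nm, 0.001 above.

Tests that must not depend on table provenance (linearity,
monotonicity, integration conventions) use synthetic narrowband
weights (`narrowbandWeighting`). Tests of the standard functions check
properties these constructions share with the published tables: the
melanopic peak between 480 and 500 nm, the ≈683 lm/W point, the
equal-energy white near (1/3, 1/3), and a deep-red line driving L
cones at >1000× its melanopic weight.

Safety evaluation reports the blue-weighted radiance L_B against the
exposure limit — 10⁶/t J·m⁻²·sr⁻¹ expressed as radiance for t ≤ 10⁴ s,
100 W·m⁻²·sr⁻¹ beyond — divided by the pupil correction factor
(d/3 mm)². Limits are stored at full precision and truncated to one
decimal only in printed reports, so a factor of 6 displays as 16.6.

## The simulated engine and spectrometer

The engine model (`EngineGroundTruth`) is additive: output = dark
spectrum + Σᵢ B(sᵢ/4095; αᵢ, βᵢ)·primaryᵢ + Gaussian noise, clamped at
zero. The beta CDF is the nonlinearity model because it is flexible,
monotone, and pinned to B(0)=0, B(1)=1; (α, β) = (1, 1) is a perfectly
linear channel. Default primaries are ten Gaussians peaking 420–660 nm
with 24 nm FWHM — the layout of a real ten-channel engine — with peak
spectral irradiance around 0.02 W·m⁻²·nm⁻¹, which puts full-drive
output near 1.4 klx at the viewing plane.

The spectrometer model is counts = irradiance·gain·t_int + dark(T,
t_int) + noise, with the dark offset linear in both PCB temperature
and integration time (dark0 + k_T·T + k_I·t_int) and optional shot
(∝√signal) and read noise. The same declared coefficients drive both
the simulation and the dark/gain correction during calibration — the
model is explicit rather than an opaque device-specific pipeline.
Saturation is flagged in metadata and saturated readings are excluded
from calibration. Timed stimulus files pair a time vector (integer ms,
10 ms minimum spacing — the device's spectral switching floor, enforced
as a validation error rather than silently coalesced) with ten 12-bit
settings per time point, serialised as documented JSON with a `.dsf`
extension; this schema is a stand-in with the same information content
as the vendor's proprietary format, not a bit-compatible clone.

## Calibration

`samplingPlan()` returns multiples of 65 from 65 to 4095 — 63 evenly
spaced levels per channel; the zero level is optional because
dark-corrected output at zero drive is identically zero, and the
context anchors interpolation there (with a message) when it is
absent. Dark-corrected readings keep their symmetric measurement
noise: clamping negatives at this stage would bias low-intensity knots
upward and flatten the fitted curves (the bias is visible as a
systematic underestimate of α at the percent level under realistic
noise). Spectra are clamped at zero only when materialised as
`Spectrum` objects.

`buildContext` interpolates per-channel spectra linearly over
intensity. Derived scalars (photopic illuminance, the five α-opic
irradiances, unweighted irradiance) are interpolated from their knot
values — exactly equivalent to integrating the interpolated spectra,
because every one is a linear functional of the spectrum — and stored
densely for all 4096 levels, while spectra themselves are interpolated
on demand from the knots (a dense 10 × 4096 × 401 spectral table would
be ~130 MB for no accuracy gain). Interpolation error falls
quadratically with plan step; the suite verifies an empirical order
≥ 1.8 between steps 512 and 256.

`fitCurves` fits B(s/4095; α, β) to normalised illuminance by
unweighted least squares over (log α, log β) (the loss was an open
choice; unweighted least squares on the normalised curve is the
simplest defensible one). On a noiseless rig with planted (2, 3) the
fit recovers the parameters to ~1e-6. Under sensor read noise giving
~1% CV on mid-range readings, recovery stays within 5% per channel —
measured on a photometrically balanced test rig, because a channel
whose photopic output is intrinsically tiny (a violet primary against
V(λ)) is noise-dominated at any noise level that is "1%" for the
others. `optimiseProfile` inverts the fitted CDF and quantises;
round-trips through the forward curve land within 2/4095.

## Matching

The α-opic matrix A (5 × 10) holds each channel's α-opic vector at
maximum drive divided by 4095 — the per-unit-setting contribution
under the linearity assumption. Two solvers minimise
‖A·s − a_target‖² over the box [0, 4095]¹⁰:

* `matchLinear`: an active-set bounded least-squares solver whose free
  subproblem is solved by SVD pseudoinverse (normal equations with a
  ridge bias the residual measurably — the solver is exact to machine
  precision on in-gamut targets);
* `matchLocal`: L-BFGS-B with analytic gradient from a caller-supplied
  start, with a descent guarantee (the result is never worse than the
  start).

Settings are rounded to integers *after* optimisation and the reported
residual is recomputed after rounding from the calibrated forward
model, so `achieved` is always what the rig would actually produce.
Box bounds are kept on both solvers: "unconstrained" optimisation over
physical drive levels still cannot leave [0, 4095]. Out-of-gamut
targets return the best boundary match with a warning. On in-gamut
targets both solvers recover the target to the ~0.05% quantisation
floor and their residuals agree to machine precision; with duplicate
primaries the null space yields visibly different settings vectors
with identical α-opic output — many solutions, one photoreceptor
state. Stimulus scaling (`scaleStimulus`) works in the linearised
output domain: forward through the fitted curves, multiply, invert,
clip with a saturation warning.

## Light stamping and capture

`lightStamp` keeps two consecutive frames and stamps the first whose
whole-frame mean intensity exceeds the previous frame's by more than
the threshold. Frames are reduced to their mean at ingestion — the
algorithm uses no spatial structure — and only positive steps are
detected by default (stimulus onsets; an `absolute` flag catches
offsets). The timeout counts stream time, not wall time, so detection
is deterministic and testable. The platform-dependent constant by
which camera timestamps lead or lag true exposure is modelled as a
single configurable offset (`applyTimestampOffset`, default 0); no
clock-synchronisation machinery is emulated. The original capture
tools run detectors in background threads returning future objects;
here streams are materialised and the functions are pure, which makes
the concurrency contract trivial — two stampers give identical results
in either evaluation order, verified in the suite.

## Preprocessing

The cleaning pipeline is: mask, reconstruct, smooth.

* **Masking.** A sample is masked when its time-aware backward
  difference (Δvalue/Δt, robust to timestamp jitter) deviates from the
  mean difference by more than 3 SD, or when confidence < 0.95
  (strictly — at-threshold samples are retained). The SD is that of
  the *derivative*, computed over the whole recording (the wording
  "first derivative exceeded ±3 SD" is ambiguous between signal and
  derivative SD; derivative SD is the reading that makes the rule a
  spike detector). A one-sample spike produces two outlying
  differences and masks the spike and its right neighbour. The mask
  report satisfies by_derivative + by_confidence − by_both = total.
* **Reconstruction.** Interior gaps are filled linearly in time;
  leading/trailing gaps take the nearest valid value (linear
  interpolation is undefined there); all-masked input is an error.
* **Smoothing.** 3rd-order Butterworth, 4 Hz cutoff, applied forward
  and backward. Zero-phase filtering was chosen because phase lag
  would bias latency; the consequence, documented and tested, is that
  the effective magnitude is squared: gain 0.5 at the cutoff and
  1/(1+(f/4)⁶) elsewhere. Two numerical points: (i) the filter input
  is padded by odd reflection over several filter time constants,
  because plain forward-backward filtering leaves edge transients
  visible at the 1e-4 level even on constants; (ii) a digital filter
  designed by bilinear transform matches the analog magnitude formula
  only where frequency warping is negligible — at 120 Hz sampling the
  response at 10 Hz follows tan-warped frequencies ~11% off the analog
  form, so the suite verifies the analytic curve at 1 kHz sampling and
  the half-power point at 120 Hz (where the cutoff maps exactly).
  A Butterworth filter is not a projection: repeated passes keep
  attenuating near-cutoff content, so pipeline idempotence holds (and
  is tested) for band-limited traces, not for arbitrary ones.

Trials are extracted over [−5, +65] s around each annotated onset
(truncated with a warning on partial coverage) and converted to
%-change from the 5 s prestimulus baseline mean, which must be
positive.

## Parametrisation

On an onset-indexed trial in absolute units: baseline is the
prestimulus mean; peak constriction the post-onset minimum; latency
the time of the acceleration minimum restricted to (0, t_peak] —
the negative acceleration peak of the initial constriction, computed
by central differences on the (filtered) trace; VConAve spans latency
to peak; VConMax is the most negative velocity in that interval;
VRedAve the mean velocity from the peak to the 75%-recovery point or
the window end. T75Rec is the time after peak constriction at which
the diameter first crosses peak + 0.75·(baseline − peak); the
75% criterion is interpreted as recovery of 75% of the *constriction
amplitude* (the alternative reading, 75% of resting size, is ambiguous
for shallow constrictions) and the fraction is configurable. A trial
that never reaches the threshold gets T75Rec = NA; session summaries
average only defined values and report the undefined count per
parameter (SD is reported as 0 for n = 1). Trials with no constriction
at all are flagged degenerate with all parameters NA. Velocities are
signed: negative during constriction, positive during redilation.
Optional cubic upsampling before derivative estimation is available
(off by default) for latency resolution beyond the frame interval.

At 120 Hz the latency estimator lands within two frame intervals of
truth on noiseless traces across a 3×3×3 grid of amplitude × latency ×
recovery-τ; baseline and peak recover within 1% and T75 within 5% of
the analytic τ·ln 4. Zero-phase filtering shifts the estimated latency
a few frames late by smoothing the constriction onset — visible in the
README example (0.30 s estimated vs 0.25 s planted) and consistent
with the general observation that latency values depend on the
calculation principle.

## The synthetic generators

`generatePlr` builds: flat baseline; after the latency point, a C¹
smoothstep (3u²−2u³) down to baseline − amplitude over the
constriction duration — a smoothstep rather than a logistic so the
peak time is exact; then exponential recovery toward
baseline − sf·amplitude with time constant τ, where sf ∈ [0, 1) is the
sustained fraction modelling melanopsin-mediated sustained
constriction. For sf < 0.25 the 75%-recovery time is analytic:
τ·ln((1−sf)/(0.25−sf)), reducing to τ·ln 4 at sf = 0. Defaults echo
adult PLR scale — 5.5 mm baseline, 2.7 mm amplitude, 250 ms latency,
0.75 s to peak, τ = 1.5 s, 120 Hz, 0.05 mm noise, 0.1 Hz blinks — and
are used for realism, never as acceptance ground truth. Blinks are
Poisson-placed collapses toward zero over a few samples with
confidence dropped to 0.2; the morphology is a pragmatic stand-in and
only its maskability is asserted.

`simulateSession` emulates a sustained-response protocol: three blue
(sf = 0.10) and three red (sf = 0) one-second pulses in seeded random
order, cues every 120 s, onsets jittered 5–10 s after each cue, 120 Hz
binocular recording (the second eye gets lower confidence and more
noise so eye selection has a correct answer), and a 60 fps scene-camera
stream with luminance pulses at the onsets. Annotation timestamps are
produced by actually running `lightStamp` on that stream, and onsets
are snapped to the camera frame grid so the stamped time is the true
onset. Each trial's constriction deficit is tapered back to zero over
70–75 s post-onset — outside the 65 s extraction window — so a blue
trial's sustained plateau cannot leak into the next trial's baseline
while the within-window waveform keeps its analytic form. All
generators are pure functions of (spec, seed) and restore the caller's
RNG state.

What the generators do *not* emulate: pupil-size dependence on
accommodation and arousal, foreshortening with gaze angle, 3D-model
refitting drift between sessions, camera dropouts, and any
physiological model of photoreceptor inputs to pupil size. Passing
tests therefore demonstrate that the machinery recovers what it is
pointed at, not that real recordings are this clean.

## Problem sizes and tolerances

The test suite runs 63-level calibrations on 401-wavelength grids,
50-target matching batches, 27-cell parameter-recovery grids, 20-seed
noise studies and ten full ~12-minute sessions at 120 Hz; the whole
suite completes in well under a minute on one core. Equality
tolerances follow the quantity's conditioning: machine precision for
linear-algebra identities, 1e-9 for interpolation closed forms, the
quantisation step for 12-bit round-trips, and stated percentages for
stochastic recovery. Beta-CDF fitting optimises (log α, log β) with
BFGS from (0, 0), which keeps the parameters positive without
constraints; non-convergence is an error naming the channel.

## Known limitations

* The α-opic and hazard tables are analytic constructions; absolute
  α-opic values can differ from published-tabulation implementations
  at the percent level, while ratios, matching solutions and all
  internal consistency are unaffected.
* Matching assumes per-channel linearity when building A; on a
  strongly nonlinear rig the achieved α-opic output (always evaluated
  through the calibrated forward model) will show that assumption's
  error, as the residual reports honestly.
* The stamper detects whole-frame steps only; gradual ramps or
  localised stimuli need a different detector.
* Latency estimates inherit the filter's smoothing bias; comparisons
  across pipelines should hold the filter fixed.
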
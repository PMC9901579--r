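---
title: "Methods: phase-windowed activation mapping of complex optical-mapping records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-windowed activation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atmapr)
```

## The problem

Optical mapping images transmembrane voltage over a tissue surface with a
potentiometric dye, typically 100 x 100 pixels at 1 kHz and sub-millimetre
pitch. During fast pacing and arrhythmia the classical activation-time (AT)
workflow breaks down: a single fixed analysis window common to all pixels
cannot straddle a reentrant cycle without different pixels locking onto
different beats, producing fragmented, physiologically meaningless AT maps.
`atmapr` implements a unified AT framework built on *pixel-independent,
phase-derived upstroke windows* (pAT): every action-potential upstroke in
every pixel gets its own window, activation times are detected inside those
windows, spatio-temporally connected activations are grouped into wave
fronts, and each front is characterized (repolarization, repetitiveness,
activation origins, conduction sources) individually.

## Pre-conditioning

Raw fluorescence stacks are filtered with a 3rd-order Butterworth low-pass
(60 Hz cutoff) applied forwards-backwards, which squares the magnitude
response and cancels the phase response - activation times are not delayed
by filtering. A 3 x 3 uniform spatial average and a 3-frame running mean
follow, then per-pixel inversion (fluorescence falls on depolarization) and
min-max normalization to [0, 1].

Numerical choices worth knowing:

* The Butterworth design (bilinear transform) and the zero-phase filter
  (odd-reflection padding with steady-state initial conditions) are
  implemented in the package and validated against the analytic magnitude
  response `1/(1 + (f/fc)^(2n))`, since no signal-processing package is
  assumed.
* The spatial kernel is mask-aware and shrinks at borders, so masked-out
  background zeros never bleed into tissue pixels.
* A per-pixel signal range below numerical noise normalizes to 0 rather
  than amplifying round-off (the 0/0 case is defined as 0).
* Time convention: frame `i` (0-based) is time `i * dt_ms`; intervals are
  half-open `[t0, t1)`; all reported times are frame-resolution.

Per-pixel signal-quality metrics accompany the stack. Their computations
are not standardized in the field, so the package states its definitions
explicitly and records them with the result: SNR is the peak-to-peak of
the sub-60 Hz signal over the SD of the residual above 60 Hz; the dominant
frequency is the spectral argmax at or above 0.5 Hz; the regularity index
is the fraction of non-DC spectral power within 0.75 Hz of the dominant
peak (a common fibrillation-analysis convention). Constant pixels are
flagged undefined rather than 0.

## Phase-derived upstroke windows

Each pixel's trace is mean-subtracted and the phase is taken as the angle of
the analytic signal `x + iH(x)` in `[0, 2pi)`. The Hilbert transform itself
imparts the -90 degree rotation to each spectral component: for
`x = sin(omega t)` the analytic signal is `-i e^{i omega t}`, the phase
advances at exactly `omega`, and for an AP-shaped pulse train the rising
edge falls in the `phi > pi` half-cycle. We verified empirically (square AP
trains across duty cycles) that an *additional* -90 degree phasor rotation
would place the window after the maximal-derivative sample, so the plain
analytic angle is used.

The Hilbert phase is only meaningful for locally periodic signals, so the
trace is recursively halved - phase is computed on the whole trace, its
halves, quarters, and so on while segments stay at or above 128 ms - and a
sample belongs to a window if `phi > pi` in *any* segment level (a union;
adding a recursion level never removes a window). Each segment gets a 5%
cosine taper before the transform. Unioned windows shorter than 3 samples
are discarded (no derivative is defined there).

Two hygiene rules apply at the stack level:

* Windows are clipped to an edge guard band (default 25 ms) at both record
  boundaries. The per-pixel normalization anchors the trace minimum there
  and the zero-phase filters have a warm-up, which together produce slow
  spurious rises that pass a slope test; no complete upstroke is resolvable
  inside the guard. A window extending across the guard keeps its interior.
* A retained window must have positive least-squares slope and an in-window
  maximal derivative at or above the derivative threshold.

## The automated derivative threshold

Derivatives of optical signals are noise-sensitive, so windows must clear a
minimal maximal derivative. The automated threshold frames this as multiple
testing at a target false discovery rate (default 1%):

1. For each pixel, the noise scale of the derivative trace is its robust
   MAD (upstrokes are temporally sparse), floored at 1% of the pixel's peak
   derivative so noiseless records do not declare numerical
   micro-fluctuations significant.
2. For a cutoff `c`, the expected number of noise windows at or above `c`
   is the sum over all windows of the extreme-value tail
   `P(max of L null derivatives >= c)` under their own pixel nulls; the
   estimated FDR at `c` is that expectation over the observed count at or
   above `c`.
3. The threshold is the smallest cutoff (found by bisection) whose
   retained set has estimated FDR at most `q`.

On pure-noise stacks the expected pass fraction is below `q` (the
estimator is conservative there); on clean stacks the threshold falls
below the weakest true upstroke; when no cutoff reaches the target the
threshold sits above every observed value. We deliberately do not fit the
null to the lower half of the window-value distribution: when nearly all
windows are true upstrokes (sustained reentry) or all are noise, those two
situations are indistinguishable from the value distribution alone,
whereas the derivative-trace MAD null separates them correctly. The MAD
null has a known limit: when activity is continuous *and* the upstroke is
smeared to the time scale of repolarization (very coarse resolutions of a
fast rotor), the derivative trace is all structure and the null inflates;
resolution sweeps therefore transfer the full-resolution threshold with
its physical scaling (see below) instead of re-estimating it.

## Activation detection

Within each retained window the activation time is the time of maximal
derivative (central difference over one frame; the same estimator is used
in all oracles). Optical upstrokes integrate several cell layers, so a
biphasic morphology can mark two distinct depolarization events: if the two
largest derivative maxima both clear the threshold and the derivative
valley between them is at least 75% of the smaller maximum, two activation
times are stored; the chronologically first is the primary component, the
second populates a secondary map. Ties break to the earliest sample, and a
run of equal derivative values counts as one candidate peak at its first
sample. `V_F*`, the maximal derivative normalized by the in-window signal
amplitude, is carried on every event.

A uniform-window baseline (`uniform_window_at()`) is kept for comparison:
per pixel, the argmax derivative inside one fixed window. Its failure mode
on reentry - pixels locking onto different cycles - is exactly what the
phase windows avoid, and the package's spiral benchmark reproduces the
ordering (pAT correlates with the electrical ground truth far better than
uAT, whose total activation time is inflated by more than half).

## Wave-front grouping

Two events are connected when their pixels are identical or 8-adjacent and
their times differ by at most the conduction-block threshold theta_t,CB
(closed interval). Wave fronts are the connected components; converging
fronts are deliberately one object. Labels are contiguous integers in scan
order (fastest through x, then y, then t) of each component's first event,
so the labeling is deterministic and equals the queue-based flood
formulation; the implementation builds the edge set with interval joins and
takes graph components, which tests verify against a brute-force transitive
closure on small stacks.

theta_t,CB can be estimated from a short-coupled reference recording: all
nearest-in-time activation delays between 8-neighbor pixel pairs are binned
at 1 ms and theta is the largest delay observed at least `n_short_stimuli`
times - one occurrence per short-coupled stimulus crossing a persistent
slow pathway. Whether an S1S2S3S4 train contributes n = 3 or 4 occurrences
is genuinely ambiguous, so `n_short_stimuli` is an explicit parameter.

## Repolarization and APD

Repolarization is mapped per wave front and pixel. The amplitude method
takes the first downward crossing of `peak - level_frac * amplitude`
(default APD80) inside user APD limits (default 80-400 ms) after the
activation; the amplitude reference is the in-window peak minus the median
of the 10 ms pre-upstroke baseline. For drifting baselines (fibrillation
onset) the fallback takes the time of minimum derivative in the same
interval. A second pass refines the limits per front to the [5th - 10 ms,
95th + 10 ms] percentile band of the first-pass durations, clipped to the
user limits; refinement needs at least two resolved durations, otherwise
the user limits stand. APD = RT - AT where both are defined; sentinels (NA)
propagate.

## Repetitiveness, origins, dynamic maps, conduction sources

*Repetitiveness.* Per pixel, repetitions = the count of same-label
activations separated by at least ERPmin, minus one; a front is repetitive
when the histogram peak (mode) of the per-pixel counts is at least 1 (a
majority rule is available; mode ties break to the larger count). Without a
reference recording ERPmin defaults to 80% of the minimum basal APD.

*Origins.* Activation origins are events with no strictly earlier
same-label event within ERPmin in their 9-pixel neighborhood. Origins are
clustered together with their same-frame 8-connected continuation; if any
cluster member *is* preceded within the ERP window the whole cluster is a
false positive (a broad plateau fed from a peripheral source) and is
rejected. Surviving clusters are passive when they touch the mask periphery
(image border or masked-out pixel), breakthrough otherwise; the centroid is
the rounded member mean. The simultaneity tolerance is 0 ms (same frame) by
default: anything larger merges origins with ordinary propagation.

*Dynamic maps.* A single per-front map hides re-excitation, so complex
episodes are tiled into a stack of partial maps: fill pixels advancing in
time until a pixel would be written twice, then start the next map as a
copy of the previous one. Every event is a fresh write in exactly one map
(a conservation property the tests check), and for a spiral each map spans
about one rotation.

*Conduction sources.* On a dynamic map, leading points are the local AT
maxima (the most recently activated sites along the advancing edges). Each
leading point's conduction field is recovered by a backward flood over
defined 8-neighbors within `(t - theta, t]`, keeping only neighbors whose
conduction-vector ray (unit spatial gradient of AT from a 3x3 plane fit,
expanded to 5x5 when rank-deficient; undefined where the gradient vanishes)
passes within half a pixel of the fed pixel. Fields are then tested against
five non-exclusive criteria: breakthrough or passive (co-localization with
an origin cluster, with a 1-pixel tolerance because fields cannot enter
vector-undefined focal cores), myocardial reentry (adjacent field points
differing by more than ERPmin), tortuous propagation (upstream temporal
neighbors but no intersecting vector), and wave-front boundary (no
intersecting field neighbor next to a different label). Percentages are
normalized over all class assignments, since the classes are not exclusive.

## The synthetic world

The generator replaces ionic-model simulations at desk scale with a
two-variable excitable medium (Aliev-Panfilov-type):

    du/dt = -k u (u - a)(u - 1) - u v + D lap(u)
    dv/dt = (eps0 + mu1 v / (u + mu2)) (-v - k u (u - a - 1))

with k = 8, a = 0.1, eps0 = 0.01, mu1 = 0.14, mu2 = 0.3, D = 0.5 (grid
units), explicit Euler at dt = 0.02 model-time units with no-flux
boundaries. The ms-per-model-time-unit scale is free and is chosen per
scenario:

* The spiral scenario uses 4 ms/unit: a cross-field half-plane stimulus
  285 ms after a planar S1 lands in the recovery tail and spawns a spiral
  with a ~114 ms period that sustains for the rest of a 4 s recording -
  cycle length, APD (~125 ms at that rate) and conduction velocity
  (~0.2 m/s at 0.7 mm pitch) all in the range reported for ventricular
  tachyarrhythmia.
* The paced scenarios (planar, focal, S1S2S3S4) use the classical
  12.9 ms/unit (APD ~400 ms, CV ~0.05 m/s); the S1S2S3S4 couplings
  (450/430/420 ms after a 500 ms S1 interval) were calibrated once to sit
  just above this model's refractory period.
* Where a property needs inter-pixel delays of about one frame
  (0.5 m/s at 0.7 mm), the scale is set to 1.3 ms/unit.

Resolution sweeps follow the design of their experimental counterpart: the
*electrical* sheet is downsampled and the optical observation model is
re-applied at the coarse grid with the blur held fixed in physical units
(blurring the already-observed stack instead would double-blur and distort
the noise statistics). Detection parameters transfer with their physical
scalings: the conduction-block threshold is a per-neighbor-hop delay limit
and scales with pitch; the derivative threshold scales inversely with
pitch because spatial mixing sets the optical rise time.

The optical observation model applies a Gaussian spatial blur (default
1 px), inverts the signal, optionally adds linear baseline drift, and adds
white Gaussian noise calibrated so the *measured* SNR (peak-to-peak of the
sub-60 Hz signal over the residual SD above 60 Hz - the same definition the
QC module reports) hits the requested target. Everything is seeded and
bitwise reproducible.

What the generator does not emulate: 3-D transmural signal integration
beyond a single blur kernel, motion, dye photobleaching beyond linear
drift, heterogeneous tissue. A green end-to-end test therefore establishes
that the pipeline recovers the imposed activation structure under blur and
noise - not that it handles every pathology of real recordings.

ERPmin: the repetitiveness default (80% of minimum basal APD) mirrors the
usual estimate when no short-coupled reference exists; the pipeline's
`erp_min = "auto"` derives it from the earliest front with a resolvable
APD map, which on the spiral benchmark gives ~96 ms against a ~114 ms
reentrant period.

## Known limitations

* A single global theta_t,CB generalizes conduction limitations over the
  whole field of view; genuinely heterogeneous substrates would need a
  local threshold.
* Converging wave fronts are one object by definition; collision interfaces
  are not split.
* Activation times are frame-resolution (no sub-frame interpolation), so
  every time-comparison tolerance is quoted in frames.
* The uniform-window baseline needs a hand-picked window; the spiral
  benchmark derives it from the probe cycle's earliest upstroke start to
  its latest upstroke peak, which is the method's own prescription.
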
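---
title: "Quantifying cardiac and respiratory CSF dynamics from real-time phase-contrast MRI"
author: "csfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac and respiratory CSF dynamics from real-time phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfdyn)
```

## The measurement and its model

Cerebrospinal fluid oscillates through the cerebral aqueduct and the
cervical subarachnoid space with every heartbeat, and this oscillation is
modulated by breathing. Real-time phase-contrast (RT-PC) MRI samples a
velocity map of one slice every 78–96 ms for about 45 s, so the flow
through a lumen of area $S$ (mm²) is available as a continuous signal

$$Q(t) = \sum_{\text{pixels} \in \text{ROI}} v_i(t)\, s^2 \cdot 10 \cdot
\tfrac{60}{1000} \quad [\text{ml/min}],$$

with $v_i$ in cm/s (positive = caudocranial) and pixel spacing $s$ in mm.
`csfdyn` models this signal as a cardiac beat waveform whose three degrees
of freedom per beat — period $T_{c,i}$, peak-to-peak amplitude $A_i$ and
net offset $N_i$ — are slowly modulated at the breathing period $T_b$:

$$p_i = p_0\left(1 + m_p \sin\!\big(2\pi(\phi_i - \text{lag}_p/360)\big)\right),$$

where $\phi_i$ is the breathing phase of the beat's midpoint. The analysis
quantifies the modulation as the inspiration-minus-expiration contrast
$\Delta p$, its normalized form $\Delta p\%$, and the breathing-cycle phase
shift $\Phi_p$ at which the contrast is extremal.

## Pipeline stages and the choices behind them

### Segmentation and background correction

CSF pixels are identified by the fraction of mean-removed spectral power in
the cardiac band (default 0.8–2.0 Hz, i.e. 48–120 bpm): pulsatile CSF
concentrates its variance there while stationary tissue and noise spread it
across the spectrum. A 4-connected region is grown from a user seed over
pixels whose fraction exceeds a threshold (default 0.3 — for white noise at
a 10.4 Hz frame rate the expected fraction is ≈ 0.23, so 0.3 sits a few
standard deviations above it for a 45 s record). The zero-velocity
reference is the spatiotemporal mean of a stationary ring at 2 to
2 + `ringWidth` pixels from the mask (default width 3), excluding pixels
that are themselves pulsatile; subtracting it removes eddy-current bias.
Velocities beyond the VENC are unwrapped per pixel in time (nearest
multiple of 2·VENC per frame-to-frame jump), and the residual global
2·VENC ambiguity of each pixel — the first frame may itself be wrapped —
is resolved by minimizing the mean speed, which is appropriate because both
CSF and stationary tissue average near zero velocity. Courses whose
corrected excursion leaves the single-wrap range are flagged and left
untouched rather than silently altered. A genuine limitation: at ~10 Hz
frame rates a sharply pulsatile waveform can produce true frame-to-frame
velocity jumps comparable to 2·VENC − |v|, in which case temporal
unwrapping is ambiguous; such pixels are reported.

### Beat segmentation

Beats are delimited at flow minima (min-to-min). Detection proceeds in
passes: (1) the cardiac fundamental $f_0$ is estimated from the spectral
peak inside the expected heart-rate band, and minima of a zero-phase
low-pass copy (cutoff `min(5 Hz, 3 f0, 0.45 fs)`) are pruned to a minimum
spacing of $0.6/f_0$; (2) each provisional beat is standardized — its
*integral-mean* offset and range are removed — and the minima are
re-detected on the standardized signal. This matters because beat-to-beat
offset and amplitude variation makes the raw signal step slightly at each
trough, which drags the smoothed minimum toward the deeper neighbour and,
left uncorrected, couples the detected beat boundaries (and hence every
per-beat parameter) to the breathing modulation itself. The integral mean
(trapezoid with interpolated boundary values) is essential here: a plain
sample mean over the ~9 frames of a beat fluctuates by several percent of
the amplitude purely with the fractional sample coverage and would inject
artificial steps. (3) Finally every boundary is re-aligned by a
matched-filter fit against the record's own average beat waveform, with the
local beat period used on each side of the boundary so that beat-to-beat
period variation is not shrunk toward the median. On noiseless synthetic
records this chain localizes boundaries to ~5 ms (≈ 5% of a frame).

### Resampling and averaging

Each beat is resampled to 32 equispaced phases (the gated CINE-PC format)
by shape-preserving Fritsch–Carlson cubic interpolation of the beat's *own*
samples. The boundary troughs fall between samples, and here a subtle bias
lurks: any interpolation spanning the boundary mixes the trough depths of
neighbouring beats, which differ under amplitude modulation; because that
error regresses each beat's trough toward its neighbours, the measured
amplitude *contrast* shrinks (we measured a regression slope of 0.64 of
measured on true per-beat amplitude) even though the mean amplitude is
unbiased — and a contrast shrinkage does not cancel in $\Delta p\%$.
The trough values are therefore estimated one-sidedly, by a zero-slope
cubic fitted to the three nearest samples of the beat itself (samples
within a quarter frame of a boundary are excluded, since a slightly
misplaced boundary can hand them to the wrong beat). Estimator errors are
then multiplicative in the beat's own parameters and cancel between the
numerator and denominator of $\Delta p\%$. The cost is that the
extrapolated troughs may extend below the sampled range (clamped to one
local sample step), so strict "never outside the data range" holds only
above; the reconstructed 32-point curve reproduces a sinusoidal beat to
~0.5% of the amplitude at 8.7 samples per beat, and the asymmetric
two-harmonic template to ~1.7%.

The reconstructed Qt is the unweighted pointwise mean of the 32-point
beats, with $T_c$ the mean beat duration. Parameters follow their
definitions: $Q_{net}$ = mean, Amplitude = max − min, $SV^{\pm}$ the
positive/negative flow-time integrals over the beat (periodic trapezoid on
the 32-point grid, $dt = T_c/32$), $SV = (SV^+ + SV^-)/2$ in mm³, and
$V_{max/min}$ the peak mean velocities for a given lumen area.

### The breathing-effect sweep

Inspiration is the ascending belt segment (trough → peak), expiration the
descending one; only complete trough-to-trough breathing cycles are kept,
and records whose breathing period varies by more than 50% are rejected as
irregular. A beat belongs to inspiration at shift $\Phi$ when its midpoint
falls inside the inspiratory window translated by $\Phi$ (half-open
intervals; this window-shift convention makes a belt delayed by $\delta$
shift the recovered $\Phi_p$ by $-\delta$). $\Delta p(\Phi)$ is evaluated
on the inclusive grid −3 s … +3 s in 0.1 s steps (61 points); isolated
missing points are linearly interpolated and more than 20% missing aborts.

Two smoothing steps stabilize the statistic under noise without touching
noiseless results. First, the per-shift inspiratory/expiratory averaged
curves are truncated to their first 6 cardiac harmonics before parameters
are read off — a physiological beat waveform is captured by a few
harmonics, while the pointwise max/min of a noisy curve is biased upward.
Second, the extremes of $\Delta p(\Phi)$ are read off a least-squares fit
of the fundamental and second harmonic of the breathing period, since the
curve of a breathing-modulated record oscillates at the breathing
frequency. Both fits reproduce harmonic inputs exactly. The intensity is
half the peak-to-peak excursion of the (fitted) curve, signed by the curve
value at the selected extreme — the extreme whose wrapped phase percentage
$\Phi_p\% \in (-50, 50]$ is smallest in magnitude (ties toward the
maximum). $\Delta p\%$ divides by the record-mean parameter computed once
from all beats at zero shift, except $\Delta Q_{net}\%$, which divides by
the mean Amplitude because net flow itself approaches zero.
$\Phi_p° = 3.6 \cdot \Phi_p\%$.

The signed intensity is what makes the null well behaved: under pure noise
the selected extreme is positive or negative with equal probability, so the
20-seed mean of $\Delta p\%$ is centred on zero, while the magnitude alone
would not be.

## The synthetic generator as the test bed

`generateFlowRecord()` lays beats end to end, drawing each beat's
$(T_{c,i}, A_i, N_i)$ from the breathing phase of its midpoint. Modulation
depths are specified directly as the $\Delta p\%$ the pipeline should
measure; since the half-cycle mean of a unit sinusoid is $4/\pi \cdot
\tfrac{1}{2}$ per half, the generator sets $m = \text{depth} \cdot \pi/400$
so that the expected measured half-cycle contrast equals the requested
depth. The net-flow modulation is additive with its amplitude referenced to
$A_0$, mirroring the Amplitude normalization of $\Delta Q_{net}\%$. The
belt is a raised cosine whose ascending half is inspiration. Defaults are a
cervical-like record: 45 s at 96 ms/frame, $T_0 = 0.832$ s,
$A_0 = 338$ ml/min, $N_0 = 9.4$ ml/min, $T_b = 3.4$ s.

Two waveforms are provided: `"sinusoid"` (closed-form oracle; all
reference values in the tests derive from it analytically) and
`"csf_like"`, a two-harmonic template
$\sin 2\pi\phi + 0.35 \sin(4\pi\phi + \pi/3)$, shifted to put its minimum
at phase 0 and scaled to zero mean and unit peak-to-peak, mimicking the
asymmetric systolic trough of real CSF flow curves. Noise is additive
white Gaussian on the flow samples, fully determined by the seed.

What the generator does *not* emulate: partial-volume effects at the lumen
edge (rendering uses a plug-flow profile, so the known segment-area
overestimation of low-resolution RT-PC is out of reach of these tests),
ultra-low-frequency (< 0.1 Hz) modulation of net flow, 1/f physiological
noise, within-beat modulation (parameters jump per beat rather than
chirping), and thoracic-vs-abdominal breathing differences. Passing the
synthetic suite therefore validates the estimators' correctness and noise
behaviour, not the fidelity of any real acquisition.

## Problem sizes and numerical choices

The validation studies use the generator's default study size — 45 s
records (≈ 54 beats, ≈ 13 breathing cycles) — with 20 seeds for the
stochastic recovery and null studies, and a 24×24-pixel, 37-pixel-lumen
(148 mm²) rendering at VENC 5 cm/s, 0.3 cm/s background offset and
0.1 cm/s pixel noise for the image chain (velocity noise of that order
corresponds to a magnitude SNR of ~20 at VENC 5). Recovered means over 20
seeds sit within a few percent of the injected depths and within ~2° of
the injected lags; the image chain recovers $Q(t)$ with ≈ 1.4% relative
RMS error.

Degenerate inputs are explicit errors: constant signals ("no cardiac
structure"), fewer than 2 complete breathing cycles, irregular breathing,
empty stationary rings, seeds on non-pulsatile tissue, beats with fewer
than 4 samples. Beats outside 0.6–1.4 times the median duration are
discarded and counted (`nDiscarded`), guarding against missed or spurious
minima. Ties in the extreme selection go to the positive extreme; a flat
$\Delta p(\Phi)$ curve reports zero intensity and phase with a `flat` flag.

## Known limitations

* At ~10 frames per beat the 32-point resampling of sharply asymmetric
  waveforms is accurate to ~1.5–2% of the amplitude, not better; gated
  acquisitions do not have this limit.
* The $\Delta p(\Phi)$ curve repeats with the breathing period only up to
  finite-record composition changes: shifting by a full $T_b$ exchanges
  the edge beats of every averaged set, which moves individual curve
  values by up to ~10–15% of the intensity on a 45 s record.
* Temporal de-aliasing assumes at most a single wrap and cannot resolve
  wraps whose jump signature overlaps the waveform's own frame-to-frame
  jumps (flagged, not corrected).
* The breathing-effect estimate assumes a quasi-stationary breathing
  period; strongly irregular breathing is rejected rather than modelled.
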
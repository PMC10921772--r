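# csfdyn

Quantification of cerebrospinal fluid (CSF) dynamics from real-time
phase-contrast (RT-PC) MRI, including the effect of free breathing on the
beat-to-beat flow curve.

## The problem

Conventional gated phase-contrast MRI (CINE-PC) averages many heartbeats
into a single 32-point flow curve Qt over the cardiac cycle, discarding all
beat-to-beat and respiratory variation. RT-PC instead acquires one velocity
map every 78–96 ms for ~45 s, giving a continuous flow signal Q(t) (ml/min,
positive = caudocranial) in which both the cardiac oscillation and its
respiratory modulation are visible. `csfdyn` implements the post-processing
that turns RT-PC velocity maps into physiological parameters:

1. **Image stage** — pixel-wise segmentation of the CSF lumen by the
   fraction of spectral energy in the cardiac band (0.8–2 Hz), stationary
   tissue selection in a ring around the lumen, background (eddy current)
   correction by re-zeroing on the stationary mean, temporal de-aliasing of
   velocities beyond the VENC, and flow integration
   `Q = Σ v · s² · 10 · 60/1000` (v in cm/s, pixel size s in mm).
2. **Cycle stage** — beat segmentation at flow minima (matched-filter
   sub-sample refinement), resampling of every beat to 32 phase points
   (shape-preserving cubic with one-sided boundary-trough fits), averaging
   into a reconstructed Qt, and the seven descriptors: net flow Qnet,
   Amplitude (max − min), cardiac period Tc, stroke volume
   SV = (SV⁺ + SV⁻)/2 (mm³), and peak mean velocities Vmax/Vmin (cm/s).
3. **Breathing stage** — inspiration/expiration delineation from a chest
   belt (ascending belt = inspiration), assignment of each beat to a
   breathing phase by its midpoint, reconstruction of Qt-Inspiration and
   Qt-Expiration, and a sweep of the breathing-window shift Φ from −3 s to
   +3 s in 0.1 s steps. For each parameter p the curve Δp(Φ) =
   p(IN) − p(EX) yields the intensity Δp (half the peak-to-peak excursion,
   signed by the selected extreme), the normalized Δp% (divided by the
   record mean of p; ΔQnet by the mean Amplitude), and the phase Φp
   (seconds, % of the breathing cycle in (−50, 50], and degrees
   Φp° = 3.6 · Φp%).
4. **Agreement stage** — heart-rate mismatch exclusion (>10% BPM
   difference), percentage Bland-Altman bias and limits of agreement, and
   normality-gated Pearson/Spearman correlation, for comparing two methods.
5. **Synthetic stage** — a generator of CSF-like records with known
   injected modulation depths and phase lags (and optional velocity-map
   rendering with noise, background offset and aliasing), so that every
   stage can be validated against ground truth.

## Worked example

```r
library(csfdyn)

# a 45 s cervical-like record: cardiac period 0.832 s, amplitude 338 ml/min,
# breathing period 3.4 s, with 6.8% amplitude modulation lagging -11 deg
cfg <- simulationConfig(depths = c(Amplitude = 6.8), lags = c(Amplitude = -11),
                        noiseSd = 16.9, seed = 7L)
rec <- generateFlowRecord(cfg)

cycles <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
phases <- delineatePhases(rec$belt)
sweep <- sweepPhase(cycles, phases, area = 148)
sweepSummary(sweep)
```

```
          parameter        delta deltaPercent phiS phiPercent    phiDeg  flat
Qnet           Qnet -1.995695856   -0.5925603 -0.5 -14.716530 -52.97951 FALSE
Amplitude Amplitude 28.880440100    8.5751560 -0.3  -8.829918 -31.78771 FALSE
SV               SV 61.305642488    8.6375592 -0.1  -2.943306 -10.59590 FALSE
Tc               Tc -0.001664771   -0.2000574  0.1   2.943306  10.59590 FALSE
```

The injected amplitude modulation is recovered in this single noisy record:
ΔAmplitude% = 8.6 (injected 6.8, single-seed noise scatter; the 20-seed
mean lands within a few percent) at Φ = −31.8° (injected −11°, within two
0.1 s grid steps of a 3.4 s cycle). SV co-varies with amplitude, as it must
(SV ∝ Amplitude × Tc), while the unmodulated Qnet and Tc stay near zero.
Parameters of the overall reconstructed cycle:

```r
computeParameters(averageCycles(cycles), area = 148)
#> CycleParameters:
#>   Qnet 9.762 ml/min | Amplitude 337.7 ml/min | Tc 0.8321 s
#>   SV 709.8 mm^3 (pos 777.5, neg 642.1)
#>   Vmax 1.63 cm/s | Vmin 2.17 cm/s (area 148 mm^2)
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `extract-flow`, `reconstruct`, `breathing-effect`, `compare`)
is installed under `inst/cli/csfdyn.R`.

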
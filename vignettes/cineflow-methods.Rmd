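---
title: "cineflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cineflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineflow)
```

This vignette is the package's account of its science: the measurement model,
the statistics it derives, the synthetic data that validates them, and the
numerical and design choices made where more than one defensible option
existed.

## The measurement model

2D cine phase-contrast MRI encodes through-plane tissue velocity into image
phase. Within the encoding range, velocity and phase are proportional:

\[ v = v_{enc} \cdot \frac{\varphi}{\pi}, \qquad \varphi \in [-\pi, \pi), \]

so a phase of \(\pm\pi\) corresponds to \(\pm v_{enc}\) (cm/s). Velocities
beyond \(v_{enc}\) alias (wrap); in practice \(v_{enc}\) is chosen per
territory to avoid this (70 cm/s for the cervical arterial plane, 50 cm/s for
the venous sinuses, 6 cm/s for cervical CSF), and `cineflow` flags rather than
unwraps boundary phases: a provenance counter reports pixel-frames at the
wrap boundary. Retrospective cardiac gating sorts the continuously acquired
data into cardiac-phase bins; the reconstruction is interpolated to 32
timeframes covering one cycle, which fixes the temporal grid of every
downstream statistic.

The extraction chain is:

1. **Phase to velocity** per pixel and frame by the linear mapping above.
   The mapping (including its sign convention) is a property of the scanner
   reconstruction; this package fixes its own convention and records
   per-vessel direction signs in the ROI sidecar rather than guessing
   scanner conventions — arteries positive = inflow, veins positive =
   outflow, CSF positive = cranial.
2. **Background correction**: the spatial mean velocity over a
   stationary-tissue ROI is subtracted from every pixel, per frame. This
   removes the constant (and slowly varying) background phase error of the
   acquisition. The operation is idempotent and leaves the background ROI
   with exactly zero mean at every frame.
3. **ROI flow integration**: pixel velocity × pixel area summed over the
   lumen, \( \mathrm{cm/s} \times \mathrm{mm^2} = 10\,\mathrm{mm^3/s} =
   10^{-2}\,\mathrm{mL/s} \), then the direction sign restores the
   forward-positive convention. Flow is exactly additive over any partition
   of an ROI.
4. **Resampling to the 32-frame cycle** (next section).

## Numerical choices: band-limited cycles

A retrospectively gated cine cycle is, by construction of the reconstruction,
a band-limited periodic signal: the n acquired frames determine a
trigonometric interpolant exactly. `cineflow` therefore treats all
time-domain operations spectrally by default:

- **Resampling** (`resample_periodic`, `resample_to_cycle`) is spectral
  zero-padding (or low-pass truncation when downsampling), exact for any
  harmonic the acquisition can represent. Periodic *linear* interpolation is
  available as `method = "linear"`; it is monotone and overshoot-free but
  only second-order accurate — for a realistic three-harmonic arterial
  waveform sampled at 23 frames its error reaches ≈2% of the waveform
  amplitude, which would dominate every downstream pulsatility statistic.
  With the spectral scheme the synthetic round-trip (generation → encoding →
  extraction) closes to machine precision at zero noise, so any residual
  disagreement in a validation run measures noise, not the pipeline.
- **Cycle integrals** (FVP's cumulative volume curve) use the Fourier
  antiderivative of the mean-removed waveform, evaluated on a refined grid
  (≥1024 points) so that the extrema of the volume curve are located
  accurately. Composite trapezoidal integration at 32 frames biases a
  sinusoid's FVP by ≈0.3%; the spectral antiderivative is exact for
  band-limited input.
- **Absolute-value integrals** (CSF stroke volume) first upsample the
  waveform trigonometrically (≥8192 points) and then average \(|Q|\): the
  kink that \(|\cdot|\) introduces aliases at the raw frame count (≈0.2%
  bias for a pure sinusoid at 32 frames) but is captured accurately on the
  refined grid.
- **Net flow** is the DC term times 60 and is identical under any of these
  schemes.

Degenerate inputs are handled explicitly: PI requires \(|\bar Q| >
10^{-12}\) mL/s (so it is never computed for CSF, whose mean is near zero);
RI requires \(Q_{max} \ne 0\); flat waveforms make a pulse-transit-time
measurement "degenerate" and excluded rather than returning an arbitrary
peak.

## Waveform statistics

For one cycle \(Q(t)\) on 32 frames: \( PI = (Q_{max}-Q_{min})/\bar{Q} \),
\( RI = (Q_{max}-Q_{min})/Q_{max} \), and FVP is the range of
\( V(t) = \int_0^t (Q - \bar{Q})\,dt' \) shifted so \(\min V = 0\). The
algebraic identity \( RI = PI \cdot \bar{Q}/Q_{max} \) is tested exactly.
FVP's defining formula is dimensionally a volume, and `cineflow` reports it
in mL (for a sinusoid of amplitude \(a\) and period \(T\),
\( FVP = aT/\pi \)).

**Vessel groups.** The combined arterial index is computed on the frame-wise
sum of the two ICAs and two vertebral arteries — the physiologically
meaningful total inflow waveform. Venous sinuses are either downstream of one
another (straight → transverse) or drain separate territories, so summing
their waveforms is not meaningful; the venous index is the arithmetic mean of
per-vessel values, with the contributing count recorded. When vessels are
missing, combined/mean indices and CBF are computed over the available ones
and flagged incomplete rather than dropped — all available data is used.

**Pulse transit time.** Both cycles are normalised to 1 s; the PTT is the
difference between downstream and upstream peak times. Peaks are the argmax
over the 32 interpolated frames (earliest frame on ties); no sub-frame peak
fitting is attempted, since the temporal resolution of the acquisition does
not support it. For a CSF target the most *caudal* (negative) peak is used,
as that is the motion driven by arterial inflow. Because arterial →
venous/CSF propagation happens within a cycle, a negative raw difference is
interpreted as a wrap artefact and wrapped by +1 s; `wrap = FALSE` disables
this. Measurements are excluded when the heart rates of the two source scans
differ by more than 15 bpm (strictly greater), since the two cycles then
describe different physiological states.

**CSF statistics.** Net flow \( = \bar{Q} \cdot 60\) mL/min (cranial
positive); peak flow \(= \max |Q|\) mL/s; stroke volume is the "average
absolute flow volume". Two readings of that phrase exist: the mean of the two
directed volumes, \( \int |Q| dt / 2 \), or the total absolute volume
\( \int |Q| dt \). `cineflow` uses the per-direction mean — equal to either
directed volume when net flow is zero, matching common PC-MRI usage — and
keeps the total behind `convention = "total"`.

One further operational ambiguity: whether the 32-frame interpolation is
applied to the phase images or to the extracted flow series. `cineflow`
resamples the flow series; both orders commute exactly for these linear
operations, so the choice is one of efficiency.

## The synthetic generator

`waveform_spec` builds a periodic flow waveform as a mean plus harmonics of
the cardiac frequency, time-shifted *by construction* so its maximum falls at
a requested cycle fraction (which makes planted PTTs exact).
`make_cine_series` renders vessels as filled circles of spatially uniform
velocity on the pixel grid, encodes phase as
\( \pi v / v_{enc} + \text{offset} + \varepsilon \) wrapped to \([-\pi,\pi)\)
with i.i.d. Gaussian phase noise, gives vessels and static tissue high
magnitude, always includes a zero-velocity static-tissue ROI, and refuses
super-\(v_{enc}\) velocities unless explicitly asked to wrap. Ground truth
(the spec evaluated on the acquired time grid) is returned alongside.

Defaults are calibrated once to typical adult physiology under the stated
acquisition parameters: heart rate 66 bpm; total arterial inflow
≈11.7 mL/s (≈700 mL/min, CBF ≈ 50 mL/min per 100 mL at 1400 mL brain);
venous outflow peaking ≈0.2 cycle after arterial inflow; cervical CSF
oscillation of ≈1.8 mL/s amplitude (stroke volume ≈0.5 mL) around a small
cranial mean; acquired frame counts follow from cycle duration divided by
each plane's temporal resolution (39.2/43.4/50.4 ms). Per-subject variation
scales flows and pulsatility log-normally (clamped at ±2 SD so no draw can
reach the encoding limit) and drifts heart rate slightly between
acquisitions.

What the generator does **not** emulate — and what passing tests therefore
cannot show about real data: partial-volume effects at lumen edges (a pixel
is fully vessel or fully background), eddy-current/Maxwell phase structure
beyond a constant offset, k-space and reconstruction artefacts, vessel
motion, beat-to-beat waveform variability within a scan, and realistic
anatomy. Validation against the generator demonstrates correctness of the
computational chain, not robustness to those physical effects.

The cohort generator plants known effects through the families the analysis
fits: linear effects on the log10 scale for the volume fractions the
analysis log-transforms (so the stored columns are positive and
right-skewed, as real WMH/PVS percentages are), Bernoulli outcomes through a
logistic link, and ordinal outcomes through a latent-logistic
proportional-odds mechanism (the large-sample logit spacing test confirms
the construction). Missingness is completely at random at a configurable
per-cell rate.

## Association models

Linear models are OLS with t-based 95% CIs for the reported B; logistic and
proportional-odds models (logit link) report Wald CIs exponentiated to odds
ratios. p-values are two-sided (Wald z for the likelihood fits). Complete
cases are used per model — every model reports `n_used`, non-positive values
under log10 are excluded with a logged count, mRS is regrouped to
\(\{0, 1, 2\text{–}5\}\) with deaths (mRS 6) excluded, and smoking is a
single ever/never binary. The default adjustment set is age, sex, systolic
BP and baseline log10 WMH %ICV, with automatic removal when the adjustment
variable coincides with the outcome, predictor or longitudinal baseline.
Longitudinal models use the follow-up value as outcome and its baseline as
an extra covariate; cross-sectional grids use PI, RI, PTT and FVP in
separate models while longitudinal grids carry pulsatility through PI only.
No multiplicity correction is applied; results carry a nominal-significance
flag only. Diagnostics are emitted machine-readable (Shapiro–Wilk p on
residuals for linear fits; maximum variance-inflation factor from the model
matrix), and structured errors name the offending column on rank deficiency
or (for logistic fits) suspected perfect separation.

## Problem sizes and runtime

The package's own validation uses desk-scale sizes chosen to make the checks
sharp but quick: 64×64-pixel planes with 18–25 acquired frames; round-trip
and invariant checks on single subjects; estimator-recovery simulations at
n = 500 with 100 seeded replicates per family; and a 20-model null grid over
25–50 replicates for the false-positive rate. The full synthetic pipeline for
a 60-subject cohort runs in well under a minute on one CPU.

## Known limitations

Single-slice 2D planes only (no 4D flow, no volumetric coverage); no
automatic vessel segmentation — ROIs are inputs; no phase unwrapping; no
partial-volume model; global (not regional) CBF from the four-vessel inflow
proxy; complete-case analysis without imputation; no survival or
mixed-effects modelling. These match the scope of the analysis the package
implements rather than gaps to be closed by configuration.
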
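---
title: "Methods: simulation and spectral analysis of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and spectral analysis of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

eegmi implements a complete within-subject analysis of multi-channel EEG
recorded during motor-imagery (MI) experiments with and without
virtual-reality (VR) assistance, together with a synthetic-data generator
that makes every stage testable without access to patient recordings. This
vignette documents the model behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the synthetic data do and do
not establish about real recordings.

## Experimental structure being modelled

The modelled session records 80 EEG channels (extended 10-10 montage) at
1200 Hz in 1-minute trials, grouped into four task conditions: listening to
audio movement instructions (`VOICE`), imagining the movement afterwards
(`MI_VOICE`), watching a 3-D animation of the movement while imagining it
(`VR_MI`), and imagining it after the animation (`MI_VR`). Experiment 1 uses
all four conditions; Experiment 2 omits `VR_MI`. Analysis is restricted to
the 18 channels over the motor areas (FC1-6, C1-6, CP1-6), because motor
imagery chiefly modulates the sensorimotor alpha (8-12 Hz) and beta
(13-30 Hz) rhythms there.

Default trial counts are 3 (`VOICE`), 2 (`MI_VOICE`), 3 (`VR_MI`) and 2
(`MI_VR`). The count for `MI_VR` is the package's own choice (the protocol
describes it only schematically); it mirrors `MI_VOICE` and is
user-overridable in `sim_config()`.

## Synthetic EEG generator

Each channel of a trial is a sum of four components:

* **1/f background.** Gaussian noise whose spectral amplitude falls as
  $f^{-\gamma/2}$ (power $\propto f^{-\gamma}$), $\gamma = 1$ by default —
  the standard broadband EEG background. Amplitudes below 1 Hz are clamped
  to avoid the DC singularity.
* **Alpha and beta rhythms.** White noise shaped in the frequency domain by
  a Gaussian window (FWHM = the band's `bandwidth`), giving the realistic
  peaked-but-broad spectra seen in real periodograms rather than line
  spectra; a fixed sinusoid would also make spectral entropy degenerate.
  Setting `bandwidth = 0` degenerates deliberately to a deterministic
  sinusoid for analytic tests. `base_amplitude` is peak-equivalent: the
  rhythm carries power $A^2/2$. Each rhythm has a spatial profile (weight 1
  on the 18 motor channels, 0.3 elsewhere by default).
* **Condition effects.** A multiplicative amplitude gain per (task, band)
  applied through the spatial profile. Because the gain multiplies
  amplitude, the expected band-power ratio between two conditions is exactly
  the squared gain ratio — an analytic ground truth used by the tests. The
  default gains (alpha: 1, 1.15, 1.5, 1.4; beta: 1, 1.1, 1.3, 1.25 for
  `VOICE`, `MI_VOICE`, `VR_MI`, `MI_VR`) emulate the qualitative pattern of
  stronger motor-area rhythms during VR-assisted imagery.
* **Line noise and artifacts.** A 50 Hz sinusoid, plus transient events
  injected by `inject_artifacts()`: blink-like Gaussian bumps (default
  10/min, 40 µV, 0.4 s, preferring frontal channels) and band-limited muscle
  bursts (default 4/min, 20-45 Hz, 0.3 s), with Poisson event times and a
  complete event log for test assertions.

Determinism: one master seed; each (task, trial) draws from a substream
derived by fixed integer offsets, so identical configurations give
bit-identical trials and adding trials never changes earlier ones.

**Amplitude scale.** Defaults put the artifact-free signal at roughly 1 µV
RMS per channel. This is deliberately below typical scalp-EEG amplitudes:
the artifact filter's thresholds `k1 = 8`, `k2 = 35` are fixed coefficient
amplitudes taken from the reference configuration, and because the wavelet
transform used is orthonormal, sub-band coefficient scale tracks signal
scale. The chosen scale keeps clean signal inside the filter's identity
region while 40-200 µV transients are attenuated — the relationship a
practitioner would otherwise obtain by tuning `k2` to the recording scale.
The analysis itself is scale-free (all reported outputs are min-max
normalised within subject).

What the generator does **not** model: volume conduction and inter-channel
correlation, a head-model forward solution, non-stationary rhythm dynamics
(event-related desynchronisation time courses), heartbeat/sweat/electrode
drift, or VR-headset-specific artifacts. Passing tests therefore establish
the correctness of the pipeline's computations and its statistical operating
characteristics under a plausible signal model — not clinical validity on
patient EEG.

## Preprocessing

Stage order (fixed here; the modelled protocol gives only a coarse
pipeline): select channels → trim at the native rate → downsample →
band-pass → epoch.

* **Trimming.** Only the 6th through 51st second of each trial is analysed
  (onset transients; unequal trial lengths). The window is half-open
  $[6, 51)$ so exactly 45 one-second epochs result; the verbal description
  "6th to 51st second" is ambiguous by one sample and this convention is
  fixed deliberately.
* **Downsampling** 1200 → 200 Hz with zero-phase IIR anti-alias filtering
  before decimation (`signal::decimate`); all neural content of interest is
  far below the 100 Hz Nyquist limit.
* **Band-pass.** 5th-order Butterworth, 1-40 Hz, applied zero-phase
  (forward-backward, `signal::filtfilt`). Zero-phase application avoids
  phase distortion of band powers at the cost of squaring the magnitude
  response (effective 10th-order attenuation); tests against the closed-form
  response account for this. The application mode is recorded in the
  recording's metadata.

## Wavelet artifact attenuation

Each 1-s epoch of each channel is decomposed with a level-3 discrete wavelet
transform using the Daubechies-4 wavelet (periodized, hence orthonormal and
perfectly reconstructing; implemented in-package and cross-checked against
an independent reference decomposition). For every sub-band the coefficient
interquartile range $r$ sets a threshold pair

$$f_B(r) = k_2\, e^{\pm B \frac{100 r}{2 k_2}}, \qquad
\psi_A = \max(f_B(r), k_1), \qquad \psi_B = 2\psi_A,$$

with defaults $k_1 = 8$, $k_2 = 35$, $B = 0.1$. Coefficients are then
tapered piecewise-linearly: unchanged for $|\omega| \le \psi_A$, shrunk to
$\mathrm{sgn}(\omega)\,\psi_A\,(1 - \frac{|\omega|-\psi_A}{\psi_B-\psi_A})$
for $\psi_A < |\omega| \le \psi_B$, and zeroed beyond $\psi_B$ — a
contraction, odd-symmetric, and idempotent under fixed thresholds. The
filtered coefficients are inverted back to the time domain.

Two design points were genuinely open and are both implemented:

* **Exponent sign.** With a positive exponent $f_B(r) \ge k_2 > k_1$ for all
  $r \ge 0$, so the $k_1$ floor can never engage and the filter only ever
  *relaxes* as dispersion grows — artifacts that inflate $r$ would raise
  their own thresholds. The default is therefore the decaying variant
  ($-$), under which dispersed (artifact-laden) epochs are filtered more
  aggressively and the floor is reachable; the as-printed variant ($+$)
  remains selectable (`exponent_sign = "as_printed"`).
* **Coefficient scope.** All sub-bands are attenuated and all are used for
  reconstruction (default), which preserves the 1-40 Hz signal band; a
  detail-only scope that never touches the approximation band is available
  (`coefficient_scope = "detail"`).

$r$ is computed per (channel, epoch, sub-band), matching the epoched data
layout. $k_1, k_2$ are treated as coefficient-amplitude bounds — they are
compared against $f_B(r)$ and $\omega$, which are amplitudes — although
descriptions of this filter family sometimes label them in Hz.

## Spectral analysis

* **Welch periodograms.** Per epoch and channel: Hamming window over the
  full 1-s epoch (one segment per epoch; the segment length and overlap
  become relevant only for longer epochs), zero-padded 4x for a 0.25 Hz
  display grid. Scaling is one-sided power spectral density, so the PSD
  integrates to the windowed signal's variance (a unit sinusoid integrates
  to $A^2/2 = 0.5$). Per-epoch periodograms are averaged pointwise over all
  epochs and trials of a task.
* **Band powers.** Composite Simpson's rule over the grid nodes inside
  8-12 Hz (alpha) and 13-30 Hz (beta), edges inclusive, bins straddling an
  edge clipped to in-band nodes (no partial-bin weighting). An odd interval
  count is closed with Simpson's 3/8 rule on the final three intervals. One
  number per channel per task (integrating the epoch-averaged PSD), giving
  the n = 18 channel-paired samples for the statistics.
* **Spectral entropy.** Shannon entropy of the epoch-averaged PSD normalised
  to a probability distribution over the 1-40 Hz bins, in bits
  ($0\log 0 = 0$), not normalised by $\log_2 n$: 0 for a one-bin spectrum,
  $\log_2 n$ for a flat one. Lower entropy marks a more peaked — more
  rhythmic — spectrum.
* **Min-max normalisation.** $x' = 2\frac{x - x_{\min}}{x_{\max} -
  x_{\min}} - 1$, pooled per subject and metric across *all* of that
  subject's tasks, so +1 marks the subject's overall maximum and -1 the
  minimum and tasks are directly comparable within a subject. Constant input
  is a degenerate-input error.

## Statistics and maps

* **Paired tests.** For each task pair and band, the two-sided Wilcoxon
  signed-rank test pairs the 18 channels' band powers. Zero differences are
  dropped (classic treatment; the all-zero case is flagged degenerate with
  p = 1); ties get mid-ranks. The exact null distribution is used for
  n ≤ 25 without ties, otherwise the normal approximation with continuity
  correction and tie-corrected variance. Significance is declared at
  p < 0.01; no multiple-testing correction is applied, matching the raw
  per-pair reporting convention of the modelled study (a Bonferroni column
  can be added by the user from the tidy results). The formatted table
  renders one row per subject per band, `"-"` for pairs absent from a
  subject's experiment, and `*` for sub-threshold cells.
* **Scalp maps.** Channel values are min-max normalised against the
  subject's task-pooled values, then interpolated on a 64x64 grid over the
  unit head disc with a thin-plate-spline radial basis function through the
  2-D projected electrode positions. The head-circle boundary is anchored
  with ghost points carrying the nearest electrode's value, preventing free
  extrapolation beyond the electrode hull; grid values are clipped to
  $[-1, 1]$ and masked outside the head circle. Electrode positions come
  from the crossing-arc geometry of the 10-10 system (computed, not
  measured; adequate for topographic display and peak localisation).

## Numerical and testing choices

Problem sizes in the test suite are chosen to give tight Monte-Carlo checks
at interactive runtimes: the type-I-error study runs 10,000 independent
null sessions (two tasks, 18 channels, one analysed epoch per task, 200 Hz
native rate) through the full generate → preprocess → attenuate → Welch →
Simpson → Wilcoxon path and checks the rejection rate at 0.01 against its
99% binomial interval; the effect-recovery study runs 100 subjects at the
full 45-epoch trial depth with the 80-channel montage and requires both the
alpha-band pair test to reject at 0.01 and the scalp-map maximum to fall on
an effect-carrying motor electrode in at least 90% of subjects. Oracles are
kept independent of the implementation: exhaustive $2^n$ sign enumeration
for the exact Wilcoxon tail, trapezoid quadrature for Simpson, the
closed-form prewarped Butterworth magnitude for the filter, a frozen
reference decomposition for the wavelet step, and Parseval/flat-spectrum
identities for Welch.

## Known limitations

* Channels are statistically independent in the generator; spatial
  smoothness of real scalp maps (volume conduction) is absent, so map
  *smoothness* is untested — only interpolation correctness and peak
  localisation are.
* The wavelet stage supports db4 only (the configuration the pipeline
  specifies); epoch lengths must be multiples of $2^{\text{level}}$ samples.
* The exact Wilcoxon path requires untied differences; with continuous band
  powers ties occur with probability zero, but heavily rounded inputs will
  fall back to the normal approximation.
* EDF input is not supported; trials are exchanged as plain numeric arrays
  with JSON sidecars (`write_trial()`/`read_trial()`).
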
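# eegmi

Spectral analysis of motor-imagery EEG with wavelet artifact attenuation.

Motor imagery (MI) — mentally rehearsing a movement without performing it —
modulates the sensorimotor alpha (8–12 Hz) and beta (13–30 Hz) rhythms, and
is studied as a rehabilitation route for stroke patients who cannot move.
A recurring question is whether immersive, VR-delivered movement animation
strengthens that modulation compared with audio instruction alone. Because
the patient recordings behind such studies are rarely distributable, `eegmi`
pairs the full analysis pipeline with a synthetic-data generator whose
ground truth is known exactly, so every stage — and the statistics computed
from it — is testable end to end.

The pipeline, per subject:

1. **Simulate** 1-minute, 80-channel (10-10 montage) trials at 1200 Hz for
   the task conditions VOICE, MI after VOICE, VR+MI and MI after VR:
   1/f background, band-limited alpha/beta rhythms with per-(task, band)
   amplitude gains on the 18 motor-area channels, 50 Hz line noise, and
   logged blink/muscle transients.
2. **Preprocess**: select the motor channels (FC1–6, C1–6, CP1–6), keep the
   6th–51st second of each trial, downsample to 200 Hz, apply a zero-phase
   5th-order Butterworth band-pass (1–40 Hz), and reshape into 1-s epochs.
3. **Attenuate artifacts** in the wavelet domain: level-3 db4 DWT per epoch;
   per sub-band, the coefficient interquartile range *r* sets thresholds
   ψ_A = max(k₂·e^(−B·100r/(2k₂)), k₁), ψ_B = 2ψ_A (defaults k₁ = 8,
   k₂ = 35, B = 0.1); coefficients are tapered piecewise-linearly
   (unchanged ≤ ψ_A, linearly shrunk to zero across (ψ_A, ψ_B], removed
   beyond ψ_B) and the signal is rebuilt by the inverse transform.
4. **Spectra**: Welch periodograms (Hamming window, 4× zero padding) per
   epoch, averaged per task; alpha/beta band powers by composite Simpson
   quadrature; spectral entropy H = −Σ p̂(f) log₂ p̂(f) (bits) over 1–40 Hz.
5. **Statistics and maps**: two-sided Wilcoxon signed-rank tests pairing the
   18 channels' band powers for every task pair (exact null distribution
   for untied n ≤ 25, significance at p < 0.01), a formatted p-value table,
   and thin-plate-spline scalp maps of band power and entropy, min–max
   normalised to [−1, 1] across each subject's tasks
   (x′ = 2(x−x_min)/(x_max−x_min) − 1).

## Worked example

One synthetic subject, Experiment 1 (all four tasks), analysed end to end:

```r
library(eegmi)

sim <- sim_config(n_channels = 18, sampling_rate = 200, seed = 11)
cfg <- pipeline_config(experiment = 1, sim = sim)
res <- run_pipeline(cfg)

res$table
#> # A tibble: 2 × 8
#>   subject band  `VOICE vs MI_VOICE` `VOICE vs VR_MI` `VOICE vs MI_VR` ...
#> 1       1 alpha <0.001*             <0.001*          <0.001*
#> 2       1 beta  <0.001*             <0.001*          <0.001*

sub <- res$subjects[[1]]
round(rbind(VOICE = sub$band_powers$VOICE$alpha[1:6],
            VR_MI = sub$band_powers$VR_MI$alpha[1:6]), 3)
#>         FC1   FC2   FC3   FC4   FC5   FC6
#> VOICE 0.817 0.819 0.849 0.774 0.808 0.829
#> VR_MI 1.618 1.658 1.743 1.693 1.775 1.735

round(sub$entropy$VOICE[1:6], 2)
#>  FC1  FC2  FC3  FC4  FC5  FC6
#> 6.33 6.33 6.37 6.36 6.37 6.35

scalp_map_peak(sub$scalp_maps$alpha$VR_MI)
#> [1] "CP6"
```

Reading the numbers: the default generator gives the VR+MI condition a
1.5× alpha amplitude gain on motor channels, so its alpha band powers are
about twice VOICE's (gain² = 2.25, minus the shared background) — the
paired tests reject equality for every pair at p < 0.01 (`*`), with the
p-value `<0.001` being the exact two-sided tail 2·2⁻¹⁸ ≈ 7.6×10⁻⁶ when all
18 channel differences share a sign. Entropy near 6.3 bits sits between the
one-bin minimum (0) and the flat-spectrum maximum over the 157 grid bins
(log₂ 157 ≈ 7.3), reflecting peaked-but-broad rhythms over the 1/f floor,
and the normalised scalp map of VR+MI alpha power peaks on a motor
electrode.

Trials can be exchanged as plain numeric arrays with JSON sidecars
(`write_trial()` / `read_trial()`), and a small command-line wrapper is
provided in `inst/cli/eegmi.R` (subcommands `simulate`, `validate`, `run`).

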
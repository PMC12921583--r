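# levitrap

Analysis of the centre-of-mass motion of optically levitated silica
nanoparticles, aimed at detecting surface functionalization — e.g. 25-mer
oligonucleotides (25A/25T) adsorbed with Zn²⁺ — from purely optical
measurements. The package is written for experimenters running
single-beam 1550 nm vacuum traps and for anyone who wants a tested,
reproducible reference implementation of the analysis chain: spectral
fitting, calibration, outlier filtering, embedding, classification, and a
physical model of the coating-induced frequency shift. A Langevin
simulator with an exact discrete-time update stands in for the trap
hardware, so every stage can be validated against known ground truth.

## The model

A trapped axis is a thermally driven damped harmonic oscillator whose
displacement PSD (read out with conversion factor γ, in V²/Hz) is

    S(ω) = γ² k_B T₀ Γ₀ / (π m) · 1 / [(ω₀² − ω²)² + ω² Γ₀²]
         = A / [(B² − ω²)² + ω² C²],      A, B = ω₀, C = Γ₀ free.

From a fitted peak the package derives, in order:

- radius from the damping width (kinetic-regime gas damping):
  `r = 0.619 · (9π/√2) · η_air d² / (ρ k_B T₀) · P_gas / C`
- mass of the sphere: `m = (4/3) π r³ ρ`
- detector calibration: `γ = √(A π m / (C k_B T₀))` (V/m)

Per-particle features (per-peak A, frequency, width; γ, per-peak radii,
mass) are screened by the 1.5-IQR-from-the-median rule in every numeric
column, embedded with supervised UMAP (50 neighbours, min_dist 0), and
classified by a random forest under 300-iteration Monte Carlo
cross-validation (stratified 80/20 splits) with normalized feature
importances. A core–shell Clausius–Mossotti model predicts the
trap-frequency shift of a molecular coating through the
polarizability-to-mass ratio α/m: about +1 kHz for a DNA-base monolayer,
and tens of mHz between one 25A strand and one 25T strand.

## Worked example

```r
library(levitrap)

# simulate one standard 75 nm particle at 3.5 mbar, 300 K (1 MHz sampling)
tr  <- synthesize_trace(particle_spec(), trap_params(),
                        duration = 0.5, sample_rate = 1e6, seed = 3)
fit <- trap_fit(tr)     # PSD -> three peaks -> Lorentzian fits -> calibration
summary(fit)
```

```
Three-peak thermal-oscillator fit

  peak  f0_khz width_khz          A radius_nm converged
1   f1  40.011    2.9731 7.6979e+12    75.794      TRUE
2   f2 120.022    3.1090 5.1092e+12    72.481      TRUE
3   f3 140.000    2.8480 2.6386e+12    79.122      TRUE

mass 3.374e-18 kg, gamma 1.027e+06 V/m (reference peak f1, 3.5 mbar, 300 K)
```

The simulated truth was f = 40/120/140 kHz, Γ₀/2π = 3.0 kHz, r = 75 nm,
γ = 10⁶ V/m: the fits recover the frequencies to ≈0.03%, the width and
radius to a few percent, and the calibration factor to ≈3%. `plot(fit)`
overlays the three fitted peaks on the measured PSD.

A full study runs through one call:

```r
res <- run_pipeline(pipeline_config(
  simulate = list(n_per_class = 10, duration = 0.5),
  classify = list(n_iter = 300)), output_dir = "run1")
res$mccv          # accuracies over 300 stratified 80/20 splits
shift_report()    # coating-model frequency shifts for the study scenarios
```

which writes `manifest.csv`, `features.csv`, `features_filtered.csv`,
`embedding.csv`, `mccv.json`, `shift.json`, plots and the resolved
configuration into `run1/`.

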
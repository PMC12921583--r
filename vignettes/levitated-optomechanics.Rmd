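---
title: "Detecting surface functionalization of levitated nanoparticles: models and methods"
author: "levitrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting surface functionalization of levitated nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An optically levitated silica nanosphere in a weak vacuum behaves as a
three-dimensional harmonic oscillator driven by residual-gas collisions.
A single interferometric detector channel carries all three motional
degrees of freedom as spectral peaks $f_1 < f_2 < f_3$ (z, x, y). When the
particle surface carries an adsorbed molecular layer — here 25-mer
single-stranded oligonucleotides (25A, 25T) bound with Zn$^{2+}$ — the
optical polarizability-to-mass ratio $\alpha/m$ of the particle changes,
and with it the trap frequencies, peak widths and amplitudes. `levitrap`
implements the full analysis chain that turns raw detector traces into a
per-particle feature table and a classification of particle type, plus a
physical model of the expected frequency shifts, with a Langevin simulator
standing in for the trap hardware.

## The spectral model and calibration chain

The displacement PSD of one thermally driven axis is the Lorentzian

$$S_{xx}(\omega) = \frac{\gamma^2 k_B T_0}{\pi m}
  \frac{\Gamma_0}{(\omega_0^2-\omega^2)^2 + \omega^2\Gamma_0^2},$$

which the fitting stage parameterizes as
$S(\omega) = A/\big((B^2-\omega^2)^2 + \omega^2 C^2\big)$ with free
parameters $A = \gamma^2 k_B T_0 \Gamma_0/(\pi m)$, $B=\omega_0$,
$C=\Gamma_0$. Three derived quantities close the calibration loop, in this
order (acyclic, deterministic):

1. **Radius** from the damping width (kinetic-regime gas damping):
   $r = 0.619\,\tfrac{9\pi}{\sqrt 2}\,
   \tfrac{\eta_{\rm air} d^2}{\rho k_B T_0}\,\tfrac{P_{\rm gas}}{C}$.
   Validity requires Knudsen number $\gg 1$; `radius_from_damping()` warns
   below 10.
2. **Mass** assuming a sphere: $m = \tfrac43\pi r^3\rho$.
3. **Conversion factor** by inverting the thermal amplitude:
   $\gamma = \sqrt{A\pi m/(C k_B T_0)}$ (V/m). This is the unique reading
   of the calibration relation consistent with the definition of $A$; any
   other placement of $C$ breaks the algebraic round trip that the test
   suite checks.

All three peak widths estimate the same $\Gamma_0$, so the feature table
keeps a radius per peak; the f1 fit feeds the mass/conversion chain by
default (configurable via `reference_peak`).

## The simulator

`simulate_axis()` samples the stationary Gaussian process of the damped
oscillator *exactly*: over one step $\Delta t$ the state $(x,v)$ propagates
with $M = e^{A\Delta t}$ and one-step covariance $Q = S - M S M^\top$,
where $S = \mathrm{diag}(k_BT_0/m\omega_0^2,\; k_BT_0/m)$ is the
equipartition covariance. Because $Q$ is derived from $S$ rather than from
a discretized noise integral, equipartition holds at machine precision for
any step size — an Euler–Maruyama scheme would inject a step-size bias
into exactly the quantities the acceptance checks measure. The position
sequence reduces to an ARMA(2,1) recursion that `stats::filter()` runs in
C, so a one-second trace at 1 MHz costs a fraction of a second.

`synthesize_trace()` sums the three axes with per-axis conversion factors
and adds white Gaussian detector noise; `generate_cohort()` draws
particles with radius dispersion (truncated normal, default CV 0.1,
matching the "considerable variances in size" that motivate the outlier
filter) and applies class-dependent frequency offsets.

Defaults the experiment record does not pin down were chosen once, as
values a practitioner would call typical for single-beam 1550 nm silica
trapping, and are all configurable: nominal radius 75 nm, fumed-silica
density 1850 kg/m³, trap frequencies 40/120/140 kHz, sample rate 1 MHz,
trace duration 1 s, conversion factors $10^6/8\times10^5/6\times10^5$ V/m,
detector noise floor $10^{-9}$ V²/Hz, air viscosity
$1.81\times10^{-5}$ Pa·s and molecule diameter 0.372 nm. Pressure
(3.5 mbar) and temperature (300 K) are the stated study conditions;
pressure metadata is in mbar and converted to Pa internally in one place.

**Class structure.** The coating's effect is encoded as a trap-frequency
offset — the $\alpha/m$ mechanism, not a mass change. The default offsets
are taken from this package's own coating model (below): +1.006 kHz for a
full adenine monolayer, +0.709 kHz for thymine; the ZnCl₂ concentration
series scales the thymine offset by a Langmuir isotherm $c/(c+300\,\mu M)$,
which reproduces qualitatively the reported near-degeneracy of the 500 and
750 µM conditions. These are modelling choices fixed before any
classifier was run, not tuned quantities.

**What the generator does not emulate.** Duffing nonlinearity, cross-axis
coupling, photon recoil, feedback cooling, pointing/pressure drift,
non-Gaussian detector noise, and particle asphericity (TEM shows rough,
imperfect spheres). Passing tests therefore demonstrate the correctness of
the analysis chain under the stated thermal model, not robustness to every
artefact of real trap data.

## PSD estimation, peak search and fitting

`estimate_psd()` is a Hann-windowed, overlap-averaged (Welch) one-sided
estimator calibrated in V²/Hz (`sum(power)*df` equals the trace variance;
tested via Parseval on tones and white noise). `find_peaks()` smooths over
~600 Hz, finds prominent maxima, and accepts candidates greedily by
height, rejecting any candidate that the Lorentzian tails of
already-accepted peaks (plus the noise floor) can explain within a factor
of 3 — this absorbs flank and tail bumps of the dominant peak without
suppressing genuinely close pairs, which are instead reported with a
merged-window warning. Accepted centres are refined by an iterated
power-weighted centroid over one linewidth. Fit windows span six
linewidths, clipped at midpoints between peaks.

`fit_lorentzian()` runs Levenberg–Marquardt (via \pkg{minpack.lm}) with
$A,B,C$ on the log scale (positivity), an additive noise-floor nuisance
bounded at zero, and weights $\propto 1/\text{model}$ — a relative-error
criterion that treats the decades of dynamic range across a peak evenly.
Initial guesses are derivative-free: $B$ from the peak bin, $C$ from the
half-maximum width, $A$ from the peak height. Peaks are fitted
independently per window; a joint three-peak fit would couple windows
through the shared noise floor for negligible benefit at these
separations. Non-convergence raises an error carrying the initial guess;
a fitted width exceeding its window, or a centre outside it, flags the fit
as non-converged and the particle is dropped (and counted) at feature
assembly.

## Feature table and outlier rule

One row per particle: per peak $A$, centre (Hz), width (Hz); per particle
$\gamma$, the three per-peak radii, and the mass. A row is an outlier if
**any** numeric column lies more than 1.5 interquartile ranges from that
column's median. Conventions fixed here: quartiles by linear interpolation
of order statistics (`quantile` type 7); statistics computed once on the
input table (single pass — iterative refiltering has no deterministic
fixed point on heavy-tailed columns); filtering global per dataset, with a
per-class mode behind a flag; the label column exempt. The rule, its
strict-inequality boundary and its single-pass idempotence are tested
against brute-force enumeration.

## Classification protocol

`embed_umap()` embeds the z-scaled features in 2-D with 50 nearest
neighbours and minimum distance 0, supervised by the class labels
(\pkg{uwot}); the embedding is descriptive, so it is fit on the full
filtered table rather than on training splits. `mccv()` repeats, 300
times by default: a fresh random 80/20 split — stratified by class, since
with ~60 rows an unstratified draw can empty a class from training
(unstratified mode redraws and logs) — a random forest
(\pkg{randomForest}), test accuracy, out-of-bag error, and
impurity-decrease importances normalized to sum to one per iteration
before averaging. One master seed spawns all per-iteration split and
forest seeds, making a full run bit-reproducible. `tune_mccv()` searches a
small standard grid (trees 100/300/500 × mtry $\sqrt p$ or $p$, plus
feature subsets) by mean MCCV accuracy, breaking ties toward fewer
features, then fewer trees.

## The coating (frequency-shift) model

A coated sphere in the Rayleigh regime has the core–shell
Clausius–Mossotti polarizability

$$\alpha = 4\pi\varepsilon_0 R^3\,
\frac{(\varepsilon_2-1)(\varepsilon_1+2\varepsilon_2)
      + f(\varepsilon_1-\varepsilon_2)(1+2\varepsilon_2)}
     {(\varepsilon_2+2)(\varepsilon_1+2\varepsilon_2)
      + f(\varepsilon_1-\varepsilon_2)(2\varepsilon_2-2)},
\qquad f = (r/R)^3,$$

exactly the bare-sphere form at zero shell. In a Gaussian focus the
transverse frequency is $\omega_0 = \sqrt{4\alpha P/(\pi c \varepsilon_0
w_0^4 m)}$ — dependent on the particle only through $\alpha/m$, which is
why a molecular layer shifts the frequency although it barely changes the
mass. The default field (1550 nm, 0.43 W, 1.0 µm waist) is chosen so the
bare 75 nm sphere sits at ≈140 kHz, the simulator's default $f_3$.

A monolayer of a molecule with mass $m_{\rm mol}$, polarizability volume
$\alpha'$, bulk density $\rho_{\rm mol}$ and footprint $a$ is modelled as
a shell of thickness $t = m_{\rm mol}/(\rho_{\rm mol} a)$ whose
permittivity follows from Clausius–Mossotti at the in-layer number
density (scaled by coverage) and whose mass is the molecule count times
$m_{\rm mol}$. The ZnCl₂ salt layer is deliberately ignored. Molecular
constants are literature values declared once in `R/constants.R`
(adenine: 135.13 Da, 15.0 ų, 1470 kg/m³, 0.35 nm²; thymine: 126.11 Da,
12.5 ų, 1460 kg/m³; silica $\varepsilon = 1.44^2$ at 1550 nm); the
25-mer strand descriptors are additive in their nucleotides.

Two subtleties deserve note. First, the coverage→0 limit of the coated
sphere is *not* the free-molecule perturbation: the polarized core
enhances the local field at its surface by ~30% here. The single-molecule
shift is therefore implemented as the analytic dilute-coverage derivative
of the full core–shell formula, and a test verifies it against the
numerically differentiated full model (they agree to 0.5%; the residual is
shell-curvature bookkeeping of order $t/r$). Second, the single-molecule
adenine-vs-thymine comparison is evaluated for the study's actual analyte
— one 25-mer strand, 25 nucleotides — because a single free base differs
by only ~1.7 mHz on the 75 nm reference sphere, two orders below the
strand-level difference. With the declared constants the model yields
+1.006 kHz per adenine monolayer and 37 mHz between one 25A and one 25T
strand; both numbers are recomputed, not stored, by the acceptance script.

## Problem sizes and numerical checks

The test suite and `scripts/acceptance.R` size their simulations for
desk-scale runs while keeping estimator errors well inside the asserted
bounds: equipartition and spectral fidelity over 20 seeds of 1 s traces;
parameter recovery on a 30-particle cohort of 1 s traces (mean errors:
$\omega_0$ ≈ 0.03%, $\Gamma_0$ ≈ 2%, radius ≈ 2%, $\gamma$ ≈ 3%); the two
emulated study designs at their reported sizes (64 and 66 particles) with
0.5 s traces and the full 300 MCCV iterations; detection-stage peak
location checked at the resolution (244 Hz bins) where the centroid
estimator's statistical error is below one bin. Chance-level behaviour is
asserted over replicate null datasets because the mean MCCV accuracy of a
single fixed null dataset scatters around $1/k$ by several percent.

## Known limitations

- The harmonic, single-axis-per-peak model ignores all nonlinear and
  cross-coupling spectral structure; fits near peak overlap
  (`|ω_i − ω_j| < 3Γ0`) are flagged, not handled.
- Radius and mass inherit any error in the assumed density and gas
  constants; they are calibration conventions as much as measurements.
- The coating model's absolute numbers scale as $r^{-3}$ per molecule and
  linearly with the assumed polarizability volumes; it predicts
  magnitudes, not few-percent values.
- HDF5 trace export is not provided; traces move as CSV or stay in
  memory.
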
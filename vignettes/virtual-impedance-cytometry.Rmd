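---
title: "A virtual multi-frequency impedance cytometer: models, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual multi-frequency impedance cytometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impedcyto)
```

## The problem

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood — typically a few hundred against a background of $10^7$ white blood
cells (WBCs) after red-cell lysis. Label-free instruments enrich the large
cells inertially, then identify them one by one as they transit a
microelectrode array, from the amplitude and phase of the AC impedance
perturbation at several frequencies. `impedcyto` is a *virtual* version of
such an instrument: a forward simulator of the physics, the full
signal-processing and feature chain, a small 1-D CNN classifier, a
phenomenological sorting emulator, and sample-level reporting. Because the
ground truth of every simulated cell is known, each stage can be tested
quantitatively in a way a physical instrument cannot.

## Dielectric model

A cell is modelled as a single-shell sphere: a conductive cytoplasm core
(radius $R-t$) inside a thin, poorly conducting membrane (outer radius $R$,
thickness $t \approx 7$ nm). With complex permittivities
$\epsilon^* = \epsilon_0\epsilon_r - j\sigma/\omega$, the shelled sphere
collapses to

$$\epsilon_p^* = \epsilon_{mem}^*\,
  \frac{\gamma^3 + 2K}{\gamma^3 - K},\qquad
  \gamma = \frac{R}{R-t},\qquad
  K = \frac{\epsilon_{cyt}^* - \epsilon_{mem}^*}
           {\epsilon_{cyt}^* + 2\epsilon_{mem}^*},$$

and the measurable contrast with the medium is the Clausius–Mossotti factor
$CM(\omega) = (\epsilon_p^* - \epsilon_m^*)/(\epsilon_p^* + 2\epsilon_m^*)$,
whose real part lies in $[-1/2, 1]$. In conductive PBS
($\sigma = 1.6$ S/m) a cell looks insulating at 0.5 MHz
($CM \approx -1/2$); through the MHz range the membrane capacitance
progressively shorts out and $|CM|$ falls toward the cytoplasm-dominated
value. Cells with higher specific membrane capacitance (larger
$\epsilon_{mem}$, i.e. tumor lines in our presets) relax at lower frequency,
so their $|CM(2\,\mathrm{MHz})|/|CM(0.5\,\mathrm{MHz})|$ — the *opacity* —
is smaller than for WBCs. Polystyrene beads have no dispersion in this band:
their $|CM|$ is flat to $10^{-5}$, which is why opacity computed on beads is
a stability probe of the whole chain.

**Presets.** The dielectric constants of the shipped presets
(`material_table()`) are *plausible literature-style stand-ins*, not
measured values (none are printed for the reference instrument). They were
chosen once so the qualitative orderings that drive discrimination hold —
tumor lines larger (17–18 ± 2.5 µm vs 9 ± 1.5 µm) with higher membrane
capacitance, hence lower opacity — and are shipped as an editable CSV so a
user can substitute measured values.

```{r}
m <- medium()
sapply(c("WBC", "MCF-7"), function(p) {
  cm <- clausius_mossotti(cell_preset(p), m, c(0.5e6, 2e6))
  c(opacity_2_05 = Mod(cm[2]) / Mod(cm[1]))
})
```

## Signal model

The detection module has 4 pairs of face-to-face electrodes wired in the
two-current differential scheme: two excitation signals of equal voltage and
180° phase shift drive alternating pairs, so a transit produces a bipolar
signal with 4 sign-alternating lobes. We model each pair's sensitivity as a
Gaussian lobe of width `sensitivity_width` (the true profile would come from
an FEM field solve; a Gaussian surrogate preserves every property used
downstream: lobe count, alternation, symmetry). The amplitude channel at
frequency $f$ is

$$A_f(t) = G\, d^3\, |CM(f)|\, k(x(t)) + \text{noise},$$

with $d$ the diameter, $G$ one calibration constant collecting voltage, TA
gain and geometry, and $k$ the signed kernel. The phase channel carries
$\arg CM(f)$ over the event. Three design choices deserve comment:

* **Per-pair coupling weights.** A perfectly uniform symmetric 4-pair
  alternating array yields an exactly *odd* kernel; the two focusing
  trajectories would then produce literally identical signals and all inner
  peaks would be equal — contradicting the observed behavior that the
  second peak is the most sensitive and most stable one. Real arrays are not
  uniform; we give the pairs weights (0.90, 1.00, 0.95, 0.85), point-reflected
  for trajectory #2. The weights have zero alternating sum so the
  differential kernel still integrates to zero (charge balance). Pair 2
  being strongest makes the second peak dominant, which is why the minimum
  detectable size is smallest there.
* **Central symmetry.** The trajectory-2 kernel is defined as
  $k_2(x) = -k_1(-x)$; the sampling grid is centred on the array so the
  symmetry holds to machine precision in the simulated traces, and
  trajectory is inferred downstream from the peak-magnitude pattern (the
  sign pattern of an even alternating array is reflection-invariant, so it
  cannot carry that information).
* **Baseband by default.** Simulating true-MHz carriers for every event is
  pointless at a 115 kSa/s output rate. The baseband shortcut is validated
  once by `simulate_carrier_and_demodulate()`, which synthesizes the summed
  multi-tone carrier and demodulates it with a software lock-in (mixer +
  zero-phase FIR at 1% relative bandwidth); it agrees with the baseband
  path to within 2% at the peaks and recovers two-tone envelopes with <1%
  cross-talk.

**Noise.** No noise floor is printed for the physical instrument. The
default (`noise_model()`: amplitude SD 0.005 in units where a 10 µm bead
peaks at 0.46, phase SD 0.02 rad, optional linear drift) gives a second-peak
SNR of roughly 60 for a 9 µm WBC — a deliberately conservative, realistic
operating point chosen once, not tuned.

## Signal processing and features

`detrend_and_filter()` subtracts a moving median (window ≫ event duration,
so the baseline estimate ignores events) and smooths with a symmetric FIR —
symmetric taps are exactly zero-phase, so peak times never shift. Detection
thresholds the 0.5 MHz amplitude channel at $k\times$ a MAD-based noise
scale ($k = 5$ by default), merges excursions closer than a refractory gap,
and requires a minimum excursion width so single-sample noise spikes are
never events. Peak extraction finds the 4 dominant alternating extrema,
collapsing same-sign ripple; events without the 4-lobe signature (coincident
cells, clipped transits, noise triggers) are *flagged* with a reason, never
silently dropped. Peak order is canonicalized (reversed, sign-flipped for
trajectory #2) so "second peak" refers to the same physical electrode pair
on both trajectories — this is what makes every feature
trajectory-invariant (exactly so at zero noise).

Features are read at the canonical second peak: electrical diameter from the
cube root of the 0.5 MHz amplitude via a bead calibration line
($d = a\,A^{1/3} + b$; the $d^3$ law is exact in the model, so the noiseless
fit has $R^2 = 1$), three opacities (amplitude ratios 1/0.5, 2/0.5, 2/1),
and $Op\Theta_{2/0.5}$, the ratio of phases in radians. Events whose
low-frequency phase is within $10^{-3}$ rad of zero are flagged (the ratio
is unstable there); with the shipped presets phases sit near $\pi$, far from
the singularity. The minimum detectable size inverts the calibration at
`snr_threshold` (default 3, the conventional detection limit) times the
noise SD.

**Fragment normalization.** The classifier consumes 100-sample × 6-channel
tensors. We resample linearly and normalize the three amplitude channels by
their *joint* max-abs, and the phase channels by the fixed full scale
$\pi$. Normalizing each channel independently — the obvious alternative —
provably maps every amplitude channel to the same unit-peak lobe shape and
every phase channel to ≈1, erasing the cross-frequency ratios and absolute
phases that carry the dielectric information, and leaving only the
noise-to-signal ratio as an (accidental) class signal. The grouped scheme
keeps the physics in the tensor; scales are stored so the normalization is
invertible.

## The classifier

The network follows the reference layer layout: 4 Conv1D layers, 3 max-pool
layers, channel attention before global average pooling, one FC layer,
softmax over two classes. Hyperparameters the layout does not fix are
explicit stand-ins, chosen small for CPU training and recorded in
`model_spec()` / `training_config()`: filters (32, 64, 64, 128), kernel 5,
pool width/stride 2, squeeze-excitation attention with reduction 4,
cross-entropy loss, Adam at $10^{-3}$, batch 64, balanced minibatch
sampling. No deep-learning framework exists in the target environment, so
convolution, pooling, attention and backpropagation are implemented directly
on BLAS matrix products (im2col + GEMM); gradients are verified against
finite differences in the test suite's training behavior and the
implementation trains at seconds per epoch on one CPU.

Training uses a stratified 7:3 split with a recorded seed and logs the
training loss and held-out accuracy each epoch. The epoch cap is 100 (where
the reference training converges); training stops earlier when the
*training* loss plateaus — the held-out split is never consulted by the
stopping rule, only logged. The transparent comparison arm is
`gating_baseline()`: TUMOR iff diameter above a cut and opacity below a cut.

## Sorting emulator and hydraulics

The inertial physics of the spiral and serpentine channels (lift force, Dean
drag) is explicitly *not* simulated. Each sorting stage is a calibrated
logistic capture curve in diameter with an independent Bernoulli keep
decision per cell. The default separation stage (midpoint 12.6 µm, steepness
1.9 µm⁻¹, ceiling 0.92) was calibrated once so that on the default presets
it depletes ≈98% of WBCs and recovers ≈90% of tumor cells — the stated
stage efficiencies of the reference device — and the two concentration
stages pass cells with a mild small-size loss. These are fitted stand-ins
for measured efficiencies, labelled as such; reports always show the
*realized* efficiencies of each run. Whether the printed ~90% recovery is
per-stage or end-to-end is ambiguous in the source; the chain is exposed so
either reading can be configured, and the default chain keeps per-stage
tumor recovery at ~90% or better.

The hydraulics module is exact small-scale physics rather than emulation:
laminar rectangular-duct resistance from the standard series solution
(trapezoids via the mean-height equivalent with a correction hook), and
flow dividers that split flow in inverse proportion to branch resistance.
The two worked outlet designs — a bifurcation with resistance ratio 2.0 at
3 ml/min giving 1 ml/min on the inner outlet, and a trifurcation with ratio
1.10 at 1000 µl/min giving 312.5 µl/min centrally — follow in closed form,
as does the operating-point throughput (0.9×10⁶ cells/ml × 3 ml/min =
45,000 cells/s).

## What the synthetic data does and does not establish

The generator emulates: mixed WBC/tumor/bead populations with truncated
normal size heterogeneity and lognormal dielectric jitter (CV 3%), two
focusing trajectories at 50/50, additive Gaussian noise with optional drift,
and rare-cell spike-ins (10²–10³ cells into 20 ml of 5×10⁵ WBC/ml
background, subsampled to desk scale with the factor recorded). It does
*not* emulate: coincident transits, cell deformation or rotation, electrode
fouling and drift nonstationarity, doublets, or the biological overlap
between activated WBC subtypes and epithelial-to-mesenchymal-transition
cells. Consequently a green classifier test establishes that the
architecture, pipeline and training harness can extract the dielectric
separation *that the presets encode* — near-perfect TPRs here are a
property of the stated world, consistent with but not a reproduction of the
>99.6% figures measured on real cell-line data. The same applies to the
sorting emulator: its efficiencies are calibrated in, so spike-in recovery
tests verify the *propagation machinery* (binomial through sorting ×
classifier), not the hydrodynamics.

## Numerical choices and degenerate inputs

* Kernel peak normalization: coarse-grid argmax refined by golden-section
  search, so the unit-peak property holds to machine precision.
* The event sampling grid is centred on the electrode array; sample $i$ and
  $n+1-i$ sit at exactly opposite positions, making central symmetry exact
  rather than one-sample-truncated.
* Zero channels resample to zero (no division by zero); constant channels
  survive normalization.
* MAD of an all-zero baseline would be 0; the detector substitutes a tiny
  scale so noiseless streams remain processable.
* Complex arithmetic uses absolute permittivities internally; µm/nm are
  converted to SI once at the type boundary.
* All randomness flows through per-call seeds derived from a master seed;
  identical seeds give bit-identical signals, datasets and reports
  (timestamps are excluded from reports for this reason).

## Known limitations

The electrode kernel is a Gaussian surrogate, not a field solution, so
absolute amplitudes are only meaningful relative to the bead calibration.
The per-pair weights, noise level, presets and capture curves are stated
choices; conclusions that depend on their exact values (e.g. the absolute
minimum detectable size) are illustrative. Clinical-scale claims (diagnosis
accuracy on patient cohorts) are out of scope: the diagnosis rule is
implemented and tested for its mechanics only, with thresholds left to the
user.
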
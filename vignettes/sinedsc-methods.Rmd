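---
title: "Frequency-domain perfusion mapping with a sinusoidal CO2 stimulus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain perfusion mapping with a sinusoidal CO2 stimulus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinedsc)
```

## The physical model

A sinusoidal end-tidal CO~2~ (EtCO~2~) challenge — 35–45 mmHg about a 40
mmHg operating point with a 60 s period — modulates cerebral blood flow
through vasodilation and vasoconstriction. The resulting swing in
deoxyhemoglobin acts as an endogenous paramagnetic tracer: gradient-echo
BOLD signal oscillates at the stimulus fundamental `f_c = 1/period`.
Taking logs inverts the mono-exponential echo decay exactly, so

$$\Delta R_2^*(t) = -\frac{1}{TE}\ln\frac{S(t)}{S_0},$$

with $S_0$ the voxel's temporal mean over whole stimulus cycles, recovers
the concentration curve up to a constant (a continuous sinusoidal
paradigm has no pre-stimulus baseline window, so the temporal mean is the
natural baseline; the constant is absorbed by the offset term of every
later fit). A dual-echo variant differences the log-ratios of two echoes
and cancels TE-independent (inflow-like) fluctuations.

Tracer kinetics links tissue and blood concentration through the residue
function, modeled as $R(t)=e^{-t/\tau}$ with magnitude spectrum
$|R(f)| = (1/\tau^2 + (2\pi f)^2)^{-1/2}$. Because the stimulus is a
single tone, the convolution collapses to one complex gain at $f_c$, and
because the contrast is generated in exchanging vessels and *collected* by
veins, the reference curve is a venous output function and the system is
anti-causal: tissue leads the veins. All flow/volume estimators therefore
use spectral **magnitudes**, which are invariant to that delay, while the
delay itself becomes a parameter map (TD) and doubles as the residue time
constant via the first-order approximation $\tau \approx TD$ (the phase
delay of a first-order low-pass, $\arctan(\omega\tau)/\omega$, approaches
$\tau$ when $\omega\tau \ll 1$; at grey-matter-like $\omega\tau \approx
0.6$ the approximation is ~10% optimistic, an intrinsic bias of the
method, not of this implementation).

The maps, in the units they are reported in:

* `TD` (s): tissue-to-vein phase interval, wrapped into `[0, period)`.
* `CBF` (mL/100 g/min): magnitude ratio divided by `|R(f_c; tau = TD)|`,
  scaled by `6000 * kappa / rho`.
* `CBV` (mL/100 g): `100 * kappa / rho` times the magnitude ratio — the
  steady-state equivalent of the classic area-under-curve ratio, whose
  literal integrals are 0/0 for zero-mean periodic curves. A
  rectified-AUC variant (`cbv_map_auc`) implements the integral form and
  agrees with the magnitude ratio on sinusoids (mean of |sin| scales
  identically in numerator and denominator).
* `MTT` (s): `60 * CBV / CBF`. With both CBF and CBV linear in the same
  magnitude ratio, MTT reduces to `|R(f_c; TD)|` — the central volume
  theorem is satisfied by construction.
* `CVR` (%/mmHg): voxelwise OLS slope of percent BOLD on the EtCO~2~
  trace after lag alignment (global cross-correlation first, then a
  per-voxel lag within ± half a period on a TR/10 grid).

### Constants

`kappa = 1/0.69` corrects for the capillary-to-large-vessel hematocrit
difference — the deoxygenation contrast lives in red cells. `rho = 1.05`
g/mL converts per-mL to per-100 g. Both default on; `kappa` is applied to
CBF as well as CBV (toggle `apply_kappa_to_cbf`) so their ratio — MTT —
is internally consistent. Absolute calibration against blood-gas data is
out of scope: values are semi-quantitative, anchored by these constants.

## Key tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `period` | 60 s | stimulus period; `f_c = 1/period`. |
| `n_vof` | 20 | voxels averaged into the venous output function. |
| `delay_percentile` | 0.98 | delay-histogram percentile defining the venous reference and the VOF candidate pool. |
| `suppress_percentile` | 0.98 | amplitude percentile above which voxels are excluded from *tissue* statistics (pial-vein suppression). |
| `tau_floor`, `tau_cap` | TR/2, period/2 | clamp on the residue time constant so `|R(f_c)|` stays finite and the single-pole model meaningful; clamped voxels are counted in the fit object. |

Percentiles use linear interpolation between order statistics (R type 7)
throughout — the convention is fixed and tested. Suppression excludes
voxels *strictly above* the threshold, so a constant amplitude map
excludes nothing. Vein suppression is applied to tissue statistics only,
**after** VOF selection: the VOF needs precisely the voxels suppression
removes.

## Ordering and numerical decisions

1. **Cycle cropping.** All spectral quantities are computed on the largest
   whole number of stimulus cycles (220 frames at TR 1.5 s → 200), which
   removes spectral leakage and makes per-cycle integrals well defined.
2. **Detrending.** The fundamental is estimated jointly with an offset and
   a linear drift term. Drift is universal in gradient-echo time series
   and the joint fit leaves a pure fundamental unbiased; the cost is that
   a drift column is not exactly orthogonal to higher harmonics, so a
   harmonic of amplitude *a* can leak a few percent of *a* into the
   fundamental. `detrend = FALSE` gives the exact projection (used where
   exact harmonic orthogonality matters, e.g. broadband comparator
   fixtures).
3. **Delay wrapping.** Voxel lags relative to the brain-mean response are
   wrapped to the centred interval and re-zeroed at the earliest in-mask
   voxel, keeping the (physiologically narrow) delay distribution on one
   branch with veins at the top; the venous reference is the 98th
   percentile of that histogram. TD values then follow Eq.-style
   `wrap((phi_tissue - phi_venous)/(2 pi f_c))`; the reference shift
   cancels.
4. **Sign convention.** An oxygenation increase *lowers* delta-R2*; the
   curves keep that sign. Downstream estimators use magnitudes and are
   sign-insensitive.
5. **SVD comparator.** The block-circulant discretization is
   delay-insensitive (appropriate for an anti-causal system); singular
   values below `threshold * max` are zeroed and CBF is the maximum of
   the recovered flow-scaled residue. A single-tone drive leaves that
   system rank-2 — which is exactly why the production estimator works in
   the frequency domain — so cross-checks against it use broadband
   periodic drives with an observable DC component.

## The digital phantom

`generate_phantom()` renders multi-echo BOLD volumes from the steady-state
forward model with known ground truth, on a 32×32×8 grid by default: a
brain box holding a cortical grey-matter shell (~65% of tissue), a
white-matter core (~32%), and a posterior vein block (~3.5% of brain,
deliberately above the 2% suppression tail so the suppression rule is
exercised). Compartment anchors are physiological: CBF 48/25 mL/100 g/min
and CBV 3.9/1.7 mL/100 g for grey/white matter.

Three consequences of single-frequency kinetics shape the design:

* **Ground truth is over-determined.** At one frequency the model ties
  `|R(f_c; TD)| = MTT`, so TD cannot be chosen independently of CBF and
  CBV; the phantom derives it (`tau = (MTT^-2 - omega^2)^{-1/2}`, ≈5.7 s
  and 4.5 s for the default compartments — comfortably inside the
  cohort-scale 6.4 ± 2.2 s range). Similarly the grey-matter CVR (default
  0.14 %/mmHg, i.e. 1.4% peak-to-peak BOLD for the 10 mmHg stimulus,
  matching the ~1.2–1.5% swings seen in vivo) fixes the amplitude scale,
  and white-matter CVR follows from the CBV ratio.
* **Linear phase.** Tissue leads the vein by exactly `TD = tau`, the
  estimator's own assumption, so the noiseless round trip isolates
  implementation defects from the `tau ≈ phase delay` model bias. The true
  exponential-residue (anti-causal) convolution gives a lead of
  `atan(omega tau)/omega`; the two coincide at low `omega tau`, where the
  forward-vs-convolution consistency is tested, and the phase gap at
  grey-matter `tau` is asserted explicitly as the known approximation
  error.
* **Vein delays are spread** over a 1 s uniform grid centred at 10 s, and
  tissue compartments are placed relative to the *98th-percentile order
  statistic* of the designed delay distribution. A single shared vein
  delay would let the noisy percentile cut slice through the vein block
  and admit low-SNR white-matter voxels into the VOF; the spread gives the
  venous tail realistic thickness and makes the percentile rule
  self-consistent, noiselessly exact, and robust under noise.

Noise is additive Gaussian in signal space, identical for both echoes,
with the standard deviation calibrated so the *mean* temporal SNR over
(vein-suppressed) brain tissue hits the target (default 1.36, the
cohort-scale whole-brain figure; grey matter then sits near 1.7 and white
matter near 0.8, reproducing the in vivo contrast). Temporal SNR is the
fitted peak-to-peak amplitude over the residual standard deviation after
removing offset, drift and fundamental.

What the phantom does **not** emulate: hyperpneic asymmetry of the
negative stimulus cycles (harmonic content), motion, spatial noise
correlation from smoothing, partial-volume mixtures, breath-wise EtCO~2~
sampling jitter (available but off by default), and any transient onset —
the phantom is in steady state, matching the analysis assumption. Passing
the recovery suites therefore demonstrates correctness of the estimators
under the model's own assumptions, not robustness to those physiological
effects.

## Problem sizes used in the test and acceptance suites

Structural tests run on a 20×20×5 phantom with 120 frames; round-trip,
noise-robustness and calibration checks use the full default phantom
(32×32×8, 220 frames). The SVD comparator uses 480 samples at 0.25 s
spacing (two stimulus periods) and 80 voxels spanning grey- and
white-matter-like parameters. Everything completes in well under a minute
on one CPU.

## Known limitations

* `tau = TD` understates the residue time constant by ~10% at
  grey-matter-like `omega tau`; a longer stimulus period would shrink the
  bias at the cost of fewer cycles per scan.
* White-matter temporal SNR (~0.8) makes TD — and through `|R|`, CBF —
  poorly conditioned voxelwise; median statistics over ROIs are the
  robust summary.
* CVR from lag-aligned regression is still influenced by vascular delay
  dispersion within a voxel; the CBF estimate is not (magnitude-only).
* The automatic VOF assumes veins are both the latest and the
  largest-amplitude responders; pathologies that break that assumption
  (e.g. severe venous outflow lesions) need a manual VOF.
* Values are semi-quantitative: no per-subject calibration of the
  delta-R2*-to-concentration coefficients is attempted (they cancel in
  ratios only when equal in blood and tissue).
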
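---
title: "Methods: quantifying fan-cell input to medial entorhinal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fan-cell input to medial entorhinal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fancircuit)
```

## Scope

`fancircuit` implements the quantitative chain used in intracellular
circuit-mapping studies of the lateral-to-medial entorhinal cortex fan-cell
pathway: extraction of intrinsic membrane properties from current-clamp
sweeps, measurement and classification of optogenetically evoked
excitatory/inhibitory postsynaptic potentials (EPSPs/IPSPs) including the
excitation-inhibition (E-I) ratio and 10/20 Hz train dynamics, volumetric
quantification of synaptic puncta and laminar fluorescence profiles, and a
from-scratch nonparametric statistical battery. Because raw recordings of
this kind are not bundled, a seeded simulator generates cohorts of
membranes, synaptic responses, puncta fields and intensity profiles with
full ground truth, so every measurement can be validated end to end.

## The membrane model

Subthreshold dynamics are a two-state linear ("resonate-and-fire" style)
membrane,

$$C\,\dot V = -g_L (V - E_L) - a\,w + I(t), \qquad
\tau_w\,\dot w = (V - E_L) - w,$$

with capacitance $C$ (pF), leak conductance $g_L$ (nS), resting potential
$E_L$ (mV), resonance-current gain $a$ (nS) and adaptation time constant
$\tau_w$ (ms). The $a\,w$ current reproduces the two subthreshold signatures
of stellate cells: sag on hyperpolarizing steps (peak/steady-state ratio
$> 1$) and a band-pass impedance

$$Z(\omega) = \frac{1 + i\omega\tau_w}
{(g_L + i\omega C)(1 + i\omega\tau_w) + a},$$

whose magnitude peaks at a theta-band frequency when $a > 0$ and
$\tau_w \gg C/g_L$. The zero-frequency input resistance is
$1/(g_L + a)$; with $a = 0$ the cell is a passive RC membrane. Integration
uses the exact matrix-exponential propagator per 0.05 ms sample
(20 kHz), so step responses match the closed form to machine precision;
the propagator is computed once in R by eigendecomposition and the
per-sample loop runs in C++.

Action potentials are stereotyped templates (half-sine rise to
`spike_peak`, half-cosine fall to the reset `V_r`) pasted when the dynamic
state crosses `V_T`. This makes threshold, amplitude and duration exactly
recoverable quantities rather than emergent ones, which is what the
descriptive spike measurements need. Recording noise is an
Ornstein-Uhlenbeck process (default sd 0.2 mV, correlation time 5 ms)
added to the recorded trace; threshold crossing is evaluated on the
noiseless dynamic state, keeping subthreshold dynamics exactly linear and
spike times deterministic per seed. White noise is avoided because at
20 kHz it would trip the 1 mV/ms spike-detection derivative on every
sample; the OU correlation time mimics the bandwidth of patch-clamp
recording noise.

## Measurement definitions

All windows below are fixed measurement conventions of the package:

* **Input resistance**: (steady-state − baseline voltage)/step current on a
  3 s hyperpolarizing step; baseline = mean over the 200 ms before onset,
  steady state = mean over the last 500 ms of the step.
* **Membrane time constant**: first time the voltage change covers
  $1 - 1/e$ (63.21%) of its steady-state value, linearly interpolated. The
  conventional "~63%" criterion is taken as exactly $1 - 1/e$.
* **Sag ratio**: maximum voltage decrease over steady-state decrease. The
  trough is read from a 25 ms-smoothed copy of the trace: the sag trough
  evolves on the resonance-current timescale (tens of ms), so smoothing
  changes the noiseless value by < 0.3% while removing the extreme-value
  bias that noise adds to a pointwise minimum.
* **Rheobase**: ramp current at the first detected spike
  (slope × time from onset) on a 50 pA/s, 3 s ramp; no spike returns `NA`.
  Low-resistance cells (~60 MOhm) may genuinely not reach threshold within
  the 150 pA this protocol delivers; the absent marker is the honest
  output.
* **Spike detection**: threshold = first sample in an excursion where the
  centred-difference dV/dt exceeds 1 mV/ms, accepted only if the voltage
  reaches −20 mV within 2 ms (rejecting fast EPSPs that also satisfy the
  derivative criterion); the event peak is the maximum of the whole
  suprathreshold excursion. Amplitude = peak − threshold; duration = width
  at the threshold voltage.
* **Impedance**: $|Z|(f) = |\mathrm{FFT}(V)|/|\mathrm{FFT}(I)|$ over a
  0.5→20 Hz, 20 s linear chirp, 0.5 Hz boxcar-smoothed and reported on
  0.5 Hz bins. The bin width equals the smoothing bandwidth because the
  boxcar deterministically shifts a curved peak by up to ~0.15 Hz —
  claiming the raw 0.05 Hz FFT resolution would overstate accuracy. The
  full-resolution spectrum is kept in `attr(, "raw_spectrum")`. Resonance
  = frequency of the smoothed maximum, ties toward lower frequency; a
  maximum at the band's lower edge flags the cell non-resonant.
* **Evoked responses** (averaged trace, centred 1 ms mean): EPSP amplitude
  = maximal depolarisation from baseline within 500 ms of stimulus onset,
  IPSP amplitude = maximal hyperpolarisation magnitude, with the EPSP peak
  sought before the IPSP trough when both exist. Baseline = mean of the
  490 ms (single pulse) or 990 ms (train) window ending 10 ms before
  onset. Latency = time to a 10% deviation of the governing component's
  own peak (the reference quantity for "10% deviation" is the peak
  amplitude, the standard 10%-rise reading); half-width at 50% of that
  peak; both reported only when the governing amplitude is at least 1 mV.
* **Classification**: suprathreshold if any individual sweep spikes within
  50 ms of the stimulus; otherwise a component "exists" when its amplitude
  reaches `max(0.5 mV, 3 × SE of the averaged baseline)`; both → biphasic,
  one → excitatory/inhibitory, neither → none.
* **E-I ratio**: `EPSP/(EPSP + |IPSP|)`, in [0, 1]. This is the only form
  that lands in the unit interval and matches reported central values
  (~0.56 for stellate, ~0.76 for pyramidal cells).
* **Trains**: per-pulse extrema against the single train-level baseline in
  contiguous windows of 1000/frequency ms (100 ms at 10 Hz, 50 ms at
  20 Hz).
* **Anatomy**: volumetric puncta density = count/volume (mm^-3) in
  half-open boxes; per-layer densities from 150 um-wide extracts (centred
  mediolaterally by default); mediolateral profile in six 150 um bins from
  the parasubiculum border; intensity profiles min-max normalised after
  baseline-ROI subtraction.

## The synthetic cohort

Synapses are injected as difference-of-exponentials *current* kernels,
numerically calibrated per cell so that each component alone produces
exactly the specified somatic peak. Current kernels (rather than
conductances) are used because the quantities of interest are somatic PSP
amplitudes, and calibrated kernels give exact ground truth for recovery
testing. Defaults: AMPA-like EPSP rise 1/decay 10 ms; GABA_A-like IPSP
rise 2/decay 15 ms, latency 1.5 ms after the EPSP (disynaptic feedforward
path); GABA_B-like IPSP rise 50/decay 200 ms, latency +5 ms. The slow
kinetics are plausible placeholders — the recorded slow-IPSP time constants
are not published — so recovery tests score against the generator's own
ground truth, never against assumed literature values.

Cohort composition mirrors the recorded study design: 90 stellate cells
(58 biphasic / 27 excitatory / 5 inhibitory) and 37 pyramidal cells
(21 biphasic / 16 excitatory), allocated deterministically by largest
remainder so empirical counts equal the configuration exactly. E-I ratios
for biphasic cells are Beta draws with mean 0.558 (concentration 10) for
stellate and 0.759 (concentration 14) for pyramidal cells, matching the
reported medians and interquartile ranges; draws are clipped to
[0.10, 0.88] and component amplitudes floored at 1 mV so that ground-truth
class labels remain consistent with the 0.5 mV detection criterion.
EPSP amplitudes are lognormal (median 3 mV stellate, 5 mV pyramidal —
pyramidal excitation is larger, as reported). Membranes: stellate
C = 200 pF, g_L = 12 nS, a = 5 nS, tau_w = 100 ms (input resistance
~60 MOhm, sag ratio ~1.2-1.3, resonance ~4 Hz); pyramidal C = 150 pF,
g_L = 6 nS, a = 1 nS (weakly resonant, higher input resistance); 12%
lognormal jitter on all four parameters. Positions are uniform over
0-900 um mediolaterally and 2.8-4.2 mm ventral to bregma, independent of
response properties — so the position regressions are null by
construction, as reported. Ten repeat sweeps per stimulus are simulated
(within the reported 10-30), which keeps the averaged-trace noise floor
well under the 0.5 mV detection criterion at 0.2 mV recording noise.

During trains, excitation is flat, fast inhibition scales linearly from 1
to a per-cell growth factor (uniform on [1.0, 2.5] for stellate,
[0.9, 1.1] for pyramidal cells), and the slow component *saturates*: after
the first pulse its increments are damped by
$1 - e^{-\Delta/\tau_{decay}}$ (with $\Delta$ the inter-pulse interval) so
the accumulated slow level holds near the single-pulse amplitude. This
emulates metabotropic receptor saturation; without it, linear summation of
a 200 ms kernel at 10 Hz grows ~2.5-fold and drives every cell's pulse-10
E-I to zero, which contradicts the observed structure (pyramidal E-I
stable across the train; stellate E-I drops and broadens).

Pharmacological conditions are represented as kernel removals:
`gabazine` removes the fast IPSP, `cgp` the slow IPSP, `nbqx_apv` and
`ttx` everything (inhibition is disynaptic, so glutamatergic block removes
it too), and `ttx_4ap` restores the monosynaptic EPSP only.

Puncta fields are homogeneous Poisson processes per layer-slab ×
mediolateral-bin cell. Default rates put 4790 mm^-3 in layer 1 (the
reported value) with low rates in L3/L5a and moderately elevated L2/L5b,
modulated by a decreasing mediolateral gradient; the imaged depth defaults
to the full 400 um slice so that 150 um extracts contain enough puncta for
stable per-slice densities at these rates. Intensity profiles are Gaussian
bumps over a flat baseline with additive noise, clipped to 8-bit gray.

### What the generator does not emulate

Dendritic filtering and multicompartment morphology (latencies of deep
cells are drawn, not propagated), conductance-based synaptic reversal
effects (no driving-force saturation near the GABA reversal), network
interactions among interneurons, electrode/series-resistance artefacts,
and image segmentation (puncta enter as point tables; the manual per-ROI
thresholding of raw stacks is not reproducible). Passing recovery tests
therefore demonstrates correctness of the measurement chain on data whose
generative assumptions are known, not robustness to every failure mode of
real recordings.

## The statistical battery

All tests are implemented from first principles and return effect sizes:

* **Friedman** with mid-ranks and the standard tie correction; Kendall's
  $W = \chi^2 / (N(k-1))$ (untied form, matching the convention that
  reproduces published chi-square/effect-size pairs; a tie-corrected
  variant is available via `tie_corrected_w = TRUE`).
* **Wilcoxon signed-rank**: zero differences dropped, mid-ranks on ties;
  exact two-sided p for $n \le 25$ via the generating-function
  distribution over all $2^n$ sign assignments (identical to brute-force
  enumeration, verified in tests); beyond that a tie-corrected normal
  approximation with continuity correction.
* **Mann-Whitney U** (rank-sum form `U = R1 - n1(n1+1)/2`): exact for
  $n_1 n_2 \le 400$ by dynamic programming over all labelings (valid with
  ties); tie-corrected normal approximation otherwise.
* **Kruskal-Wallis** with tie correction and
  $\eta^2 = (H - k + 1)/(n - k)$; **Dunn** post-hocs on pooled mean ranks
  with tie-corrected SEs and Bonferroni over all $k(k-1)/2$ pairs.
* **Two-sample Kolmogorov-Smirnov**: exact p by lattice-path counting
  (ties traversed freely, deviations checked at distinct values) for
  $n_1 n_2 \le 400$, else the asymptotic Kolmogorov distribution.
* **Simple linear regression** in closed form with the overall F-test on
  $(1, n-2)$ df; exact fits report `F = Inf`, `p = 0`.
* **Bonferroni**: `min(1, m p)`.

Two-sided exact p-values are `2 × min(lower tail, upper tail)` capped at
1, which coincides with the standard convention on tie-free data (verified
against the reference implementations to 1e-9 in the suite). Null
calibration is checked at moderate sizes (n = 25 pairs, 14 + 14, 3 × 15,
25 × 3, n = 30 regression) where discreteness of the exact distributions
keeps achievable levels within about a point of 5%.

## Numerical choices and degenerate inputs

Sweep files are tab-delimited text with a key=value sidecar; the time
column must be uniform to 1e-6 relative tolerance. FFT lengths are trimmed
to the nearest 2-3-5-smooth integer (a 20 s sweep at 20 kHz is 400001
samples — a near-prime length would make the FFT quadratic). Constant
profiles are a degeneracy error for min-max normalisation; all-zero
differences are a degeneracy error for the signed-rank test; empty groups,
zero-volume ROIs and missing manifest columns raise named errors.
Impedance ties break toward the lower frequency. Cohort mixture weights
must sum to 1 within 1e-9. All generators are pure functions of
(arguments, seed); per-cell seeds are derived as
`(seed + 104729 * index) mod (2^31 - 1)`.

## Problem sizes

The bundled analyses use the full 127-cell cohort for single-pulse
measurements, 10 biphasic cells per class for trains, 6-8 cells per class
for the intrinsic battery, 11 synthetic slices for the anatomy battery,
and 2000 replicates for null-calibration checks; the complete pipeline
(`run_experiment()` with defaults) runs in well under a minute on one
core. Larger cohorts only change runtime linearly.

## Known limitations

* The E-I ratio is computed from amplitudes measured on the same averaged
  trace, so temporal overlap of excitation and inhibition biases both
  components downward (and the ratio slightly toward excitation) relative
  to the generative component amplitudes; the recovery report quantifies
  this.
* Resonance frequency is ill-conditioned for weakly resonant cells (flat
  spectra near the band edge); such cells are flagged rather than forced.
* Exact-test cutoffs (n = 25; n1 n2 = 400) are computational choices;
  beyond them p-values are asymptotic with continuity and tie corrections.
* The paper-style protocols are fixed (3 s steps, 50 pA/s ramps, 3 ms
  light pulses); cells whose rheobase exceeds the ramp's 150 pA ceiling
  return an absent rheobase.
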
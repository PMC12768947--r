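---
title: "Methods: simulation, networks, and quantification in sersmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, networks, and quantification in sersmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sersmix` analyses multiplexed SERS spectra of five PAH pollutants (PY, TP,
NP, BAP, ANT) in water: a classifier decides which targets are present and
a regressor quantifies them. This vignette is the package's account of the
science behind each stage — the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Spectra and preprocessing

All spectra live on one uniform wavenumber grid. The spectral dimension is
fixed at w = 660 points; the range, 400–2000 cm⁻¹, is a package choice that
brackets every band the simulator uses (the PY marker at 1241 cm⁻¹, the
shared PY/NP/ANT structure near 1240 and 1400 cm⁻¹, and everything else in
the reference tables) with margin on both sides. Both are configurable
through `wavenumber_grid()`.

Preprocessing is the standard chain for dispersive Raman data:

1. **Savitzky–Golay smoothing** (`sg_smooth`, window 5, degree 3): light
   local-polynomial smoothing. Edges are handled by the in-window
   polynomial fit — no padding or wraparound — so polynomials up to the
   filter degree are exact fixed points end to end, and the filter is
   linear.
2. **Baseline subtraction** (`subtract_baseline`, degree 1): the baseline
   is estimated by a linear Savitzky–Golay filter and subtracted
   pointwise. The baseline window defaults to about one third of the
   spectrum (219 points ≈ 530 cm⁻¹): a linear filter over a window much
   wider than any Raman band (bands here have 12 cm⁻¹ FWHM) tracks the
   broad background while passing narrow peaks nearly unchanged. A
   five-point window — the span used for the *smoothing* step — would
   subtract the peaks themselves, which is why the baseline span is a
   separate parameter and deliberately wide.
3. **Unit-max normalization** (`max_normalize`): the network input scale.
   The raw maximum is retained as metadata; it is the quantity the
   quantification chain multiplies back in, so normalize ∘ denormalize is
   the identity.

## The synthetic reference library

No measured spectra ship with the package; the reference library is a
synthetic stand-in, and every file that persists it is labelled as such.
Bands are **Lorentzian** (the natural line shape for Raman transitions)
with a common default FWHM of 12 cm⁻¹. The five band tables are package
conventions constrained by the qualitative structure of the real spectra:

* PY's dominant band sits at 1241 cm⁻¹ (ring C=C stretch);
* ANT has exactly three resolvable bands and the weakest response;
* BAP has eight;
* NP has *no unique bands*: every NP center lies within one FWHM of some
  other target's center, which is what makes NP the hardest target to call
  without multivariate analysis;
* PY, NP and ANT each have a band within 10 cm⁻¹ of both 1240 and
  1400 cm⁻¹.

These audit rules are asserted by the test suite, along with a pairwise
cosine-similarity bound (< 0.95) guaranteeing the library is actually
distinguishable. Exact centers other than PY's are conventions, not
reconstructions.

**Concentration response.** Peak height follows a Hill/Langmuir form
h(c) = h_max · c / (K + c): zero at zero, strictly increasing, saturating —
the qualitative shape of SERS adsorption isotherms — and closed-form
invertible, which a free polynomial fit is not outside its data range. The
default K = 0.35 μM places the 10 nM–1 μM calibration range at roughly
3–74% of saturation; h_max is per-target (0.5 for ANT, mirroring its weak
signal, up to 1.0 for PY).

**Backgrounds.** The water blank is a smooth low-order polynomial hump
scaled to 10% of unit reference height, in two presets: drinking (tap)
water, and river water (broader, with a stronger low-wavenumber rise) used
only in test-set generation.

## The mixture simulator and its labels

Training spectra are fabricated by scaled addition:
M = Σᵢ aᵢ·Rᵢ + blank + noise, with aᵢ = ℓᵢ·S. Per sample:

* each target's contribution is independently **zeroed with probability
  0.2**; survivors get positive fractions ℓᵢ normalized to Σℓᵢ = 1 and
  redrawn until each is **at least 1% of total signal** (samples with all
  five zeroed are kept as blank-class negatives);
* the total-signal scale S is drawn log-uniformly over two decades
  (0.1–10 in unit-reference height) so the models see varied
  signal-to-background ratios — the scaling distribution is a package
  choice;
* the spectrum is shifted by an integer offset uniform in ±2 grid points
  (edge-value extension) and Gaussian noise of sd 1% of the spectrum
  maximum is added; both magnitudes are package choices exposed in
  `noise_config()`;
* the sample is stored unit-max-normalized together with its 6-number
  regression label (ℓ₁…ℓ₅, z) and 5-bit presence label.

**The normalization factor z** is defined as z = max(M)/S, so that
(ℓᵢ / z) · max(M) = aᵢ identically: dividing a predicted contribution by z
and scaling by the raw maximum of the test spectrum recovers that target's
absolute signal height, which is what the calibration curve inverts. This
is the one definition under which the conversion chain is exact on
noiseless self-consistent labels, and the quantification round-trip test
asserts precisely that. For all-blank samples z is set to 1 by convention
(any value is consistent when every ℓᵢ = 0).

Dataset sizes default to train 10,000, validation 2,000, optimization
6,000. Everything is reproducible bit-for-bit from the seed.

## The networks

Both heads share one backbone: three conv–ReLU–maxpool blocks
(16/32/64 filters, kernel 9, pool 2, 'valid' convolution), one dense layer
(64 units, dropout 0.2), then either 5 independent sigmoids (multilabel
presence; binary cross-entropy) or 6 unconstrained outputs (ℓ̂₁…ℓ̂₅, ẑ;
mean squared error). The regressor head is deliberately unconstrained —
non-negativity is enforced downstream at concentration conversion, not in
the network.

No deep-learning framework is used: convolution and pooling are
implemented as compiled kernels (a valid 1D convolution decomposes into
`kernel` shifted BLAS matrix products in the sample-fastest batch layout),
with backpropagation verified against numerical gradients in the test
suite. Training is minibatch Adam (learning rate 10⁻³, batch 64) with
early stopping: the weights returned are those of the best validation
epoch, never worse — an explicit contract the tests assert. Defaults are
max 10 epochs with patience 8; on the default synthetic problem both
models converge well before that (the full simulate–train–evaluate
benchmark runs in roughly ten minutes on one CPU), and all stages are
seeded so repeated runs agree to numerical tolerance.

The architecture values are package defaults, overridable via
`cnn_architecture()`; `search_architecture()` provides a seeded random
search over a bounded space, trained briefly on an 80/20 split of the
optimization set, for re-tuning.

## Decisions and quantification

* **Thresholds** are fitted per target on *validation* scores only, never
  on test data, by maximizing the geometric mean √(sensitivity ·
  specificity) over candidate cutoffs at midpoints between adjacent sorted
  unique scores (plus the all-positive and all-negative extremes, so every
  achievable classification is reachable). A score exactly equal to the
  threshold counts as positive; ties in the geometric mean resolve to the
  lowest threshold. The implementation is oracle-checked against
  exhaustive search.
* **Calibration** defaults to the Hill form; a `poly_log` form (quadratic
  in log₁₀ c) is provided for a literal polynomial calibration and is
  accepted only if strictly increasing over the data range, because an
  unconstrained polynomial need not be invertible. Inverse round-trips are
  exact to 10⁻⁶ relative within the calibrated range.
* **LOD** is the smallest concentration whose predicted height reaches
  S/N · σ_blank, with S/N defaulting to 3.5; it is flagged when it falls
  below the calibrated range and is monotone in both σ_blank and S/N.
* **Conversion** computes hᵢ = max(ℓ̂ᵢ, 0)/ẑ · max(M) and inverts the
  target's curve, with a hard floor of 0 (sub-blank heights report zero)
  and an extrapolation flag above the calibrated range; heights at or
  beyond the Hill saturation are capped at 100× the calibrated maximum
  rather than diverging. Predicted ẑ at or below 10⁻⁶ is a
  degenerate-normalization error, never silently patched.

## Evaluation

Per-target 2×2 confusion matrices feed precision, sensitivity,
specificity, NPV and F1. Zero-denominator metrics are reported as `NA` and
*excluded* from macro averages with a warning — coercing them to 0 or 1
silently biases small test sets. Micro averages are metrics of the pooled
count matrix. ROC uses the same score ≥ threshold convention as
classification; AUC is trapezoidal and equals the normalized Mann–Whitney
U statistic, which the tests assert on random instances. Because "accuracy"
is ambiguous for multilabel calls, both subset accuracy (all five calls
correct per sample) and pooled per-call accuracy are reported.

RMSE_spectrum compares max-normalized spectra (the scale the networks
operate on, so the value is dimensionless and comparable across samples);
predicted spectra are reconstructed as Σ (ℓ̂ᵢ/ẑ)·max(M)·Rᵢ from the
reference library — without the blank, so background mismatch appears in
the spectral residual by design. RMSE_conc is in μM over the n × 5
concentration matrix.

## The benchmark

Four synthetic test sets mirror a realistic evaluation design: {drinking,
river} backgrounds × {full mixtures of all five targets at concentrations
uniform in 0.1–0.5 μM, sparse mixtures of exactly 2 of 5 targets at
0.5 μM each}, with 10/10/10/9 samples (39 total). Test spectra are
simulated through the *response model* (concentration → height), not the
training-label path, so the regressor is genuinely inverting the forward
model. At default sizes the trained classifier reaches micro-F1 above 0.9
and the regressor concentration RMSE well under 0.15 μM; the acceptance
tests run exactly this benchmark.

## What the simulator does and does not emulate

The generator reproduces the *structure* of the problem: overlapping
bands, shared NP structure, saturating responses, varied
signal-to-background, wavenumber jitter, blank-only negatives. It does not
emulate instrument artifacts (cosmic rays, detector etalonning),
matrix-dependent enhancement chemistry, inter-batch substrate variability,
or non-additive spectral interactions between co-adsorbed analytes.
Passing the benchmark therefore demonstrates that the pipeline is correct
and well-conditioned on data matching its generative assumptions — it does
not certify performance on measured spectra, which is why the synthetic
library is labelled a stand-in throughout.

## A note on permutation null controls

A standard sanity check for any learning pipeline is to retrain on
label-shuffled data and confirm that performance collapses. Here the
collapse must be measured against the right baseline. With the 20%
zeroing rule, presence labels are ~80% positive, so binary cross-entropy
drives the null model's mean logit positive; the network realises that
positive mean through nonnegative ReLU features whose magnitude tracks
overall spectral richness — and richness correlates with how many targets
are truly present. A permutation-null classifier therefore scores
true-label test AUC visibly above 0.5 *without having learned any
target-specific association*, while an untrained network sits at chance
(the test suite asserts the latter, and balancing the null's label
prevalence removes the effect). The chance baseline that is well-defined
under class imbalance is the prevalence-determined F1 of the all-positive
call, 2p/(1+p) ≈ 0.89 at p = 0.8, and the test suite asserts that
shuffled-label training lands on that baseline. The gap between the
permutation null and the genuinely trained classifier is what
demonstrates that the reported performance is signal-driven.

## Numerical notes and limitations

* Degenerate inputs fail loudly: all-nonpositive spectra cannot be
  normalized, single-class truth vectors cannot be thresholded or ROC'd,
  an all-zero mixture over a zero blank cannot be composed.
* Repeat-run equality of training is asserted at 10⁻⁴ relative tolerance
  (identical in practice on one BLAS, but bitwise equality across numeric
  backends is not promised).
* Concentration uncertainty is out of scope — the pipeline reports point
  estimates only.
* The classifier and regressor are trained independently; no weight
  sharing or joint loss weighting between the contribution outputs and ẑ
  is attempted.
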
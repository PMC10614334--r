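---
title: "Methods: the eegtrio recognition pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eegtrio recognition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtrio)
```

## The problem and the model

`eegtrio` implements a binary emotion-recognition pipeline for multichannel
EEG: trials labeled by a dichotomised affective dimension (valence or
arousal) are band-pass filtered, summarised by four feature families, and
classified by an ensemble of three small neural models whose readout layers
are tuned by a population metaheuristic rather than by gradient descent.
The design premise is that the discriminative information lives in the
spectral composition of each trial, so the classifiers can stay small and
the search space for the optimizer desk-scale.

## Preprocessing

The band-pass filter is an order-4 Butterworth applied forward-backward
(`signal::filtfilt`), with a default 0.5–50 Hz passband at any sampling
rate (128 Hz default, mirroring common down-sampled affective datasets).
The source method states only that a band-pass filter is used; the family,
order, and band are this package's choices, standard in EEG practice. Zero
phase matters because several features (DWT statistics, entropy of the
amplitude distribution) are sensitive to waveform shape, and a causal IIR
pass would distort it with frequency-dependent delay. Per pass the
magnitude response is exactly −3 dB at the band edges; the
forward-backward application squares the response, which only deepens the
attenuation. Filtering is linear to machine precision, which the test
suite asserts at a 1e-9 relative tolerance.

Segmentation cuts consecutive trials of `trial_len_s` seconds and discards
a `baseline_s` pre-trial baseline (60 s trials with a 3 s baseline
reproduce the layout of the standard affective dataset: 7680 retained
samples per trial at 128 Hz). Sample identity is conserved — epochs plus
the discarded baselines tile the consumed recording exactly.

Recordings with non-finite samples are rejected at load with the offending
cell named; silent imputation felt more dangerous than an explicit error.
EDF input is not provided in this build (no EDF reader is available to the
package); delimited text and an RDS array container cover the practical
cases.

## Feature families

Per channel and per trial, in fixed order:

1. **DWT sub-band statistics.** A periodized orthogonal Mallat pyramid
   (Daubechies-4 by default, 4 levels at 128 Hz so the detail bands
   approximate gamma/beta/alpha/theta with a delta approximation band),
   with mean, standard deviation, energy, and mean absolute value per
   sub-band. The transform is orthonormal: coefficient energy equals
   signal energy and reconstruction is exact, both asserted at 1e-8. The
   periodized form requires the signal length to be divisible by
   `2^levels`; the decomposition errors otherwise rather than silently
   padding. The statistic set is a package choice — the source method
   does not name one.
2. **Band powers.** Welch's averaged periodogram (Hann window, 2 s
   segments, 50 % overlap) integrated over delta (0.5–4), theta (4–8),
   alpha (8–12), beta (12–30), and gamma (30–100 Hz, capped at Nyquist —
   30–64 Hz at 128 Hz, since the printed upper edge exceeds what the
   sampling rate supports).
3. **Spectral flatness.** Geometric over arithmetic mean of the
   positive-frequency magnitude bins of the whole epoch, epsilon-guarded;
   1 for a flat spectrum, 0 for the all-zero signal by convention. Note a
   statistical subtlety: for white noise the raw-periodogram magnitude
   bins are Rayleigh distributed, so the *expected* flatness is
   `exp(-γ/2)/(√π/2) ≈ 0.845`, not 1 — flatness approaches 1 only for
   spectra that are flat after averaging. The test suite pins the
   simulated white-noise mean to that closed form.
4. **Improved entropy.** Amplitudes are binned into `b = 8` equal-width
   histogram bins over `[min, max]`; with `pos`/`neg` the global counts of
   positive/negative samples and `P(pos|y_i)` the positive fraction in bin
   `i`, the value is

   `Σ_i P(pos|y_i) · (neg/pos) · log2(|ln(P(neg|y_i) · pos/neg + ε)| + ε) / wei_i`,

   with `wei_i` the iterates of the Bernoulli doubling map
   `w ← 2w mod 1` from seed `w0 = 0.7` (floored at ε) and empty bins
   contributing zero. Three numerical decisions are baked in and
   documented here because the printed formula is not well defined as
   stated: the inner logarithm's argument can lie in (0,1), where a
   second logarithm of a negative number would be complex, so the guard
   `log2(|ln(z + ε)| + ε)` with `ε = 1e-12` keeps the double-log shape
   real; the per-bin weight is applied inside the sum (the only reading
   in which its index is meaningful); and "positive/negative" is
   interpreted as the sign of the (zero-mean, filtered) samples — the
   natural binary attribute the signal offers. Signals of a single sign
   are rejected with a pointer to mean-centering. The value is homogeneous
   of degree −1 in the weights and exactly invariant under negation of a
   sign-symmetric sample multiset; both are tested. The conventional
   Shannon entropy of the same amplitude histogram is available as the
   ablation counterpart (`entropy_mode = "conventional"`).

The dyadic-rational guard on `w0` exists because every coarse dyadic seed
collapses the doubling map to zero in a few iterations, which would make
all weights equal to the floor ε and the entropy numerically explosive.

Feature extraction is deterministic given its configuration; a 4-channel
montage yields 4 × 27 = 108 features per trial with the default statistic
set.

## The tri-classifier ensemble

All three classifiers share the feature vector and emit softmax
probabilities over the two classes; the fused prediction is their
arithmetic mean, with argmax ties broken toward the lower class index
(documented and tested). The readout of each classifier is an affine map
plus softmax — the source gives a softmax only for one of the three, but a
uniform readout is required for the fused probabilities to be comparable.

- **LSTM**: the standard forget/input/output gate recurrence with separate
  input and hidden biases per gate, `A_0 = Y_0 = 0`, reading out from the
  final hidden state. The printed recurrence renames the output gate and
  its parameters mid-derivation; this implementation aliases those to a
  single output-gate parameter set.
- **RNN**: Elman form, `wg_t = tanh(P x_t + Q wg_{t−1})`.
- **DBN**: a stack of two RBMs (32 and 16 hidden units by default)
  pretrained greedily by CD-1 on `[0,1]` min-max-normalised features, then
  read out deterministically (sigmoid mean activations, no sampling at
  inference). The "improved" aspect is the mean-absolute-error
  reconstruction criterion monitored during pretraining
  (`loss_mode = "mae"`); the conventional squared error is the ablation
  switch. Whether that loss participates in or merely monitors CD is not
  specified by the source; here it is a monitoring/selection criterion
  only, which keeps CD untouched.

Feature vectors are folded into 4 time steps (zero-padded) for the
recurrent models — the source treats features as classifier input without
prescribing a sequence structure, and a short fixed fold keeps the forward
pass cheap while giving the recurrences something to iterate over.

The optimizer tunes the three readout layers only (54 weights at hidden
size 8 and a single 8-unit DBN top layer; 70 with the default 16-unit
top layer), flattened in the order LSTM → DBN → RNN, each bounded in
`[-1, 1]`. The source says the classifiers' "weights" are tuned without
saying which; tuning the readouts keeps the search dimension compatible
with a population of 10 and 25 iterations, and the configuration can widen
the encoding if desired. Non-tuned weights are seeded uniform(−0.1, 0.1);
DBN hidden weights come from pretraining.

## SSU-BES

The objective is `1 / max(accuracy, 1e-6)` on the held-out validation
split, so cost 1 is the attainable minimum and 1e6 the zero-accuracy
sentinel (objective errors are absorbed as the same sentinel and the run
continues). Three greedy stages per iteration:

1. **Select** contracts toward the best-ever position.
2. **Search** spirals around neighbours, scaled by `η_k · R1 / ĝ_i`:
   `η_k` anneals linearly 1 → 0.1, `R1` is a circle-map draw
   (`a = 0.5, b = 0.2, x0 = 0.7`, one draw per eagle per use), and `ĝ_i`
   is a secant estimate of the cost gradient,
   `(cost_i^k − cost_i^{k−1}) / (‖Z_i^k − Z_i^{k−1}‖ + ε)`, magnitude
   floored at `ε = 1e-8`. A true derivative of the black-box objective
   does not exist; the secant reuses costs that are already available so
   the estimate costs no extra evaluations.
3. **Swoop** divides a best-anchored numerator element-wise by
   `η_k · R1 · ĝ_i + α_k · R2 · V_i` (inertia `α_k` anneals 0.9 → 0.4,
   `V_i` is the eagle's previous displacement, and the floor is
   sign-preserving) and scales by `sd_w`, the weighted standard deviation
   of the population costs under rank weights (best cost → largest
   weight). The printed weighted-deviation formula lacks the square and
   is identically zero as written; the standard weighted sample standard
   deviation is used instead.

Spiral coefficients are normalised by the population maximum of their
absolute values (an all-zero normaliser yields zero coefficients). The
deterministic arctan/arccos polar angles that the derivation also defines
are available behind `chaotic_polar = TRUE`; whether they replace or
coexist with the random angles is not recoverable from the derivation, so
the random form is the default and the deterministic one a switch.
`it1 = it2 = 2` (the upper end of the customary `[1, 2]` range),
`β = 2`, `Q = 1.5`, all configurable.

Every proposal is clipped to bounds and accepted only on improvement, so
positions never contain non-finite values and the best-cost trace is
monotone — both asserted on every run in the test suite, including under
an adversarial objective that raises errors and returns NaN. Runs are
bit-reproducible given the config seed. Plain BES uses the unmodified
search/swoop updates; an equal-budget uniform random search provides a
superiority floor (the suite checks SSU-BES's 20-seed median final sphere
cost does not exceed random search's).

## Evaluation protocol

`metrics_report()` computes the 11 metrics from a binary confusion matrix
with class 1 positive; 0/0 ratios resolve to 0 by convention (they arise
only for degenerate predictions). The four complement identities hold to
1e-12 by construction, and the bundled published comparison table (seven
classifiers × two affective dimensions) satisfies them to 1e-4 and the
F1/precision/sensitivity harmonic-mean relation to 1e-3 — the resolution
of the printed cells — which is how the package's metric definitions are
validated against the source values without access to the restricted
dataset. Multi-run summaries use the sample (n−1) standard deviation.
`run_ablation()` evaluates the variant grid on one shared split and seed.

## The synthetic generator

`generate_epochs()` plants a spectral class signature the feature set is
provably sensitive to: every trial is unit-variance 1/f noise (spectral
shaping of white Gaussian noise, slope checked by periodogram regression)
plus 10 Hz and 20 Hz oscillations of amplitude 1; class-1 trials scale the
20 Hz amplitude by `1 + effect_size`. At `effect_size = 0` the classes are
identically distributed (no accidental leakage — verified by a location
test on alpha power and by a label-permutation run of the full pipeline);
at the default `effect_size = 2` a single threshold on the beta/alpha
power ratio separates the classes at ≥ 95 %, so end-to-end recovery tests
probe the pipeline rather than the generator. Defaults are 100 trials,
4 channels (desk-scale; 32 channels available to mirror full montages),
128 Hz, and 12 s trials — long enough for six Welch segments and four DWT
levels, short enough that the whole recovery study (10 seeds × two
training arms) runs in well under five minutes on one CPU.

What it does **not** emulate: volume-conduction correlations between
channels, artifacts (ocular, muscular, line transients), non-stationarity
within a trial, and inter-subject variability. Passing recovery tests
therefore demonstrate that the pipeline can extract a planted spectral
contrast, not that it attains any particular accuracy on real recordings.

## Numerical choices and degenerate inputs

- ε-guards: `1e-12` inside logarithms (flatness, improved entropy),
  `1e-8` for gradient and denominator floors (sign-preserving),
  `1e-6` accuracy floor in the objective.
- Histogram bins are left-closed, right-open, except the last (closed).
- Zero-parameter classifiers sit at exact uniform outputs (gates at 0.5,
  zero hidden states) — the fixed point used as a degeneracy test.
- All-zero signals: flatness 0 by convention; band powers 0; the improved
  entropy rejects single-sign input instead of guessing.
- Min-max normalisation spans degenerate (constant) feature columns with
  a unit denominator; validation data are clipped into `[0, 1]`.
- Stratified 70/30 split, seed-fixed; one global seed fans out to
  per-stage seeds through a fixed integer hash so stage reordering cannot
  silently couple RNG streams.

## Problem sizes in the checks

The acceptance-level checks use the 5-dimensional sphere benchmark
(population 20, 200 iterations, 20 seeds), 100 random inputs per oracle
comparison at 1e-9, and the 100-trial/4-channel recovery study over
10 seeds — sizes chosen so the entire suite completes in about a minute
and a half on a single CPU while keeping the Monte-Carlo assertions
stable.

## Known limitations

- The improved-entropy formula is this package's guarded reading of an
  inconsistently printed definition; other readings are defensible and
  would change feature values (not the pipeline's structure).
- Readout-only tuning is the default encoding; widening to recurrent/RBM
  weights grows the search dimension far beyond what a population of 10
  explores usefully.
- The optimizer maximises accuracy *on the validation split*; with small
  validation sets the reported validation accuracy is an optimistically
  biased estimate of generalisation, which is the main reason the
  label-permutation check matters.
- No artifact rejection, re-referencing, channel selection, or
  connectivity features — out of scope by design.
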
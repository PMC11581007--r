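---
title: "Methods: from network encoding models to tuning subspaces"
author: "tunespace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from network encoding models to tuning subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tunespace)
```

## The problem

Auditory cortical neurons respond to nonlinear combinations of
spectro-temporal sound features. Network encoding models (here, a causal
population convolutional network driven by a gammatone log-energy
spectrogram) predict time-varying firing well, but their parameters are
hard to interpret. This package implements a pipeline that converts a
fitted nonlinear model into an interpretable *tuning subspace*: a small set
of orthonormal spectro-temporal filters such that the neuron's response is
(approximately) a function only of the stimulus projections onto those
filters, together with descriptors of the nonlinear tuning within that
subspace.

The chain is:

1. **Frontend** — waveform to F x T log-energy spectrogram `s(f, t)`
   (gammatone filterbank, envelope extraction, 10-ms frames, log
   compression).
2. **Encoding model** — LN (rank-1 FIR filter bank, per-neuron weights,
   double-exponential output) or population CNN (two causal conv layers,
   two dense layers, ReLU, per-neuron double-exponential output), fitted
   with Adam under a two-stage schedule, 8-fold jackknifing and multiple
   seeded initializations.
3. **dSTRF** — at each stimulus frame t, the locally linear filter
   `d_t(f, u) = dr(t) / ds(f, t-u)`, computed as the exact Jacobian of the
   fitted model by analytic backpropagation (a central finite-difference
   oracle cross-checks it), then shrinkage-averaged across jackknife
   members.
4. **Subspace** — uncentered PCA of the T x (F*U) dSTRF collection; the
   smallest number of components reaching 90% cumulative variance defines
   the tuning subspace. The stimulus is projected into the subspace and a
   compact readout (dense two-layer network, or first/second-order
   polynomial) is refit on the projections alone.
5. **Metrics** — tuning surfaces and marginal curves, tuning symmetry index
   (TSI), subspace similarity index (SSI), modulation power spectra,
   response-field tiling with a shuffle control, noise-corrected prediction
   correlation, spike-width classification.

## Model definitions and conventions

**Double-exponential output.** `r = b + a*exp(-exp(-k*(x - s)))` with
baseline `b`, amplitude `a`, threshold `s` and gain `k`. The printed form of
this nonlinearity is typographically ambiguous about the inner sign; we
adopt the Gompertz convention (increasing in `x` for `k > 0`), which is the
standard in this model family. The inner exponent is clamped to
`[-700, 30]` purely to avoid floating-point overflow; the clamp is
unreachable in any fitted operating range.

**Causality.** All convolutions are causal with zero left-padding: the
output at frame t depends only on frames `<= t`. The CNN's temporal
footprint is `K1 + K2 - 1` frames (24 at the default 15 + 10 taps); the
dSTRF lag window is nevertheless fixed at U = 25 frames (250 ms at 100 Hz)
and the final column is verified to be zero.

**Rank-1 filter bank.** LN filters are stored as spectral x temporal
profile pairs and only materialized on demand; this makes the rank-1
structure a testable invariant rather than a convention.

**Normalization.** Before fitting, stimulus channels and response rates are
min-max normalized to [0, 1]; the affine maps are derived from the fit data
only, stored in the fitted model, and reused for validation data and for
putting dSTRFs back into physical units (rate per log-energy unit). A
constant channel maps to zero. Downstream analysis (projections, tuning
surfaces) uses the same spectrogram the model saw.

## Fitting protocol and numerical choices

* Loss: mean squared error over all neurons simultaneously, plus L2 on the
  linear weights only (never biases or output-nonlinearity parameters);
  `l2Strength` defaults to 1e-4 in normalized units (no coefficient is
  prescribed by the model family; this value leaves noiseless recoveries
  unbiased at desk scale).
* Two stages: stage 1 replaces the output nonlinearity with a per-neuron
  level shift (learning rate 0.01, tolerance 1e-3); stage 2 restores the
  double exponential, initialized at `(b, a, s, k) = (mean rate, rate
  range, 0, 1)`, and continues from the stage-1 linear parameters (learning
  rate 1e-3, tolerance 1e-4).
* Stopping semantics: the tolerances are interpreted as *relative
  improvement of the running-best fold-validation loss over a patience
  window*. The window defaults to 100 epochs. Symmetric-response targets
  (e.g. quadrature-energy neurons) put full-batch Adam on a long plateau
  before the symmetry is broken through the ReLU layers; a short window
  stops inside that plateau and strands the fit at the constant predictor,
  which is why the window is this wide. The optimizer keeps the
  best-validation parameters seen, so overshooting the plateau is harmless.
* Jackknife: the timeline is cut into `nJackknife` contiguous blocks (not
  interleaved bins, to respect temporal correlation); fold i excludes block
  i, which doubles as that fold's validation set for early stopping and for
  choosing the best of `nInits` seeded initializations.
* Every random draw flows from one master seed through named substreams
  (`fold3-init2`, `poisson`, ...), so stages are independently reproducible.
* Polynomial readouts (orders 1 and 2) are linear in their coefficients;
  they are fitted fold-wise by penalized least squares — the exact minimizer
  of the same MSE + L2 objective the gradient path would approach — rather
  than by iterating Adam.

## dSTRF and subspace choices

* The Jacobian includes the stored normalization affines, so dSTRFs are in
  physical units and directly comparable across neurons.
* Lags that would reach before stimulus onset are set to zero, matching the
  finite-difference convention.
* Shrinkage across jackknife estimates: per coefficient,
  `m * max(0, 1 - (se/|m|)^2)` with `m` the member mean and `se` its
  standard error; a coefficient is zeroed when its standard error reaches
  its magnitude. This is the simplest variance-penalized shrinkage
  consistent with attenuating jackknife noise; it never flips a sign and
  never increases a magnitude, and is exposed as a strategy option.
* PCA is *uncentered* (SVD of the raw T x (F*U) stack): the subspace then
  contains the mean dSTRF, which carries the LN-like component needed for
  prediction. Centered PCA is available as an option. Component signs are
  fixed by making each component's largest-magnitude coefficient positive;
  all downstream metrics (SSI via absolute correlations, TSI from binned
  data) are invariant to this arbitrary choice.
* The dimension rule is the smallest N whose cumulative explained variance
  reaches the threshold (inclusive), threshold default 0.90.
* Dense readout hidden widths are not prescribed by the two-layer
  definition; (30, 20) with ReLU and a double-exponential output are the
  defaults here.
* Tuning surfaces use a 25 x 25 grid spanning the central 99% of each
  projection with a minimum occupancy of 5 samples per bin; marginal
  curves for the symmetry index use 20 bins. Whether surfaces are built
  from actual or predicted rate is the caller's choice and is logged, as
  both are legitimate uses.

## Metric conventions

* **SSI** sums *absolute* Pearson correlations between flattened filters,
  normalized by the smaller filter count (default cap 4 filters per
  neuron, with the 80%-variance selection available as an option). Raw
  signed correlations would make the index depend on the arbitrary PCA
  sign convention and break its [0, 1] anchoring.
* **TSI** uses adjacent-bin derivatives of the binned curve; the derivative
  at a bin midpoint exactly at zero counts toward the positive side (the
  tie only matters for monotone curves, where both branches agree).
* **Noise-corrected prediction correlation** normalizes
  `cov(prediction, PSTH)` by the signal power estimated from
  trial-to-trial covariance, `SP = (var(sum_i R_i) - sum_i var(R_i)) /
  (M(M-1))`; the estimate is clipped to [-1, 1], and with a noiseless
  raster it reduces exactly to the plain Pearson correlation (also exposed
  directly). No specific correction formula is prescribed by the framework
  this implements; this signal-power estimator is the standard choice.
* **Tiling shuffle** translates each response field toroidally by a seeded
  random offset, preserving its shape and area exactly.
* **Spike width**: narrow iff strictly below threshold (0.35 ms or
  0.375 ms depending on probe filtering); a width exactly at threshold is
  regular.

## Frontend choices

* Gammatone filters are realized in the frequency domain via the analytic
  gammatone response `(1 + i(f - fc)/b)^(-n)` (equivalent to n cascaded
  second-order sections, default n = 2), with `b` set so the equivalent
  rectangular bandwidth equals ERB(fc). Envelopes are the magnitude of the
  analytic output, averaged over non-overlapping 10-ms frames, then
  log-compressed as `log(x + 1e-4)` (the floor, 1e-4 of full scale, keeps
  digital silence finite; no floor is prescribed).
* The ERB law is configurable as `a*(b*f/1000 + 1)`; the default is the
  standard human law (24.7, 4.37). A species-specific ferret law exists but
  its printed form is corrupted in the source material, so the human law is
  the fallback and the coefficients are exposed.
* Excitation patterns multiply the segment power spectrum with half-cosine
  filters evenly spaced on the ERB-rate axis (32 filters, each spanning two
  center spacings), then compress with exponent 0.3. Correlations between
  patterns are invariant to overall segment gain.
* Sequence assembly: each segment contributes its nominal duration; the
  10-ms crossfade consumes the raw margin, using complementary
  raised-cosine ramps that sum to exactly 1 at every overlap sample. Level
  roving draws gains uniformly on [-10, +10] dB (the 20-dB range read as
  symmetric). The category cap rejects a candidate whose category already
  accounts for >= 20% of the accepted set.

## What the synthetic generator emulates — and what it does not

`generateStimulus()` produces 32-channel spectrogram surrogates (smoothed
Gaussian noise, ripple mixtures, or concatenated heterogeneous blocks with
level roving that mimic the natural-segment sequence design).
`simulatePopulation()` drives ground-truth neurons — linear, quadrature-
energy, gain-control (suppression `exp(-beta*x2^2)`, beta = 4 in
standardized projection units), and and-gate — through a double-exponential
nonlinearity (default `b=0, a=1, s=0.5, k=2`, peak rate 50 spikes/s) and
draws Poisson spike counts per 10-ms bin and trial. A neuron's projections
share a single standardization scale so quadrature pairs remain circular
(phase invariance is exact for matched ripples). Quadrature pairs are built
by a 90-degree carrier phase shift of a Gabor ripple.

These surrogates have controllable second-order statistics but lack the
heavy-tailed, harmonic, and cross-channel comodulation structure of natural
sound, and the Poisson noise ignores refractoriness and trial-to-trial gain
drift. Passing recovery tests on them demonstrates that the estimator
chain is correct and self-consistent — not that real cortical data meet its
assumptions.

## Problem sizes

The generator's default dataset (2 minutes of fit stimulus at 100 Hz,
1,200 validation frames, 8 neurons, 10 trials) reflects the study design it
emulates. The test suite and the recovery experiments run smaller
configurations chosen as this package's own desk-scale defaults — typically
2,500-4,000 frames, 2 jackknife folds, 1-2 initializations, and conv/dense
widths of 8-20 channels. At these lengths the Poisson PSTH's noise floor,
not the estimator, dominates subspace recovery error, so the recovery
experiments fit the network to the noiseless ground-truth rates (recovery
of the generative subspace is then a property of the estimator chain), and
the tuning-curve statistics are computed from the Poisson PSTH at the
generator's default 10 trials, where binned means average the trial noise
out. Recovery quality at these scales is reported by the tests themselves.

## Known limitations

* Full-batch Adam is simple and deterministic but slow on plateaus;
  minibatching is deliberately not used to keep runs bit-reproducible.
* The dSTRF is a first-order expansion; strongly non-smooth response
  regions (deep ReLU saturation) are represented only by their local slope.
* Uncentered PCA mixes the mean dSTRF into the leading component; when the
  mean is large relative to the fluctuations, component 1 is close to the
  mean filter rather than the direction of greatest variation (this is the
  intended trade-off; see above).
* The and-gate ground truth is not smooth at `x1 = x2`, so its recovered
  subspace is well-defined but its tuning surface has a ridge that binned
  means blur.
* Model bundles store full-precision doubles in JSON; round trips reproduce
  predictions to better than 1e-6 (the documented contract) but are not
  guaranteed bit-identical.
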
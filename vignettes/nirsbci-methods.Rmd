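---
title: "Methods: models, preprocessing choices and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, preprocessing choices and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nirsbci` implements a complete classification pipeline for block-design
functional near-infrared spectroscopy (fNIRS) brain-computer interfaces:
rest vs. right- vs. left-hand motor execution from multichannel
hemodynamic time series. This vignette documents the models, the numerical
choices and their rationale, and what the synthetic-data generator does and
does not establish.

# Signal model and preprocessing

## Modified Beer-Lambert law

A continuous-wave instrument measures optical-density changes
$\Delta OD(\lambda)$ per channel. Under the modified Beer-Lambert law,

$$\Delta OD(\lambda) = d \cdot DPF(\lambda)\,
  \bigl(\varepsilon_{HbO}(\lambda)\,\Delta[HbO] +
        \varepsilon_{HbR}(\lambda)\,\Delta[HbR]\bigr),$$

with $d$ the source-detector distance (default 3 cm), $DPF$ the
differential path length factor (default 6 at every wavelength) and
$\varepsilon$ the extinction coefficients. `od_to_concentration()` inverts
the stacked system: exactly for two wavelengths, by least squares for
three or more (the two paths agree when given the same two wavelengths).
Systems with condition number above `1e8` are rejected rather than
silently amplified. The shipped extinction table for 780/805/830 nm is a
standard literature compilation and is *configuration, not ground truth* —
override it to match your instrument. Which two of three measured
wavelengths the original instrument pipeline used is not knowable from the
outside; the package defaults to using all provided wavelengths.

## Wavelet multiresolution denoising

Physiological noise (cardiac ~0.8 Hz, respiration ~0.2 Hz, Mayer waves
~0.1 Hz, very-low-frequency oscillations ~0.03 Hz) is removed by a
10-level multiresolution analysis with the orthogonal Daubechies db5
wavelet. Detail level $j$ occupies the nominal dyadic band
$(f_s/2^{j+1},\, f_s/2^j)$; at $f_s = 25.7$ Hz, levels 8 and 9 jointly
cover ~0.025-0.1 Hz, the band of the task-evoked hemodynamic response, so
the denoised signal is simply $d_8 + d_9$.

Numerical choices:

* **Periodized transform.** Component lengths stay exact and the analysis
  operator is orthogonal, so per-level components are obtained by zeroing
  all other levels and inverse-transforming (equivalent, for orthogonal
  wavelets, to the inner-product expansion of the underlying MRA theory).
* **Non-dyadic lengths.** Signals whose length is not a multiple of
  $2^{10}$ are extended periodically to the next multiple and every
  component is cropped back, so the additive identity
  `approximation + sum(details) == signal` holds to floating point at any
  length. Measured reconstruction error is ~1e-11 on random signals; the
  tests enforce 1e-8.
* **Whole-recording filtering.** A 10-level decomposition needs at least
  $2^{10} = 1024$ samples; one 10-s block (257 samples) cannot support it.
  The continuous session is therefore filtered *before* segmentation. One
  session of 4 blocks (1028 samples) is already deep enough.
* **Normalization granularity.** After filtering, each channel of the
  continuous recording is mapped to $[0,1]$ (mean-subtraction, then
  min-max). Recording-level scaling avoids leaking per-block amplitude
  into individual trials; per-trial or per-subject scaling would be
  alternative readings of "normalized into range (0,1)" and this choice is
  a documented default, not an inference of intent.
* **No coefficient thresholding.** The method reconstructs a fixed band;
  shrinkage-style wavelet denoising is deliberately out of scope.

# Features and classifiers

## Conventional features

Per trial, channel and chromophore: mean, population variance (divisor
$N$), non-excess kurtosis ($\mathrm{E}[(x-\mu)^4]/\sigma^4$, Gaussian
$\to 3$), skewness, peak (maximum of the signed trace, as printed in the
source formulas — not the maximum absolute value), and the OLS slope
against the sample index (per-sample units; a linear change of time units
only rescales the feature and is absorbed by min-max normalization).
Population moments are used without bias correction: the classifiers only
need consistency. For 34 channels this gives $6 \times 2 \times 34 = 408$
dimensions. Min-max feature scaling is fitted on training rows only and
clips held-out values into $[0,1]$; a constant training column maps to 0.5
with a warning.

## Linear SVM on principal components

PCA (fitted on training rows) reduces the 408 features; a linear
soft-margin SVM with penalty $C$ classifies the scores, one-vs-rest for
the three classes (the multiclass scheme is not dictated by the binary
objective; one-vs-rest is the simplest standard choice). The primal is
solved with the *squared* hinge so the objective is differentiable and
BFGS from a zero start converges deterministically — no RNG enters SVM
training.

## Fully connected networks

Six catalogue structures (`ann_structures()`): one hidden layer of
128/256/512 units or two hidden layers of 256+128 / 512+256 / 512+128,
ReLU activations (chosen for consistency with the convolutional stack;
configurable in principle, fixed here), softmax output, categorical
cross-entropy (the reference procedure states softmax output; the loss is
the canonical pairing). Weights initialize uniform in
$\pm\sqrt{1/\text{fan-in}}$ from the run seed.

## Convolutional networks

Four catalogue structures (`cnn_structures()`): one convolutional layer of
32 or 64 filters, or three layers of 32 or 64 filters each. Every filter
spans the full channel width (68 chromophore-channels) and slides along
time with kernel size 3, stride 1 and **length-preserving zero padding** —
forced by the reference shape table, where a 257-sample input stays 257
after convolution. Max-pooling of size 2 uses floor division (257 → 128;
the orphan sample is dropped), then dropout at 0.5. Two fully connected
ReLU layers (256, 128) and a 3-class softmax head follow.
`cnn_shapes()` reproduces the reference propagation table for CNN2-a on a
257 × 68 input exactly.

## Optimization

Adam with $\beta_1 = 0.9$, $\varepsilon = 10^{-8}$, mini-batch shuffling
and inverted dropout, all seeded — two runs with the same seed produce
identical weights. The reference procedure prints $\beta_2 = 0.1$; that value
effectively disables second-moment smoothing and is almost certainly a
typo, so the package defaults to the standard $\beta_2 = 0.999$ and
provides `train_config(paper_adam = TRUE)` to restore the printed value
for strict reproduction.

# Evaluation

`stratified_kfold()` balances classes across folds (per-class counts
differ by at most one), so the 2:1:1 rest/right/left prior holds per fold.
Plain fold-size balance would satisfy a literal reading of "identical
amount of data per fold"; stratification is the stricter choice and makes
the majority-class null exactly 0.5. Accuracy is top-1 correct rate — the
only metric the method reports.

All data-dependent preprocessing (feature min-max, PCA) is fitted inside
each training fold; a poisoning test asserts that corrupting held-out rows
cannot change fitted statistics or predictions. Hyperparameter grids
(epochs {20, 50, 100}, batch {16, 32, 64}, learning rate
{1e-4, 5e-4, 1e-3}; SVM: $C$ log-spaced 1e-2..1e2, components
{2, 5, 10, 20, 50, 100, 200} — the network grids are the observed
per-subject value sets, the SVM grids are package defaults) are searched
on the same k-fold loop, ties broken toward the cheaper model (fewer
epochs, smaller batch, lower learning rate; fewer components, smaller
$C$). There is no nested cross-validation: hyperparameters are optimized
on the same folds that produce the reported accuracy, which is optimistic;
this mirrors the evaluated procedure as written and is documented rather
than silently "fixed".

`learning_curve()` subsamples stratified subsets (preserving 2:1:1),
cross-validates each size and averages over repeated draws; at the full
sample size no subsampling occurs, so the result coincides with
`cross_validate()` under the derived seed.

# Interpretation

`pca_scatter()` projects any representation (raw flattened trials, the
feature table, or first-layer feature maps) onto its top two principal
components. `filter_channel_attribution()` averages each first-layer
filter's weights over the kernel (time) dimension to one weight per input
channel — the *signed* mean, as the procedure states; because training can
flip sign conventions, an absolute-value variant is available behind
`use_absolute = TRUE` — selects the arg-max channel and extracts that
channel's trace from every trial. Filters are reported ranked by
class-conditional amplitude contrast (largest |task mean − rest mean|),
since the original selection rule for which filters to display was
unstated.

# The synthetic world

No public recordings exist for this task (8 in-house subjects, 34
channels, 25.7 Hz), so the package ships a generator whose defaults *are*
the stated experimental design: 10 experiments × 5 sessions × (rest,
right, rest, left) 10-s blocks = 100/50/50 trials; channels 1-17 over C4,
18-34 over C3; right-hand tasks activate contralateral C3, left-hand C4;
HbO rises while HbR falls (HbR amplitude −1/3 of HbO, a typical
neurovascular coupling ratio; the reference procedure states polarity only). The
response is a unit-peak difference-of-gamma kernel (peak 6 s, undershoot
16 s — the reference procedure names no kernel, only that activation was observed
5-10 s into the block, which these defaults place inside it) convolved
with the task boxcar; ipsilateral channels receive a 0.2 fraction so
attribution tests are non-degenerate. Noise is four sinusoids (0.8, 0.2,
0.1, 0.03 Hz) with uniform random phases per channel, component and
chromophore, plus white noise.

**Amplitude calibration (done once, then frozen).** No reference SNR or
amplitude figures exist. Only the Mayer (0.1 Hz) and VLF (0.03 Hz) components survive the
d8+d9 band-pass, and the Mayer period equals the 10-s block length, so it
repeats identically in every block and adds no trial-to-trial variability
— the VLF drift is the effective discriminability limit. With weak noise
the world is trivially easy (cross-validated accuracies ≈ 0.99 at every
training size, saturating any learning-curve trend). The frozen defaults —
cardiac 0.4, respiration 0.3, Mayer 1.0, VLF 1.5, white 0.8, relative to a
unit-peak response — put systemic low-frequency activity at or above the
response amplitude (the regime real recordings occupy) and yield
cross-validated accuracies around 0.9-0.98 with a cleanly increasing
learning curve.

**What a green test does not establish.** The generator has no motion
artifacts, no superficial/scalp hemodynamic layer, no optode-geometry
photon transport, no inter-subject variability, and its noise is
stationary sinusoids rather than broadband 1/f physiology. Passing the
recovery tests shows the pipeline extracts a lateralized, correctly signed
hemodynamic response from realistic in-band interference — it does not
certify real-data accuracy levels.

# Degenerate inputs and tie-breaks

* Constant traces: kurtosis/skewness are undefined → error, not NaN.
* Constant feature columns: map to 0.5 after min-max, with a warning.
* Max-pooling ties (`a == b`): the earlier sample wins.
* Arg-max over class scores/probabilities: first maximum wins.
* Rank-deficient PCA requests are reduced with a warning.
* MBLL systems with condition number > 1e8: rejected.
* Signals shorter than $2^{levels}$: rejected with the required minimum.

# Known limitations

* The CNN/ANN engine is plain R; it is fast enough for the package's
  problem sizes (a full 10-fold CNN cross-validation of the 200-trial
  default world runs in a few minutes on one core) but is not a
  general-purpose deep-learning tool.
* Only orthogonal Daubechies wavelets and periodic boundary handling are
  implemented; other boundary modes would change component values near the
  edges (not the perfect-reconstruction property).
* `learning_curve()` assumes the full data's class ratio is the target
  ratio for subsamples.
* No SNIRF or vendor binary readers; records travel as CSV + JSON sidecar.
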
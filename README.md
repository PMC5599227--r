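# nirsbci

Classification pipeline for functional near-infrared spectroscopy (fNIRS)
brain-computer interfaces: three-class discrimination of **rest**,
**right-hand** and **left-hand motor execution** from multichannel
hemodynamic recordings.

fNIRS measures cortical activity optically: neurovascular coupling raises
oxygenated hemoglobin (HbO) and lowers deoxygenated hemoglobin (HbR) under
the activated cortex, and hand movement activates the *contralateral*
motor area (C3 for the right hand, C4 for the left). A BCI must turn a
10-s task block — a matrix of `M = 257` time points × `2N = 68`
chromophore-channels at 25.7 Hz — into one of three commands, reliably.

## What the package provides

| Stage | Functions |
| --- | --- |
| Data model + I/O | `hemodynamic_record()`, `optical_density_record()`, `read_record()` / `write_record()` (CSV + JSON sidecar), `segment_trials()` |
| Synthetic sessions | `simulation_config()`, `simulate_session()`, `canonical_hrf()` |
| Modified Beer-Lambert law | `mbll_coefficients()`, `od_to_concentration()`, `forward_mbll()` |
| Wavelet denoising | `mra_decompose()`, `band_reconstruct()`, `band_edges()`, `denoise_record()` |
| Features | `stat_features()`, `extract_feature_table()`, `fit_minmax()` / `apply_minmax()` |
| Classifiers | `svm_spec()` + `train_svm()`, `ann_structures()` + `train_ann()`, `cnn_structures()` + `train_cnn()`, `cnn_shapes()` |
| Evaluation | `stratified_kfold()`, `cross_validate()`, `grid_search()`, `learning_curve()` |
| Interpretation | `pca_scatter()`, `cnn_feature_maps()`, `filter_channel_attribution()` |
| Orchestration | `run_pipeline()`, `inst/cli/nirsbci` command-line script |

The core method: convert per-wavelength optical-density changes to
ΔHbO/ΔHbR with the modified Beer-Lambert law
`ΔOD(λ) = d · DPF · (ε_HbO(λ) ΔHbO + ε_HbR(λ) ΔHbR)`; band-pass each
channel by keeping details d8 + d9 of a 10-level Daubechies-5
multiresolution analysis (≈ 0.025-0.1 Hz at 25.7 Hz, suppressing cardiac
0.8 Hz, respiratory 0.2 Hz and broadband noise); then either extract the
conventional 408-dimensional feature vector (mean, variance, kurtosis,
skewness, peak, slope × HbO/HbR × 34 channels) for a PCA + linear SVM or a
fully connected network, or feed the raw 257 × 68 trials to a 1-D
convolutional network whose filters span all channels and slide along
time. Stratified 10-fold cross-validation with grid search scores every
model; first-layer filter weights, averaged over the kernel dimension,
attribute each filter to the input channel it tracks.

Because no public recordings exist for this task, the
package includes a seeded simulator reproducing the stated experimental
design (10 experiments × 5 sessions × rest/right/rest/left 10-s blocks =
100/50/50 trials) with contralateral HbO-positive / HbR-negative responses
and physiological noise at 0.8 / 0.2 / 0.1 / 0.03 Hz.

## Worked example

```r
library(nirsbci)

# a full synthetic subject: 200 blocks, 34 channels, 25.7 Hz
sess   <- simulate_session(simulation_config(seed = 1))
den    <- denoise_record(sess$record)           # d8+d9 band-pass + [0,1]
trials <- segment_trials(den, sess$onsets_s, sess$labels)
trials
#> trial_set: 200 trials of 257 samples x 68 columns (rest=100, right=50, left=50)

feats <- extract_feature_table(trials)
dim(feats)
#> [1] 200 408

# conventional route: min-max + PCA + linear SVM, 10-fold CV
cross_validate(svm_pipeline(svm_spec(c_regularization = 1,
                                     n_components = 20)),
               feats, trials$labels, k = 10, seed = 1)
#> cv_report [SVM(C=1, pc=20)]: mean accuracy 0.9850 over 10 folds (seed 1)

# proposed route: 1-D CNN on raw trials
cross_validate(cnn_pipeline(cnn_structures()[["CNN1-a"]],
                            train_config(epochs = 20, batch_size = 16)),
               trials, trials$labels, k = 10, seed = 1)
#> cv_report [CNN1-a]: mean accuracy 0.9700 over 10 folds (seed 1)

# which input channel does each trained filter track?
model <- train_cnn(trials, spec = cnn_structures()[["CNN1-a"]],
                   config = train_config(epochs = 20, batch_size = 16,
                                         seed = 1))
att <- filter_channel_attribution(model, trials)
att[[1]]$selected_channel   # top-contrast filter -> a C3 HbO channel (18-34)
#> [1] 29
round(att[[1]]$class_means, 3)
#>  rest right  left
#> 0.512 0.507 0.440
```

The mean accuracies are what the cross-validation loop printed for these
seeds on this machine; they say the band-passed hemodynamic response is
recoverable from in-band physiological interference in the simulated
world, not that real recordings reach these levels. The attribution output
shows the highest-contrast filter locking onto channel 29 — a
left-hemisphere (C3) HbO channel, i.e. one of the lateralized channels the
simulator planted; for this filter the left-hand blocks deviate most from
rest (C3 is ipsilateral to the left hand, so after per-channel [0,1]
normalization its left-block amplitude sits low). The acceptance suite
checks the right-hand recovery property across ten seeds: some filter
selects a C3 HbO channel whose right-hand amplitude exceeds rest.

The reference shape arithmetic is reproduced exactly:

```r
cnn_shapes(cnn_structures()[["CNN2-a"]], c(257, 68))
#>                      layer   input  output
#> 1    Convolutional layer 1 257, 68 257, 32
#> 2            Max-pooling 1 257, 32 128, 32
#> ...
#> 10 Fully connected layer 1    1024     256
#> 11 Fully connected layer 2     256     128
#> 12            Output layer     128       3
```

## Command line

```sh
Rscript inst/cli/nirsbci simulate --seed 1 --out-dir out
Rscript inst/cli/nirsbci denoise  --in out/record.csv --out out/filtered.csv
Rscript inst/cli/nirsbci crossval --in out/record.csv --events out/events.csv \
                                  --model cnn:CNN1-a --k 10 --seed 1
```

See `vignettes/nirsbci-methods.Rmd` for the model details, numerical
choices, and exactly what the synthetic world does and does not establish.
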
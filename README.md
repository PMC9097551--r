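# esndecode

Decoding the movement direction of the primary (right) hand from EEG while
the opposite (left) hand is moving at the same time. Bimanual movement is
the norm in daily activity, but most EEG movement decoders are built and
evaluated on single-hand paradigms; `esndecode` implements and tests a
complete pipeline for the harder bimanual setting, where the signal of
interest — the movement-related cortical potential (MRCP), a slow
(< 4 Hz) centrally-peaked deflection around movement onset — is overlaid
by the opposite hand's activity.

The package is aimed at BCI / neural-engineering researchers who want a
reproducible, fully testable reference implementation: every stage runs on
a bundled synthetic bimanual center-out session generator with known
ground truth, so the whole chain is verifiable without any recordings.

## Method

The decoding feature is the readout of an echo state network (ESN). A
fixed random reservoir maps the multichannel epoch `u(n)` (channels ×
time) into a high-dimensional nonlinear state sequence

    x(n) = tanh(W_in u(n) + W_NN x(n−1)),      x(0) = 0

with `W_in` (NN × C, uniform on [−1, 1]) and the sparse recurrent matrix
`W_NN` (density `c`, rescaled to spectral radius ρ = 0.98) frozen after
initialization. Per trial, a ridge regression (λr = 1e−4) maps
`[x(n); u(n); 1]` to the next sample `u(n+1)`:

    W_out = Y Xᵀ (X Xᵀ + λr I)⁻¹

The flattened `W_out` — dimension `Num_F = C·(NN + C + 1)` — captures the
trial's nonlinear dynamics and is the classification feature. Features
are PCA-reduced (99% cumulative variance, fitted on training folds only)
and classified with LDA under 5 × 5 stratified cross-validation. Accuracy
under opposite-hand movement (W-OHM) is computed separately within the
opposite-hand F and B subsets and averaged. The reservoir hyperparameters
are selected per subject by mesh grid search over
`c ∈ {0.1, …, 0.9}` × `NN ∈ {10, 20, …, 70}`.

Before feature extraction the pipeline applies, in order: down-sampling
to 100 Hz, re-referencing to the mean of two mastoid-proxy channels,
per-trial baseline correction, common average reference, ICA-based
ocular-artifact rejection (components whose absolute correlation with an
EOG channel exceeds 0.4 are removed), an FFT band-pass in [0.01, 4] Hz,
epoching to the [0, 1] s window after the Go-Cue, and per-trial z-score
normalization.

## Worked example

Simulate a full session (80 trials per direction combination), preprocess
it, and decode with a fixed reservoir:

```r
library(esndecode)

spec <- synthetic_spec(fs = 500, seed = 3)        # bimanual center-out session
rec  <- generate_session(spec)
ep   <- preprocess_recording(rec, preprocess_config())

model <- init_reservoir(esn_config(NN = 60, c = 0.4, seed = 7), C = 24)
feats <- extract_features(ep, model)
acc   <- wohm_accuracy(feats, ep$labels, cv_spec(seed = 1))
as.numeric(acc)            # 0.97
attr(acc, "per_subset")    # F: 0.99375   B: 0.94625
```

The W-OHM accuracy 0.97 is the mean of the two opposite-hand subsets:
within trials whose left hand moved forward (F) the right hand's L-vs-R
direction is decoded at 99.4%, within backward-moving trials at 94.6%.
With `dynamics_separation = 0` the generator removes the class-dependent
dynamics and the same pipeline drops to chance (≈ 0.49).

The statistical helpers reproduce the published group-level analyses from
the per-subject result tables bundled in the package:

```r
summarize_accuracies(wohm_results_table()$proposed)
# $mean 89.475    $std 5.924486

anova_oneway(with(wohm_results_table(), list(model1, model2, proposed)))
# F = 16.88, df = (2, 39), p = 5.2e-06

effect_size_f2(0.417)
# 0.7152659
```

A thin command-line front end is available at `inst/cli/decode.R`
(subcommands `simulate`, `preprocess`, `decode`, `gridsearch`,
`signatures`, `stats`, `run`).

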
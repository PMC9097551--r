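---
title: "Decoding primary-hand movement direction under opposite-hand movement"
author: "esndecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding primary-hand movement direction under opposite-hand movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

During bimanual movement, the EEG correlates of one hand's movement are
superimposed on those of the other. The quantity of interest here is the
direction (left/right, "L"/"R") of the primary right hand while the left
hand simultaneously moves forward or backward ("F"/"B"). The informative
signal is the movement-related cortical potential (MRCP): a slow
deflection, largest at the vertex (Cz), with a small positive peak about
300 ms after the Go-Cue and a pronounced negative peak about 500 ms after
it, i.e. at actual movement onset. Direction-dependent *amplitude*
differences of the MRCP are small; the premise of the method is that
direction information is also carried by the *nonlinear dynamics* of the
low-frequency signal, which a linear amplitude feature cannot capture.

The feature extractor is an echo state network. A fixed random reservoir
of `NN` neurons evolves as

$$x(n) = \tanh(W_{in}\,u(n) + W_{NN}\,x(n-1)), \qquad x(0)=0,$$

with input weights $W_{in}$ uniform on $[-1,1]$ and a sparse recurrent
matrix $W_{NN}$ (fraction $c$ of entries nonzero) rescaled to spectral
radius $\rho = 0.98 < 1$, which gives fading memory: test
`different initial states are forgotten` verifies that two state
trajectories started from different $x(0)$ converge. Per trial, a ridge
readout maps the stacked regressor $[x(n); u(n); 1]$ to the next sample
$u(n+1)$,

$$W_{out} = Y X^\top (X X^\top + \lambda_r I)^{-1}, \qquad
\lambda_r = 10^{-4},$$

and the flattened $W_{out}$ is the trial's feature vector of length
$\mathrm{Num}_F = C\,(NN + C + 1)$. The regressor stack is the only
reading consistent with that dimension formula, which is why the bias
and the current input are included. One readout is fitted *per trial*
(the feature), using all $T-1$ transitions without washout — epochs are
only 100 samples long at 100 Hz, so discarding a washout period would
cost a large fraction of the data while $x(0)=0$ is part of the feature
definition.

Features are PCA-reduced to the smallest number of leading components
reaching 99% cumulative explained variance and classified with a
two-class LDA (shared covariance). Accuracy is estimated by five
repetitions of stratified five-fold cross-validation; under opposite-hand
movement it is computed separately within the F and the B subset and the
two subset means are averaged ("W-OHM" accuracy). Fold means are averaged
within each subset first, then across subsets. Reservoir hyperparameters
are selected by an exhaustive mesh grid search over
$c \in \{0.1,\dots,0.9\}$ and $NN \in \{10,\dots,70\}$; ties are broken
toward the smaller reservoir, then the smaller density — the cheaper
model at equal performance.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.98 | spectral radius of `W_NN`; < 1 for the echo-state property |
| `c` | grid 0.1–0.9 | density of recurrent connections |
| `NN` | grid 10–70 | reservoir size |
| `lambda_r` | 1e-4 (unitless) | ridge penalty of the readout |
| `variance_target` | 0.99 | PCA cumulative explained-variance cutoff |
| `target_fs` | 100 Hz | analysis sampling rate |
| `band` | [0.01, 4] Hz | MRCP band |
| `ica_corr_threshold` | 0.4 | EOG-correlation rejection criterion (strictly exceeded) |
| `epoch_window` | [0, 1] s of Go-Cue | decoding window (= [−0.5, 0.5] s of movement onset) |
| `baseline_window` | [−2, 0] s | pre-movement baseline (flat MRCP period) |

"Sparse degree" is interpreted as the *density* (fraction of nonzero
recurrent weights), the common reservoir-computing convention; decoding
accuracy varies little with `c`, consistent with either reading.
Sparsity is realized with an exact count (`round(c·NN²)` positions drawn
without replacement) so the density contract is deterministic rather than
binomial.

## The synthetic session generator

No public recording of this paradigm exists, so the generator emulates
its statistical structure on the paradigm timeline (cue at 0 s, Go-Cue at
4 s, movement onset at 4.5 s, trial end at 11 s; 80 trials per L/R × F/B
combination; 24 scalp channels, two mastoid proxies, two EOG channels).
Each trial is a sum of:

* **MRCP template** — two raised-cosine deflections (positive, +3 µV at
  0.3 s, width 0.25 s; negative at 0.5 s, width 0.36 s) whose negative
  extremum at Cz is −10.4324 µV for L and −9.4153 µV for R, scaled across
  channels by a squared-exponential profile peaking at Cz. Raised cosines
  rather than Gaussians: their compact support pins the extremum value
  and latency exactly and keeps the pre-cue baseline identically zero,
  which the template contract asserts exactly; over 99% of the template's
  power lies below 4 Hz.
* **Direction-dependent dynamics** — per-channel AR(2) noise whose
  resonance is 0.8 Hz for L and `0.8 + 2.6·dynamics_separation` Hz for R
  (bandwidth 0.3 Hz, sd `2·noise_sd`, spatially scaled like the
  template). This is the information the reservoir readout picks up;
  at `dynamics_separation = 0` the classes differ only in the
  (non-significant) 1 µV amplitude difference and decoding sits at
  chance, reproducing the premise that amplitude alone is insufficient.
* **Opposite-hand dynamics** — a weaker AR(2) component (sd `noise_sd`,
  bandwidth 0.6 Hz) at 1.9 Hz (F) vs 2.4 Hz (B), so the F/B split of the
  W-OHM evaluation is exercised non-trivially.
* **Broadband noise** (`noise_sd`, default 2 µV) and **ocular
  artifacts** — Poisson-timed 200-ms raised-cosine blinks (~100 µV)
  mixed through a fixed frontal gain vector returned as ground truth.
  The opposite hand's movement intensity is not quantified in the
  paradigm description; the fixed amplitude ratio (half the primary
  dynamics) is the generator's own choice.

All AR amplitudes scale with `noise_sd`, so `noise_sd = 0` yields exact
noiseless template trials (used by the round-trip tests). The same spec
and seed always produce byte-identical sessions.

What the generator does **not** emulate: realistic 3-D scalp geometry and
volume conduction (the spatial profile is an index-distance decay),
inter-subject and inter-trial nonstationarity, EMG and electrode
artifacts, or genuinely nonlinear cortical dynamics beyond AR(2)
resonances. Passing tests therefore demonstrate correctness of the
pipeline's computations and its sensitivity to class-dependent dynamics —
not performance on real recordings.

## Preprocessing decisions

* **Reference channels.** The montage contains no ear electrodes, so
  "binaural" re-referencing is configurable by label and defaults to the
  two synthetic mastoid proxies `M1`, `M2`.
* **Order.** Resample → re-reference → per-trial baseline correction →
  common average reference → ICA → band-pass → epoch → z-score. Baseline
  correction is per trial/channel over [−2, 0] s (the flat pre-movement
  period) and is applied segment-wise while the data are still
  continuous, keeping the step order; the epoch-level operation is also
  exported.
* **ICA.** FastICA (`ica::icafast`, logcosh, symmetric updates) with as
  many components as the numerical rank of the channel covariance (the
  common average reference removes one dimension). The unmixing matrix is
  estimated on at most 50,000 evenly spaced samples; component time
  courses, their Pearson correlations with the EOG channels (computed on
  the full recording) and the back-projection use all samples. A
  component is rejected when its maximum absolute EOG correlation
  *strictly* exceeds 0.4. The symmetric-FastICA stopping rule demands
  that every direction stabilize; near-Gaussian background dimensions
  oscillate indefinitely while artifact components stabilize within a few
  dozen sweeps, so the default on reaching `maxit` is to use the last
  iterate and warn with diagnostics (an error or pass-through is
  available by flag). ICA is fitted after down-sampling, following the
  pipeline order.
* **Filters.** The decoding path uses a brick-wall FFT mask (bins outside
  [0.01, 4] Hz zeroed — exactly linear, used by the linearity tests); the
  waveform/visualization path uses a 4th-order zero-phase Butterworth
  band-pass. Both are applied with odd-reflection padding to suppress
  edge transients. The two dialects agree to correlation > 0.95 on
  in-band content.
* **Weighted average filter at Cz.** `Cz := Cz − Σ wᵢ·chᵢ` with weights
  from baseline-period correlations of each channel with Cz, floored at
  zero, shrunk toward uniform and normalized to sum 1. Pure correlation
  weights are ill-conditioned when baseline correlations are near zero
  (as in synthetic noise); the shrinkage keeps the filter well-defined
  while preserving the correlation weighting where it exists.
* **z-score.** Per trial and channel, population σ (divisor *n*),
  matching the dispersion convention used throughout the package; this
  makes features invariant to per-trial affine amplitude changes and is
  leak-free by construction.
* **Epochs.** Half-open `[start, end)` windows, so [0, 1] s at 100 Hz is
  exactly 100 samples and the first sample is the Go-Cue sample.

## Cross-validation and leakage

PCA and LDA statistics are computed on training folds only; the test fold
is projected with the training centering and rotation. A `paper_mode`
flag reproduces the global-PCA variant (projection fitted once on all
trials before cross-validation) for comparison with analyses that report
a single reduced dimension; the default is the leak-free variant. Folds
are stratified — with 80 trials per condition this keeps class balance
exact — and the fold assignments derive from the CV seed, so repeated
runs are identical.

Each grid cell uses its own frozen reservoir, seeded deterministically
from the global seed and the cell's `(c, NN)`, so a cell's 25 fold
accuracies are internally consistent and the whole surface is
reproducible from one integer.

## Neural-signature summaries

Grand-average MRCPs are plain trial means at a channel with peak
quantification on the mean waveform. Time-frequency power uses Morlet
wavelets (7 cycles, 0.5–16 Hz in 0.5-Hz steps) with optional decibel
normalization against the [−1.5, −0.5] s baseline — the standard choice
for low-frequency event-related power; the analysis epoch is shorter than
a 7-cycle wavelet below ~2 Hz, so the lowest frequencies are smoothed
estimates. Scalp snapshots are per-channel trial means at the nearest
sample to each requested latency. Note that the pipeline's spatial
filters (common average reference, the Cz weighted average filter)
attenuate the template amplitude, so grand averages computed after them
are smaller than the generator's nominal peaks; the exact round-trip of
the −10.4324 µV extremum is asserted on unfiltered noiseless epochs.

## Statistics

* Cohen's effect size for F-ratios: $f^2 = R^2/(1-R^2)$; the worked
  value $f^2(0.417) = 0.7153$. The two-group equivalent is
  $d = 2\sqrt{f^2} = 1.69$ — the package computes this rather than
  hard-coding the rounded 1.6 sometimes quoted for this $f^2$; the
  discrepancy is documented here deliberately.
* Sample size for a two-tailed test at effect size $d$: the
  closed-form normal approximation
  $n = \lceil ((z_{1-\alpha/2} + z_{\beta})/d)^2 + z_{1-\alpha/2}^2/2
  \rceil$, floored at 2, in place of tabulated power values. At
  $d = 1.6$, $\alpha = 0.05$, power 0.8 it gives $n = 5 \le 9$.
* One-way fixed-effects ANOVA (`stats::oneway.test`, equal variances)
  and Tukey-Kramer post-hoc comparisons (`stats::TukeyHSD`, unequal-n
  correction).
* Wilcoxon signed-rank: exact two-sided distribution up to 25 nonzero
  untied differences, normal approximation with tie correction
  otherwise; all-zero differences degenerate to $p = 1$. The exact mode
  is validated against brute-force enumeration of all $2^n$ sign
  assignments.
* Summary dispersion is the population standard deviation (divisor
  *n*), the convention that reproduces the published summary rows
  (89.48 ± 5.92).

## Numerical choices and degenerate inputs

* The reservoir recursion runs in compiled code; states are exactly 0
  for zero input and bounded by the tanh range.
* `fit_readout` with $\lambda_r = 0$ on a singular Gram matrix raises an
  error advising a positive penalty; the λ → ∞ limit shrinks
  $\|W_{out}\|$ monotonically (tested).
* An all-zero recurrent draw (possible at tiny `NN·c`) is redrawn with
  an incremented sub-seed and a message.
* LDA falls back to a ridge-stabilized pooled-covariance discriminant
  (diagonal jitter 1e-8) when the standard fit finds a singular
  covariance.
* Zero-variance channels abort z-scoring with the offending trial and
  channel named.

## Problem sizes used by the test suite

Unit tests run on reduced sessions (typically 200–500 Hz sampling, 2–15
trials per condition) chosen to exercise every code path quickly; the
end-to-end acceptance checks run the full-scale conditions — 1000 Hz, 80
trials per condition, the complete 9 × 7 grid — once, plus two
reduced-separation sessions for the monotonicity property. These sizes
are the package's own test-design choices.

## Known limitations

Besides the generator's simplifications listed above: only two-class
(L/R) primary-direction decoding is implemented; the comparison feature
sets (amplitude features, band-power features) are not part of the
package surface; topographic rendering is limited to per-channel value
tables; EDF/BrainVision interoperability is out of scope — sessions and
epochs round-trip through the package's native container only; and the
sample-size routine is a normal approximation, not a reproduction of
tabulated power analyses.
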
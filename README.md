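# adtrca

Frequency recognition for SSVEP brain–computer interfaces in R.

When a user gazes at a stimulus flickering at frequency *f*, the EEG over
occipital cortex contains a steady-state visual evoked potential (SSVEP): a
quasi-sinusoidal response at *f* and its harmonics. An SSVEP BCI selects one
of *Ns* targets by deciding which stimulation frequency a short multi-channel
EEG trial contains. This package implements **adaptive task-related component
analysis (adTRCA)** — a recognizer designed for noisy recordings and small
calibration sets — together with the CCA and TRCA baselines, their ensemble
variants, a synthetic SSVEP generator, and a leave-one-block-out evaluation
harness.

## The method

**TRCA** finds, per class *s*, a spatial filter
**w**ₛ = argmax (**w**ᵀAAᵀ**w**)/(**w**ᵀBBᵀ**w**), where A is the mean of the
class's training trials (Nch × Nt) and B their horizontal concatenation; a
test trial X is assigned to argmaxₛ corr(**w**ₛᵀX, **w**ₛᵀAₛ).

**adTRCA** inserts a class-specific *temporal* filter learned from the same
calibration trials. Every single-channel time course of every trial of class
*s* is treated as one regression task on a shared dictionary
Φ = [Y(f₁) … Y(f_Ns)] of stimulus harmonics (Y(f) holds sin/cos pairs at
f, 2f, …, Nh·f). The L = Nch·M tasks share one precision vector α (one
entry per dictionary column) and one noise precision α₀; type-II maximum
likelihood (sparse Bayesian learning / RVM-style evidence maximization)
estimates them jointly, pooling evidence across channels and trials and
pruning sinusoids the data do not support. The posterior yields the
smoothing matrix

    F_s = α₀ Φ Σ Φᵀ,   Σ = (α₀ ΦᵀΦ + diag(α))⁻¹,

a symmetric Nt × Nt operator with eigenvalues in [0, 1] that shrinks each
trial toward the learned sinusoidal subspace of its class. Trials are
filtered in time (X F_s), the TRCA eigenproblem is solved on the filtered
mean/concatenation, and the test trial is filtered with each candidate
class's F_s before correlation. With F_s = I the method reduces exactly to
TRCA — a limiting case the test suite asserts to machine precision. The
ensemble variant stacks all Ns filters into W and correlates the flattened
matrix projections WᵀX F_s with WᵀA_s.

## Worked example

```r
library(adtrca)

stim <- stimulus_set(c(6.66, 7.50, 8.57, 10.00, 12.00),
                     n_harmonics = 3, sampling_rate = 128, n_samples = 128)
cfg <- sim_config(stim, n_channels = 8, n_blocks = 6, snr_db = 3,
                  spatial_pattern_seed = 1, noise_seed = 2)
sim <- simulate_dataset(cfg)          # 30 trials: 5 classes x 6 blocks
trials <- centralize(sim$trials)
dict <- build_dictionary(stim)

lobo_cv(trials, "trca")
#> lobo_result (trca): 6 folds, accuracy 0.900, ITR 70.44 bits/min
lobo_cv(trials, "adtrca", dictionary = dict)
#> lobo_result (adtrca): 6 folds, accuracy 1.000, ITR 92.88 bits/min

bank <- adtrca_fit(subset_trials(trials, trials$blocks > 1), dict)
adtrca_classify(trial_matrix(trials, 3), bank)
#> recognition_result: predicted class 3 (scores: 0.015 -0.039 0.856 -0.346 0.027)
```

The generator produces one trial per class per block at a configurable
*narrowband* SNR (signal power relative to the background-noise power in one
DFT bin at the stimulus fundamental — the spectral SNR convention of the
SSVEP literature); here 3 dB is a moderately noisy recording, and the
adaptive temporal filter recovers the fold the plain TRCA loses. Scores are
Pearson correlations between filtered test projections and class templates;
the decision is their argmax.

A small CLI wraps the same functions:

```sh
Rscript inst/cli/adtrca simulate --out data.rds --seed 7
Rscript inst/cli/adtrca evaluate --data data.rds --method cca,trca,adtrca --out results.tsv
```

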
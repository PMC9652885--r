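---
title: "Methods: optimal symmetric EEG montages for MCI screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal symmetric EEG montages for MCI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable EEG headsets carry far fewer electrodes than the 32-channel
laboratory montages used in research on mild cognitive impairment (MCI).
This package asks, and answers computationally: *which small electrode set
preserves the machine-learning separability between MCI patients and
healthy controls (HC)?* The search space is restricted to bilaterally
symmetric configurations — combinations of the 4 midline electrodes (Fz,
Cz, Pz, Oz) and the 14 left/right symmetric pairs of the modified 10–20
montage — because symmetric headsets are what device manufacturers build.
A pair enters or leaves a configuration atomically, so the number of
configurations of size $k$ is $\sum_{2p+m=k}\binom{14}{p}\binom{4}{m}$:
20, 176, 924 and 3276 for $k = 2, 4, 6, 8$.

## Pipeline

1. **Preprocessing** (`preprocess_subject`): per-channel baseline
   subtraction; 0.5–50 Hz band-pass with a 6th-order Butterworth design
   applied forward–backward (zero net phase; effective magnitude order
   12); segmentation into non-overlapping 5-s epochs; rejection of any
   epoch whose absolute potential exceeds 75 µV on any channel; random
   subsampling to exactly 20 clean epochs per subject under a fixed seed.
2. **Feature extraction** (`build_feature_table`): ten families per
   channel and epoch, averaged across the 20 epochs. Per channel (39
   features): absolute and relative power spectral density in nine
   sub-bands (δ 1–4, θ 4–8, α_L 8–10, α_H 10–12, α 8–12, β_L 12–18, β_H
   18–30, β 12–30, γ 30–50 Hz), 14 phase–amplitude couplings ({δ, θ}
   phase × 7 amplitude bands), 3 Hjorth parameters, Shannon entropy,
   largest Lyapunov exponent, Hurst exponent, Lempel–Ziv complexity. Per
   symmetric pair (18): differential (left − right) and rational
   (left / right) band-power asymmetry in the nine sub-bands. Full
   montage: 39·32 + 18·14 = **1500** candidate features.
3. **Evaluation** (`evaluate_configuration`): leave-pair-out
   cross-validation — each fold holds out one MCI and one HC subject
   (21 × 21 = 441 folds at full cohort size). Per fold: z-scoring
   statistics fitted on the training rows only; Fisher-score ranking
   $(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ of the normalized training
   features; a linear-kernel SVM (unit box constraint) trained on the top
   $N$ features for $N = 1\ldots15$; the configuration's accuracy is the
   best $N$-feature accuracy. Because folds are class-balanced, accuracy
   ≡ (sensitivity + specificity)/2 exactly. The SD reported alongside is
   computed over the 21 blocks of folds sharing an MCI test subject.
4. **Search** (`search_optimal`): every enumerated configuration is
   restricted (a pair's asymmetry features enter only when both members
   are present) and scored; ties are broken by sensitivity, then
   enumeration order. Device montages (`evaluate_devices`) go through the
   identical path.
5. **Statistics** (`chi_square_2x2`, `students_t_two_tailed`,
   `ks_normality`, `wilcoxon_bonferroni`): demographic comparisons and
   Bonferroni-corrected signed-rank comparisons of per-fold accuracies
   between montages.

## Numerical choices

* **Butterworth realization.** The filter is designed as analog
  zero-pole-gain, bilinear-transformed, and factorized into second-order
  sections (one zero at $z=1$ and one at $z=-1$ per section); the cascade
  gain is normalized to exactly 1 at the warped band centre.
  Forward–backward application uses odd-symmetric edge extension (three
  periods of the low band edge) with steady-state initial conditions.
  "6th-order zero-phase" is read as a 6th-order *design* applied twice
  (effective magnitude order 12); `filter_order = 3` gives the other
  reading.
* **Spectral estimation.** Band powers integrate a Welch estimate (1-s
  Hann segments, 50% overlap) over half-open bands $[f_1, f_2)$, making
  the five primary bands an exact partition of 1–50 Hz; the relative-power
  denominator is the 1–50 Hz total so relative powers sum to one. A
  raw-periodogram mode is kept as the oracle path for tests. Absolute
  scale follows the density convention (power in µV²); any consistent
  convention is acceptable downstream because classification z-scores
  every feature.
* **Phase–amplitude coupling** is envelope coherence: band-pass to the
  amplitude band (4th-order zero-phase Butterworth), analytic-signal
  magnitude as the envelope, magnitude-squared coherence between envelope
  and raw signal (same Welch segmentation), averaged over the phase
  band's frequencies. With nine 1-s segments per 5-s epoch the coherence
  noise floor is ≈ 1/9, which is why resting values sit near 0.1.
* **Lyapunov exponent** is Rosenstein-style: delay embedding (K = 5),
  nearest neighbours outside a Theiler window of one mean period, slope
  of the mean log-divergence over the first half mean period. The
  embedding delay defaults to the first lag at which the autocorrelation
  drops to $1 - 1/e$ — the canonical choice for this estimator. (A
  zero-crossing rule was considered and rejected: on the fully chaotic
  logistic map, whose autocorrelation is ≈ 0 but positive at lag 1, it
  doubles the delay and biases $\hat\lambda$ to 0.64 versus the analytic
  $\ln 2 \approx 0.693$.) The divergence average is taken over at most
  400 evenly strided reference points; all points remain neighbour
  candidates.
* **Hurst exponent** is classical rescaled-range analysis: the slope of
  $\log(R/S)$ against $\log$ window size over 8 geometric window sizes.
  The ladder starts at 64 samples for signals of ≥ 1024 samples (16
  otherwise): classical R/S is biased upward in small windows
  (Anis–Lloyd), and starting higher keeps white noise near
  $\hat H = 0.5$. Estimates outside $(0,1)$ warn and are clipped to
  $(0, 1.2)$.
* **Lempel–Ziv complexity**: median binarization, LZ76 exhaustive phrase
  counting, normalization $c(n)\log_2 n/n$ (≈ 1 for i.i.d. bits).
* **Shannon entropy**: 64 equal-width amplitude bins over the sample
  range, entropy in nats, so values live in $[0, \ln 64]$.
* **SVM.** The kernel is not dictated by the problem, so the default is a
  linear kernel with $C = 1$ on z-scored features (RBF with
  $\gamma = 1/N$ available via `kernel = "rbf"`). The solver is a
  deterministic sequential-minimal-optimization C-SVC (partner chosen by
  maximal KKT gap, falling back in gap order until progress is made), so
  results are exactly reproducible and independent of RNG state. Tests
  cross-check it against an exact quadratic-programming solution of the
  dual. When every multiplier ends at a bound the bias term is not
  unique; such degenerate fits are rare in practice but the test oracles
  compare decision values only where free support vectors exist.
* **Fisher ranking ties** break by column order; zero-variance training
  features score 0 and are zeroed rather than dropped, preserving column
  indexing across folds.

## The synthetic cohort: what it emulates and what it does not

The clinical recordings behind the reference results are private, so the
package ships a generative model (`simulate_cohort`) that reproduces the
*statistical structure* the analysis assumes — not the waveforms of real
EEG. Each channel is the sum of:

* a 1/f-like background: fractional Gaussian noise (Davies–Harte exact
  synthesis) with group Hurst parameter — MCI 0.78, HC 0.73, the
  direction and rough magnitude of the reference group difference;
* a posterior-dominant ~10 Hz alpha rhythm (eyes-closed), subject-level
  amplitude and frequency variability;
* a 2 Hz delta rhythm, with an MCI-specific amplitude surplus at FC5
  (`delta_asym_gain = 0.5`, i.e. 2.25× delta power at FC5 vs FC6),
  planting the left-frontal delta asymmetry direction;
* at P8, a 6 Hz theta rhythm whose phase modulates a 24 Hz (high-beta)
  carrier with envelope $(1+d\cos\phi_\theta)/2$ — the standard
  generative model for envelope-coherence coupling — with depth
  $d = 0.4$ (MCI) vs $0.6$ (HC), so estimated coupling is *lower* in
  MCI;
* white measurement noise; everything clipped at ±74 µV so synthetic
  epochs pass the rejection stage by construction.

The carrier amplitude (6 µV) was calibrated **once** so that the
estimated coupling feature lands near 0.12–0.13 with a between-group
separability of Cohen's d ≈ 1, matching the scale of the reference
clinical effect; at smaller amplitudes the broadband background swamps
the high-beta envelope and the planted depth difference does not express.
No generator parameter was adjusted after that calibration.

A green synthetic test therefore establishes that the *pipeline* recovers
planted effects of realistic size and direction, that a null cohort
yields chance-level accuracy, and that every counting/identity contract
holds. It does **not** establish clinical accuracy: real EEG has
artifacts, volume conduction, non-stationarity and inter-site variability
the generator deliberately omits, and the reference clinical accuracies
are explicitly not an acceptance surface here.

## Scaling of the calibration tests

The full search (3276 configurations × 441 folds × 15 feature counts) is
an overnight desk job; the test suite scales *problem sizes* — never
effect sizes, seeds or thresholds — to fit CI budgets:

* null calibration: full subject count (21+21, 250 Hz) at 8 epochs per
  subject, with simulation, features and evaluation restricted to F3–F4 —
  the null property concerns the evaluation machinery; neither feature
  noise level nor montage width moves accuracy off chance under the null;
* planted FC5/FC6 recovery: the complete k = 2 search over all 32
  channels on a 10+10-subject, 3-epoch cohort;
* strong-effect check (effects at 3× defaults): 21+21 subjects, 5
  epochs, the 8 planted channels.

## Known limitations

* The SVM hyper-parameters (kernel, C) of the original clinical analysis
  are unknown; only the linear default is calibrated against the
  synthetic world.
* The Bonferroni family size for device comparisons defaults to 20
  (4 optimal sizes × 5 devices) and the signed-rank pairing unit is the
  441 per-fold accuracies; both are configuration knobs, since neither
  is fully determined by the source analysis.
* The amplitude-rejection criterion is applied per epoch on any channel;
  a per-channel variant and manual block exclusion are out of scope.
* The EDF reader covers continuous, uniform-rate recordings only (no
  EDF+ annotations, no discontinuous files).
* R/S Hurst estimation retains its classical small-sample bias; the
  window ladder mitigates but does not remove it. Group *differences*
  are unaffected because the bias is common-mode.
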
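---
title: "Single-trial word decoding with DTW kernels: model and design notes"
author: "dtwdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial word decoding with DTW kernels: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwdecode)
```

## The problem

Speech production — overt or imagined — is temporally variable across
repetitions of the same word: onsets shift and the utterance locally
stretches or compresses. A classifier built on fixed-time features treats
two renditions of the same word as different patterns whenever their
neural time courses are misaligned. `dtwdecode` implements a pairwise
word decoder for single-trial, multichannel high-gamma (70–150 Hz)
envelope features, as recorded with electrocorticography (ECoG), that
builds the time alignment into the classifier's kernel instead of trying
to estimate per-trial onsets.

The pipeline is, per word pair:

1. **Features.** Continuous recordings are band-passed, notch-filtered,
   re-referenced to the common average, band-passed in the high-gamma
   range (Hamming-window FIR, order 20, zero-phase), converted to
   envelopes by the analytic-signal magnitude, decimated to 100 Hz, and
   cut into epochs — speech-onset/offset bounded (±100 ms pad) where an
   audio channel defines onsets, or fixed 1.5-s cue-locked windows where
   it cannot (imagined speech). Each electrode is z-scored against the
   pooled 500-ms pre-stimulus baseline.
2. **Alignment.** For each electrode, the dissimilarity between two
   trials is the dynamic-time-warping (DTW) distance: the minimal average
   accumulated distortion `(1/K) * sum_k |x[phi_x(k)] - y[phi_y(k)]|`
   over monotone warping paths with steps {(1,0), (0,1), (1,1)} from
   (1,1) to (M,N), found by dynamic programming. Normalizing by path
   length K makes trials of unequal length comparable.
3. **Kernels.** Each electrode's distance matrix becomes a Gaussian
   kernel `K_e = exp(-gamma * D_e)`.
4. **Fixed-rule multiple kernel learning.** Electrode kernels are
   averaged with weights `w_e = dpi_e / sum(dpi)`, where the
   discriminative power index (DPI) of an electrode is the ROC AUC of its
   distances for separating between-class from within-class trial pairs.
   The weights are a deterministic formula of the training set — there is
   no weight optimization.
5. **Classification.** A soft-margin SVM runs on the combined precomputed
   kernel. Decision values are `sum_i alpha_i t_i K(x, x_i) + beta_0`
   with `alpha_i` in `[0, C]`.
6. **Evaluation.** Nested leave-one-out cross-validation: each outer fold
   holds out one trial per class; the DPI weights and the `(gamma, C)`
   grid search (inner leave-one-out on the training set) use training
   trials only. Significance comes from a full-pipeline label-permutation
   test, with Benjamini–Hochberg FDR across word pairs and one-sample
   t-tests against the 50% chance level at the group level.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | grid `2^(-4:2)` / median off-diagonal training distance | kernel bandwidth; median scaling makes the grid unit-free |
| `C` | grid `10^(-2:2)` | SVM soft margin |
| band-pass | 70–150 Hz, FIR order 20 | high-gamma definition; order 20 at 1 kHz is a shallow transition and is kept configurable |
| feature rate | 100 samples/s | post-decimation envelope rate |
| epoch pad | 100 ms | margin around detected speech onset/offset |
| baseline | 500 ms pre-stimulus, pooled | z-score reference (per-trial mode available) |
| onset threshold | 10% of trial max, sustained 50 ms | envelope-based speech onset/offset detection |
| `band` | none | optional Sakoe–Chiba constraint on the warping path |

Ties in the grid search go to the smallest `C`, then the smallest
`gamma` (prefer smoother models). The label-to-sign map is
deterministic: the lexicographically first word is +1, and a decision
value of exactly zero is classified +1.

## The synthetic generator

No public single-trial ECoG word data accompany this method, so the
package ships a generator that reproduces the statistical structure the
decoder assumes: per-class smooth response templates (mixtures of 2–4
Gaussian bumps, ~800 ms, matching the task's word length of 800 ± 20 ms)
on a configurable subset of informative electrodes; per-trial onset
delays (SD 0 for time-locked stimuli, 220 ms for overt-speech-like
variability — the measured figure for the task this framework was built
for); smooth monotone time warps built from a piecewise-linear rate
function bounded by `warp_strength`; and additive Gaussian noise in
z-units, optionally AR(1)-coloured. Epochs are emitted either
onset-locked (±100 ms, as for audio-segmented conditions) or as fixed
cue-locked windows (as for imagery). A raw-voltage mode synthesizes
1 kHz carriers — band-limited 70–150 Hz noise amplitude-modulated by the
templates, plus 60 Hz mains and broadband noise — solely to exercise the
preprocessing chain end to end; a paired audio-envelope channel supports
the onset-detection round trip.

What the generator does **not** emulate: spatially correlated noise
across electrodes, non-stationary baselines, epileptiform artifacts,
behavioural errors, or any biophysical forward model. Passing tests on
synthetic data therefore demonstrate the pipeline's correctness and its
qualitative behaviour (alignment benefit under jitter, chance-level
calibration), not clinical decoding performance.

## Numerical choices

- **DTW normalization.** The distance divides the accumulated cost by
  the path length K (the "average accumulated distortion"); an
  unnormalized mode exists. Equal-cost predecessors resolve to the
  diagonal step, which fixes the reported path but not the distance.
- **Warp-quantization floor.** DTW aligns integer sample indices; for a
  smoothly interpolated warp of a band-limited envelope the residual
  distance has a floor of roughly `mean|f'| / (2 fs)` (~0.01 for
  unit-amplitude envelopes at 100 Hz). Only warps inside DTW's exact
  alignment class (integer duplication/deletion) realign to distance
  zero. Tests assert both regimes.
- **Indefinite kernels.** Gaussians of DTW distances need not be
  positive semidefinite. The SMO solver (LIBSVM-style maximal-violating-
  pair working-set selection, duality gap 1e-6) consumes the kernel
  as-is, substituting a small positive curvature where a working set is
  non-convex; the combined kernel's smallest eigenvalue is recorded, not
  enforced.
- **DPI with ties.** The AUC uses midranks, so tied distances count 1/2;
  the index is invariant under strictly monotone transforms of the
  distances.
- **Permutation p-values.** Add-one convention
  `p = (#{null >= observed} + 1) / (n_perm + 1)` (never exactly 0), with
  `>=` in the null count (conservative); a plain-proportion mode exists.
  The shuffle stream is seeded and isolated from the global RNG.
- **Degenerate inputs.** Single-class training sets, empty grids,
  classes with fewer than 3 trials, zero baseline SDs, envelopes that
  never cross threshold, and mismatched electrode counts are all
  rejected with specific errors rather than propagated.

## Study conditions used by the validation suite

Desk-scale sizes were chosen so the full suite runs in minutes on one
core, while keeping every structural property of the protocol intact:

- *DTW optimality*: 500 random pairs of length ≤ 6 against exhaustive
  path enumeration, exact equality.
- *Alignment benefit*: 4 electrodes (2 informative), 8 trials/class,
  noise SD 0.5 z, 20 seeded replicates; onset jitter SD 150 ms with warp
  0.3 versus fully time-locked. The time-locked control is deliberately
  in the high-signal regime: in the data this framework models, the
  stimulus-locked listening condition decodes at or near ceiling, and
  there DTW and fixed-time kernels coincide. At substantially lower SNR
  unbanded DTW *costs* accuracy on time-locked data — it partially
  aligns distinct templates and noise — which is a known limitation of
  DTW in noisy settings (see Limitations).
- *Chance calibration*: one jittered dataset (8 electrodes, 10
  trials/class) with 200 label shuffles; plus 200 independent no-signal
  datasets.
- *Weight recovery*: 1 informative electrode among 8 at high SNR (noise
  SD 0.2), 50 replicates.
- *Type-I error*: 100 no-signal experiments, 99 permutations each, with
  a reduced 3×3 `(gamma, C)` grid as the desk-scale choice (the grid
  size is a free parameter of the protocol, not of the test).

## Limitations

- **DTW under noise.** With unconstrained paths, DTW can align noise
  and partially align different templates; on time-locked low-SNR data
  the DTW kernel measurably *underperforms* the fixed-time kernel. The
  optional Sakoe–Chiba `band` limits this at the cost of absorbing less
  jitter. Users decoding stimulus-locked conditions should compare both
  (`align = FALSE`).
- **Permutation-null centring.** For a fixed dataset whose trials carry
  label-independent structure (e.g. onset-jitter clusters), the
  cross-validated permutation null centres slightly above 50% at small n
  (the classifier recovers the structure whichever way the shuffled
  labels lean); at 10 trials/class we observe null means of ~51–54%.
  This is a property of cross-validated accuracy under permutation, not
  leakage; the permutation test remains valid because the observed
  statistic is referred to the same null.
- **Imagery timing.** Nothing in the pipeline estimates the true onset
  of imagined speech; cue-locked windows plus DTW absorb only part of
  that uncertainty, which is the central open problem for imagery
  decoding.
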
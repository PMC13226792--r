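---
title: "Modeling time-resolved ERP state dynamics in the auditory oddball task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-resolved ERP state dynamics in the auditory oddball task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdyn)
```

## Overview

`erpdyn` analyses epoched, multichannel EEG from auditory oddball
paradigms (frequent *standard* tones, rare *target* tones) in three
complementary ways:

1. **Conventional ERP measures** — N200 (standards, 150–250 ms, negative)
   and P300 (targets, 250–450 ms, positive) mean amplitude and peak
   latency per electrode, plus an inter-trial topographic similarity index.
2. **Continuous state-space geometry** — window-averaged scalp
   topographies (T1–T6, six half-open 100-ms windows over 0–600 ms) are
   projected into a two-dimensional PCA plane; standard and target
   trajectories are compared by summed Euclidean distance, angular
   separation relative to the T1 anchor, and path length, with bootstrap
   pseudo-populations (subjects resampled per group, PCA refit per
   iteration) providing distributions for inference.
3. **Discrete state sequences** — four dominant topographic states
   (PC1–PC4) are extracted by PCA on concatenated group-averaged
   responses; each sample is labeled by its best polarity-invariant
   template match (or *Other* when no match is significant), giving
   row-stochastic transition matrices, self-transition stabilities and
   targeted transition probabilities.

A linear-SVM classifier on per-subject target-minus-standard projection
differences, with a label-shuffling chance baseline, and a nonparametric
statistics layer (Kruskal–Wallis, Dunn–Šidák, BH-FDR, partial
correlation, chi-square, noncentral-F power analysis) complete the
pipeline. Because clinical recordings of this kind are not public, a
synthetic-cohort generator with known ground truth is a first-class,
tested module: every downstream stage is validated against planted
structure.

## The synthetic world

The generator emulates the post-preprocessing stage of a pediatric
oddball study: 19-channel 10–20 montage, 500 Hz, epochs −200…800 ms,
278 standard and 80 target trials, three groups (TD, ADHD-I, ADHD-C).
Signals are built from `n_states = 4` planted templates — random
orthonormal directions in the average-reference (zero-sum) subspace —
driven by per-window activation coefficients:

$$x_t(s) = \sum_k a_k(s - \delta_t)\,\mathbf{v}_k + \varepsilon,\qquad
\varepsilon \sim \mathcal N(0, \sigma^2)\ \text{i.i.d.},\quad
\delta_t \sim \mathcal N(0, \sigma_\delta^2)\ \text{truncated at } 3\sigma_\delta.$$

Key defaults and why:

* **Activation curves** are piecewise-constant over the six 100-ms
  windows with a 20-ms linear ramp at window boundaries (`ramp_ms`).
  Ramps avoid edge ambiguity exactly at window boundaries; with
  `ramp_ms = 0` the window means reproduce the configured coefficients to
  machine precision, which the tests exploit. Pre-stimulus activation is
  identically zero.
* **Group geometries** encode the qualitative clinical findings the
  pipeline must be able to detect: target responses add a late loading on
  states 3–4 (a P300-like excursion) on top of the standard response
  (states 1–2). ADHD-I scales the target-minus-standard deviation by 0.4
  (overlapping trajectories), ADHD-C scales the whole response by 1.5
  (amplified excursions), TD is the 1/1 reference. These factors were
  chosen once so that bootstrap distance distributions order
  ADHD-I < TD < ADHD-C decisively at desk scale, and are not tuned
  further.
* **Noise** defaults to 1 μV per channel/sample — with ≥60 trials the
  trial-average noise is ≈0.1 μV against 2–10 μV signals, a realistic
  post-averaging SNR for pediatric ERP data. **Latency jitter** defaults
  to 10 ms SD, applied as a whole-trial shift of the activation curves
  only (noise unshifted), a one-parameter model of inter-trial response
  instability.
* **Subject variability** (`subject_sd = 0.1`) multiplies each subject's
  excursion and separation by independent Normal(1, 0.1) factors. Their
  product is the subject's *latent separation scalar*, which links to
  simulated clinical subscales (SNAP-IV, Conners, Weiss entries with
  published group means/SDs) through configurable linear loadings —
  giving the correlation layer a known ground truth.
* **Clinical scores** are truncated at zero, as rating scales are.

What the generator does **not** emulate: continuous raw EEG, ocular or
muscular artifacts, volume-conduction-realistic topographies tied to
electrode geometry, non-Gaussian noise, or trial-order effects. A green
test therefore establishes algorithmic correctness and sensitivity to the
planted effects — not that the pipeline would detect the same effects in
any particular clinical sample.

## Identifiability and the template-recovery criterion

PCA recovers the planted *span* of templates on any zero-noise cohort
(cumulative explained variance of four components = 1), but individual
templates are only identifiable when their activation time courses are
uncorrelated with distinct energies; with temporally co-active states the
principal axes are arbitrary rotations within the span.
`recovery_activation_curves()` therefore gives each state disjoint time
support and distinct energy — the standard identifiability condition —
and the ≥ 0.999 per-template recovery test runs on that configuration
with `ramp_ms = 0`. The default (co-active) geometry is checked at the
span level instead.

## Numerical and procedural choices

* **Filtering.** No IIR-filter design library is assumed;
  `bandpass()` is a zero-phase frequency-domain filter (real raised-cosine
  transfer function, edges 10% of each corner frequency). Zero phase
  holds by construction. Filtering is **off by default** for synthetic
  data, which is band-limited at source.
* **Rejection boundary.** A trial is rejected iff max |value| is
  *strictly* greater than the 500 μV threshold; exact boundary values are
  retained.
* **Windows** are half-open `[a, b)`: a sample at exactly 100 ms belongs
  to T2. Ties in peak-latency search break toward the earliest sample.
* **PCA conventions.** Topographies are centered across channels (not
  across time); components are SVD right-singular vectors with the
  largest-magnitude loading forced positive, making output deterministic.
  Bootstrap bases are aligned to the full-sample reference by per-component
  sign flips only — all geometry metrics are invariant to rotation and
  reflection of the plane, so alignment matters only for labeling.
* **Angular separation** is the angle between the two conditions'
  displacement vectors from their own T1 anchors (windows T2–T6);
  displacements below 1e−12 give flagged `NA` angles. The alternative
  reading (each trajectory against its own T1 direction) is not the
  default and is easy to compute from the returned trajectories.
* **State assignment** uses the two-sided critical r at `alpha = 0.05`
  with `channels − 2` df, uncorrected per sample (the correction policy
  is not standardized in the microstate literature; `alpha` is exposed).
  Ties break toward the lowest-index state. *Other* is a first-class row
  and column of the transition matrix; self-pairs are counted so that
  stability is a probability within the same matrix.
* **Within-group correlation matrices** exclude the trivially-1 diagonal
  when locating row maxima; "aligned with the diagonal" then means the
  maximum sits adjacent to it.
* **Classifier.** A linear SVM was required but no SVM library is
  guaranteed; the package implements the L2-regularized squared-hinge
  primal (the LIBLINEAR default loss) fit by BFGS, one-vs-one with
  margin-sum tie-breaking, `C = 1`, and per-feature standardization
  estimated on training folds only. On matched constructions its CV
  accuracy tracks scikit-learn's `SVC(kernel="linear")` within a few
  points. The basis is deliberately fit on all subjects before
  cross-validation — reproducing the circularity of the emulated design —
  so shuffle nulls, not absolute accuracies, carry the inference.
* **Power analysis.** The required-N search constrains total N to
  multiples of the group count (balanced integer allocation, the G*Power
  convention); the unconstrained search (`balanced = FALSE`) stops one
  to two subjects earlier.
* **Seeds.** All randomness flows from one master seed through a fixed
  linear-congruential split (`derive_seed`), so cohorts, bootstraps and
  CV repeats are independently reproducible and every derived seed stays
  below 2^31.

## Known limitations

* The FFT band-pass assumes the epoch is long relative to the low corner
  period; at 0.1 Hz the attenuation inside a 1-s epoch is necessarily
  approximate (DC is removed exactly).
* Bootstrap pseudo-populations resample subjects *without* replacement
  (with-replacement is used, with a warning, only when a group is smaller
  than the pseudo-population), so iterations are exchangeable but not an
  i.i.d. bootstrap in the strict sense — matching the emulated procedure.
* The SVM has no hyperparameter search by design; `C` is exposed.
* Transition statistics at full sample resolution inherit the
  autocorrelation of the underlying ERP; they describe the labeled
  sequence, not an underlying Markov process.

## Running the pieces

```{r, eval = FALSE}
cfg <- generator_config(n_per_group = 15, seed = 1)
cohort <- simulate_cohort(cfg, return = "erps")
basis <- extract_states(group_average_erps(cohort$erps), K = 4)
seqs <- lapply(cohort$erps, window_means)
boot <- bootstrap_metrics(seqs, n_per_group = 15, iterations = 1000, seed = 1)
```

or, end to end,

```{r, eval = FALSE}
run_pipeline(run_config(generator = cfg, seed = 1), "results/")
```

The same stages are scriptable through the `erpdyn` CLI
(`inst/cli/erpdyn`): `simulate`, `run`, and `stats` subcommands with a
JSON configuration file.
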
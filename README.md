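# erpdyn

Time-resolved analysis of event-related potential (ERP) dynamics in
auditory oddball EEG, aimed at researchers comparing clinical groups
(e.g. typically developing children vs. ADHD inattentive/combined
subtypes) beyond classical component measures.

Given epoched multichannel EEG per subject and condition
(channels × time × trials), the package quantifies:

- **Classical components** — N200 (standards, 150–250 ms) and P300
  (targets, 250–450 ms) mean amplitude, peak latency, and inter-trial
  topographic similarity.
- **Trajectory geometry** — scalp topographies averaged in six 100-ms
  windows (T1–T6, 0–600 ms) and projected into a 2-D PCA state space;
  standard vs. target trajectories compared via summed Euclidean distance
  `D = Σ_w ‖x_w^tgt − x_w^std‖`, angular separation relative to the T1
  anchor, and path length, with bootstrap pseudo-populations
  (n subjects/group resampled, PCA refit per iteration) for inference.
- **Dominant neural states** — PCA on concatenated group-averaged
  responses yields K = 4 topographic templates (PC1–PC4); per-subject
  time-resolved projections and target−standard projection differences.
- **Microstate-style sequences** — each sample labeled by its best
  polarity-invariant template correlation (|r| above the critical value at
  α, df = channels − 2) or "Other"; row-stochastic transition matrices,
  self-transition stability, targeted transition probabilities.
- **Classification** — linear SVM on projection-difference features,
  repeated stratified 10-fold CV with a label-shuffling chance baseline
  and rank-sum comparison.
- **Statistics** — Kruskal–Wallis with Dunn–Šidák post hoc tests,
  Benjamini–Hochberg FDR, Pearson/partial correlation, chi-square
  contingency tests, and noncentral-F a priori power analysis.

Because such clinical recordings are not public, a synthetic-cohort
generator with planted orthonormal templates, group-specific activation
curves, trial noise, latency jitter, and clinical covariates linked to a
latent separation scalar is part of the package and is what the tests and
acceptance checks run on.

## Worked example

```r
library(erpdyn)

cfg    <- generator_config(n_per_group = 8, n_standard = 60, n_target = 60, seed = 1)
cohort <- simulate_cohort(cfg, return = "erps")          # preprocessed averages
basis  <- extract_states(group_average_erps(cohort$erps), K = 4)
round(100 * cumsum(basis$explained_var[1:4]), 2)
#> 75.77 96.23 99.85 99.91

seqs <- lapply(cohort$erps, window_means)                # T1–T6 topographies
bm   <- bootstrap_metrics(seqs, n_per_group = 6, iterations = 200, seed = 1)
round(colMeans(bm$metrics$distance_total), 2)
#>     TD ADHD-I ADHD-C
#>  19.08   5.89  27.76

sq <- assign_states(cohort$erps[["TD01_standard"]], basis)
round(other_proportion(sq), 3)
#> 0.003
round(state_stability(transition_matrix(sq))[1:4], 3)
#>   PC1   PC2   PC3   PC4
#> 0.963 0.458 0.167    NA
```

Reading the output: the four extracted states capture >99% of the
concatenated response variance (the cohort is built from four planted
templates plus noise). The bootstrap standard↔target trajectory distances
recover the planted subtype geometry — reduced separation for ADHD-I,
amplified excursions for ADHD-C, TD in between. The standard-condition
state sequence almost never falls into "Other" at this noise level, PC1
dominates the early response (high self-transition stability), and PC4 is
never visited by standards (NA stability) because only target responses
drive it. Note that planted templates are random orthonormal maps, so
electrode-wise values (e.g. P300 amplitude at Pz) carry no physiological
polarity here.

Statistics layer one-liners:

```r
anova_required_n(f = 0.25, alpha = 0.05, power = 0.80, k_groups = 3)$N
#> 159
chi_square_contingency(matrix(c(52, 44, 32, 19, 18, 10), ncol = 2))$p
#> 0.8401957
```

## Full pipeline and CLI

```r
run_pipeline(run_config(generator = cfg, seed = 1), "results/")
```

writes tidy CSVs (components, topographic correlations, trajectories,
state templates, transitions, statistics) plus `summary.json` with MD5
checksums — reruns with the same seed are byte-identical. The same stages
are available from the shell via `inst/cli/erpdyn`
(`simulate`, `run`, `stats` subcommands, JSON configs).

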
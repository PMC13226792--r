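# Synthetic oddball-ERP cohort generator.
#
# The generator plants K orthonormal, channel-mean-centered scalp templates
# and drives them with group x condition specific activation time courses
# (piecewise-constant over six 100-ms windows, linearly ramped at window
# boundaries), adds per-trial latency jitter and i.i.d. Gaussian sensor
# noise, and links a per-subject latent trajectory-separation scalar to
# simulated clinical subscales. Ground truth is returned so downstream
# recovery can be tested.

#' Default per-window activation coefficients for one group
#'
#' Standard-condition responses load mainly on states 1-2 (an early
#' negative-going complex); target responses add a late load on states 3-4
#' (a P300-like excursion). `excursion` scales the whole response;
#' `separation` scales the target-minus-standard deviation only.
#'
#' @param excursion Multiplicative gain on both conditions.
#' @param separation Multiplicative gain on the target-standard difference.
#' @return List with 6 x n_states matrices `standard` and `target` (uV).
#' @export
default_activation_curves <- function(excursion = 1, separation = 1) {
  std <- matrix(c(
    2.0, 0.0, 0.0, 0.0,
    6.0, 2.0, 0.0, 0.0,
    4.0, 5.0, 0.5, 0.0,
    2.0, 3.0, 1.0, 0.5,
    1.0, 2.0, 1.0, 0.5,
    0.5, 1.0, 0.5, 0.0), nrow = 6, byrow = TRUE)
  dev <- matrix(c(
    0.0, 0.0, 0.0, 0.0,
    0.0, 1.0, 1.0, 0.5,
    0.0, 1.0, 3.5, 2.0,
    0.0, 0.5, 5.5, 3.5,
    0.0, 0.0, 4.5, 3.0,
    0.0, 0.0, 2.0, 1.0), nrow = 6, byrow = TRUE)
  dimnames(std) <- dimnames(dev) <-
    list(paste0("T", 1:6), paste0("state", 1:4))
  list(standard = excursion * std,
       target   = excursion * (std + separation * dev))
}

#' Identifiable activation curves for template-recovery tests
#'
#' Each state is active in time windows where no other state is, so the
#' states' activation time courses are exactly uncorrelated over the
#' epoch and PCA on a zero-noise cohort recovers the planted templates
#' individually (not just their span). Activation energies are distinct,
#' fixing the component order. Use with `ramp_ms = 0`; boundary ramps
#' reintroduce small cross-covariances.
#'
#' @param gain Multiplicative gain applied to both conditions.
#' @return List with `standard` and `target` 6 x 4 matrices (uV).
#' @export
recovery_activation_curves <- function(gain = 1) {
  std <- matrix(c(
    8, 0, 0, 0,
    8, 0, 0, 0,
    0, 6, 0, 0,
    0, 0, 5, 0,
    0, 0, 0, 4,
    0, 0, 0, 4), nrow = 6, byrow = TRUE)
  dimnames(std) <- list(paste0("T", 1:6), paste0("state", 1:4))
  list(standard = gain * std, target = gain * 1.25 * std)
}

#' Default clinical-subscale parameters
#'
#' Group means and SDs follow the published demographics of a comparable
#' TD / ADHD-I / ADHD-C cohort; loadings link the per-subject latent
#' separation scalar to the attention-related subscales (higher separation,
#' i.e. more TD-like dynamics, predicts lower symptom scores).
#'
#' @return A list with `mean` and `sd` (subscale x group matrices) and
#'   `loading` (per-subscale coefficient on the latent separation scalar).
#' @export
default_clinical_params <- function() {
  subs <- c("snap_attention", "snap_hyperactive",
            "conners_hyperactivity_index", "weiss_family")
  grp <- c("TD", "ADHD-I", "ADHD-C")
  mean <- matrix(c(
    1.12, 1.74, 2.03,
    0.68, 0.87, 1.70,
    0.73, 1.14, 1.42,
    0.32, 0.60, 0.82), nrow = 4, byrow = TRUE,
    dimnames = list(subs, grp))
  sd <- matrix(c(
    0.46, 0.60, 0.62,
    0.50, 0.55, 0.53,
    0.31, 0.38, 0.49,
    0.26, 0.34, 0.48), nrow = 4, byrow = TRUE,
    dimnames = list(subs, grp))
  loading <- c(snap_attention = -0.5, snap_hyperactive = 0,
               conners_hyperactivity_index = -0.3, weiss_family = 0)
  list(mean = mean, sd = sd, loading = loading)
}

#' Loading needed for a target latent-subscale correlation
#'
#' For subscale = mean + loading * latent + noise, returns the loading that
#' yields population Pearson r between subscale and latent.
#'
#' @param r Target correlation in (-1, 1).
#' @param sd_latent SD of the latent scalar.
#' @param sd_noise SD of the additive subscale noise.
#' @return The loading coefficient.
#' @export
loading_for_r <- function(r, sd_latent, sd_noise) {
  stopifnot_scalar_number(r, "r")
  if (abs(r) >= 1) abort_invalid("|r| must be < 1")
  r / sqrt(1 - r^2) * sd_noise / sd_latent
}

#' Build a generator configuration
#'
#' Defaults encode the emulated acquisition: 19-channel 10-20 montage at
#' 500 Hz, epochs -200..800 ms, 278 standard / 80 target trials, four
#' planted states, 1 uV trial noise and 10 ms latency jitter, and group
#' geometries in which ADHD-I shows reduced standard/target trajectory
#' separation and ADHD-C amplified excursions relative to TD.
#'
#' @param n_per_group Subjects per group (TD, ADHD-I, ADHD-C).
#' @param n_channels,channel_names Montage size and ordered labels.
#' @param fs Sampling rate in Hz.
#' @param epoch_window Epoch extent in ms relative to stimulus onset.
#' @param n_standard,n_target Trial counts per condition.
#' @param n_states Number of planted templates.
#' @param activation_curves Named list (per group) of lists with `standard`
#'   and `target` 6 x n_states coefficient matrices (uV per window T1-T6).
#'   `NULL` builds the built-in TD / ADHD-I / ADHD-C geometries from
#'   [default_activation_curves()], truncated to `n_states` columns.
#' @param ramp_ms Linear ramp length at window boundaries (0 = piecewise
#'   constant at sample resolution).
#' @param trial_noise_sd Per-channel, per-sample Gaussian noise SD (uV).
#' @param latency_jitter_sd Per-trial latency shift SD (ms), truncated at
#'   3 SD.
#' @param subject_sd SD of the per-subject multiplicative excursion and
#'   separation modifiers (both centered at 1).
#' @param amplitude_range Declared bounds (uV) for activation coefficients;
#'   violated bounds trigger a warning, not an error.
#' @param sex_prob_m Per-group probability of male sex.
#' @param clinical_params See [default_clinical_params()].
#' @param seed Master seed for the cohort.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_per_group = 15,
                             n_channels = 19,
                             channel_names = NULL,
                             fs = 500,
                             epoch_window = c(-200, 800),
                             n_standard = 278,
                             n_target = 80,
                             n_states = 4,
                             activation_curves = NULL,
                             ramp_ms = 20,
                             trial_noise_sd = 1,
                             latency_jitter_sd = 10,
                             subject_sd = 0.1,
                             amplitude_range = c(0, 10),
                             sex_prob_m = c("TD" = 52 / 71, "ADHD-I" = 44 / 62,
                                            "ADHD-C" = 32 / 42),
                             clinical_params = default_clinical_params(),
                             seed = 1L) {
  if (is.null(channel_names))
    channel_names <- if (n_channels == 19) montage_1020_19()
                     else sprintf("Ch%02d", seq_len(n_channels))
  if (is.null(activation_curves)) {
    if (n_states > 4)
      abort_invalid("default activation curves cover at most 4 states; supply activation_curves")
    # built-in group geometries, truncated to the requested state count
    activation_curves <- lapply(
      list("TD" = c(1.0, 1.0), "ADHD-I" = c(0.8, 0.4), "ADHD-C" = c(1.5, 1.0)),
      function(g) lapply(default_activation_curves(g[1], g[2]),
                         function(m) m[, seq_len(n_states), drop = FALSE]))
  }
  cfg <- list(n_per_group = n_per_group, n_channels = n_channels,
              channel_names = channel_names, fs = fs,
              epoch_window = epoch_window, n_standard = n_standard,
              n_target = n_target, n_states = n_states,
              activation_curves = activation_curves, ramp_ms = ramp_ms,
              trial_noise_sd = trial_noise_sd,
              latency_jitter_sd = latency_jitter_sd,
              subject_sd = subject_sd, amplitude_range = amplitude_range,
              sex_prob_m = sex_prob_m, clinical_params = clinical_params,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_states > cfg$n_channels - 1)
    abort_invalid("n_states must be <= n_channels - 1")
  if (cfg$fs <= 0) abort_invalid("fs must be positive")
  if (!(cfg$epoch_window[1] <= 0 && cfg$epoch_window[2] >= 600))
    abort_invalid("epoch window must span at least 0..600 ms")
  if (cfg$n_standard <= 0 || cfg$n_target <= 0)
    abort_invalid("trial counts must be positive")
  if (cfg$trial_noise_sd < 0) abort_invalid("trial_noise_sd must be >= 0")
  if (cfg$ramp_ms < 0 || cfg$ramp_ms >= 100)
    abort_invalid("ramp_ms must lie in [0, 100)")
  if (length(cfg$channel_names) != cfg$n_channels)
    abort_invalid("channel_names length must equal n_channels")
  for (g in c("TD", "ADHD-I", "ADHD-C")) {
    ac <- cfg$activation_curves[[g]]
    if (is.null(ac) || is.null(ac$standard) || is.null(ac$target))
      abort_invalid(sprintf("activation_curves missing group %s", g))
    for (m in list(ac$standard, ac$target)) {
      if (!all(dim(m) == c(6, cfg$n_states)))
        abort_invalid("activation curve matrices must be 6 x n_states")
      if (any(abs(m) > max(abs(cfg$amplitude_range)) + 1e-9))
        warning("activation coefficients exceed declared amplitude_range")
    }
  }
  invisible(cfg)
}

#' Generate orthonormal channel-mean-centered state templates
#'
#' Templates are random directions in the zero-sum (average-referenced)
#' subspace, orthonormalized by QR decomposition. Each template has zero
#' mean across channels, unit Euclidean norm, and is orthogonal to the
#' others; the element of largest magnitude is made positive so output is
#' deterministic given the seed.
#'
#' @param n_channels Number of electrodes.
#' @param n_states Number of templates, at most `n_channels - 1`.
#' @param seed RNG seed.
#' @return An `n_states x n_channels` matrix of template loadings.
#' @export
make_state_templates <- function(n_channels, n_states, seed = 1L) {
  if (n_states < 1 || n_states > n_channels - 1)
    abort_invalid("need 1 <= n_states <= n_channels - 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 101L))
  raw <- matrix(rnorm(n_states * n_channels), nrow = n_channels)
  raw <- sweep(raw, 2L, colMeans(raw)) # project into zero-sum subspace
  q <- qr.Q(qr(raw))[, seq_len(n_states), drop = FALSE]
  q <- sweep(q, 2L, colMeans(q)) # numerical re-centering
  q <- sweep(q, 2L, sqrt(colSums(q^2)), "/")
  tmpl <- t(q)
  sgn <- apply(tmpl, 1L, function(v) sign(v[which.max(abs(v))]))
  tmpl * sgn
}

# Save/restore the global RNG state so generator calls are reproducible
# without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Evaluate one state's activation curve at arbitrary times (ms).
# coeffs: length-6 per-window values; zero outside [0, 600 + ramp).
activation_at <- function(coeffs, t_ms, ramp_ms) {
  if (ramp_ms == 0) {
    idx <- findInterval(t_ms, seq(0, 600, by = 100))
    vals <- c(0, coeffs, 0)
    return(vals[idx + 1L])
  }
  kx <- c(0, as.vector(rbind(seq(0, 500, 100) + ramp_ms, seq(100, 600, 100))),
          600 + ramp_ms)
  ky <- c(0, rep(coeffs, each = 2L), 0)
  out <- numeric(length(t_ms))
  inside <- t_ms > 0 & t_ms < 600 + ramp_ms
  if (any(inside))
    out[inside] <- approx(kx, ky, xout = t_ms[inside], rule = 2)$y
  out
}

#' Simulate one subject/condition's epoched EEG
#'
#' Each trial is `sum_k a_k(t - delta) * template_k + noise`, where `a_k`
#' is the group x condition activation curve scaled by the subject's latent
#' excursion/separation modifiers, `delta` a per-trial latency shift
#' (Normal, truncated at 3 SD), and noise i.i.d. Gaussian per channel and
#' sample. The same `subject_seed` yields identical latent modifiers for
#' both conditions of a subject; trial noise streams differ per condition.
#'
#' @param config A [generator_config()].
#' @param group One of "TD", "ADHD-I", "ADHD-C".
#' @param condition "standard" or "target".
#' @param templates Planted templates from [make_state_templates()].
#' @param subject_seed Per-subject seed.
#' @param subject_id Identifier stored in the result.
#' @return An `epoch_set` (channels x samples x trials).
#' @export
simulate_subject <- function(config, group, condition, templates,
                             subject_seed, subject_id = "S01") {
  if (!group %in% c("TD", "ADHD-I", "ADHD-C"))
    abort_invalid(sprintf("unknown group '%s'", group))
  if (!condition %in% c("standard", "target"))
    abort_invalid(sprintf("unknown condition '%s'", condition))
  lat <- subject_latents(config, subject_seed)
  curves <- subject_curves(config, group, lat)
  cm <- curves[[condition]] # 6 x n_states
  n_trials <- if (condition == "standard") config$n_standard else config$n_target

  fs <- config$fs
  t_ms <- seq(config$epoch_window[1], config$epoch_window[2] - 1000 / fs,
              by = 1000 / fs)
  n_samp <- length(t_ms)
  n_ch <- config$n_channels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  cond_code <- if (condition == "standard") 1L else 2L
  set.seed(derive_seed(subject_seed, 1000L + cond_code))
  if (config$latency_jitter_sd > 0) {
    delta <- rnorm(n_trials, 0, config$latency_jitter_sd)
    lim <- 3 * config$latency_jitter_sd
    delta <- pmin(pmax(delta, -lim), lim)
    if (max(600 + config$ramp_ms + delta) > config$epoch_window[2]) {
      warning("latency jitter shifts activation past the epoch end; clipped")
    }
  } else delta <- numeric(n_trials)

  data <- array(0, dim = c(n_ch, n_samp, n_trials))
  for (tr in seq_len(n_trials)) {
    a <- vapply(seq_len(config$n_states),
                function(k) activation_at(cm[, k], t_ms - delta[tr],
                                          config$ramp_ms),
                numeric(n_samp)) # n_samp x n_states
    data[, , tr] <- t(templates) %*% t(a) # n_ch x n_samp
  }
  if (config$trial_noise_sd > 0)
    data <- data + array(rnorm(length(data), 0, config$trial_noise_sd),
                         dim = dim(data))
  epoch_set(data, channel_names = config$channel_names, fs = fs,
            t0_offset_ms = config$epoch_window[1], subject_id = subject_id,
            group = group, condition = condition)
}

subject_latents <- function(config, subject_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(subject_seed, 7L))
  exc <- 1 + rnorm(1, 0, config$subject_sd)
  sep <- 1 + rnorm(1, 0, config$subject_sd)
  exc <- max(exc, 0.05); sep <- max(sep, 0.05)
  list(excursion = exc, separation = sep, latent = exc * sep)
}

subject_curves <- function(config, group, lat) {
  ac <- config$activation_curves[[group]]
  dev <- ac$target - ac$standard
  list(standard = lat$excursion * ac$standard,
       target = lat$excursion * (ac$standard + lat$separation * dev))
}

#' Simulate a full cohort with clinical covariates and ground truth
#'
#' Generates `3 * n_per_group` subjects (both conditions each), a clinical
#' table whose subscales are group mean + loading x (subject latent
#' separation scalar, centered at its group expectation of 1) + Gaussian
#' noise truncated at 0, and the ground truth actually used.
#'
#' @param config A [generator_config()].
#' @param return `"epochs"` keeps raw epoch sets (memory heavy);
#'   `"erps"` stores only preprocessed condition averages.
#' @return List with `epochs` (or `erps`), `clinical` (data.frame) and
#'   `ground_truth` (templates, per-subject curves and latent scalars).
#' @export
simulate_cohort <- function(config, return = c("epochs", "erps")) {
  return <- match.arg(return)
  validate_generator_config(config)
  templates <- make_state_templates(config$n_channels, config$n_states,
                                    seed = config$seed)
  groups <- c("TD", "ADHD-I", "ADHD-C")
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", sub("-", "", g), seq_len(config$n_per_group))))
  grp_of <- rep(groups, each = config$n_per_group)

  epochs <- list()
  latents <- numeric(length(ids)); names(latents) <- ids
  subj_curves <- list()
  for (i in seq_along(ids)) {
    sseed <- derive_seed(config$seed, 50000L + i)
    lat <- subject_latents(config, sseed)
    latents[i] <- lat$latent
    subj_curves[[ids[i]]] <- subject_curves(config, grp_of[i], lat)
    for (cond in c("standard", "target")) {
      es <- simulate_subject(config, grp_of[i], cond, templates, sseed,
                             subject_id = ids[i])
      key <- paste(ids[i], cond, sep = "_")
      if (return == "epochs") {
        epochs[[key]] <- es
      } else {
        epochs[[key]] <- condition_average(
          preprocess_epochs(es, filter = FALSE))
      }
    }
  }

  clinical <- build_clinical_table(config, ids, grp_of, latents)
  gt <- list(templates = templates, latents = latents,
             curves = subj_curves,
             clinical_loading = config$clinical_params$loading)
  out <- list(clinical = clinical, ground_truth = gt, config = config)
  out[[if (return == "epochs") "epochs" else "erps"]] <- epochs
  out
}

build_clinical_table <- function(config, ids, grp_of, latents) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 90001L))
  cp <- config$clinical_params
  n <- length(ids)
  demo_mean <- list(age = c("TD" = 9.01, "ADHD-I" = 9.59, "ADHD-C" = 8.74),
                    iq = c("TD" = 88.2, "ADHD-I" = 91.37, "ADHD-C" = 92.85))
  demo_sd <- list(age = c("TD" = 1.86, "ADHD-I" = 2.09, "ADHD-C" = 1.88),
                  iq = c("TD" = 14.55, "ADHD-I" = 11.67, "ADHD-C" = 12.69))
  df <- data.frame(
    subject_id = ids, group = grp_of,
    sex = ifelse(runif(n) < config$sex_prob_m[grp_of], "M", "F"),
    age = pmax(6, rnorm(n, demo_mean$age[grp_of], demo_sd$age[grp_of])),
    iq = pmax(60, rnorm(n, demo_mean$iq[grp_of], demo_sd$iq[grp_of])),
    latent_separation = latents,
    stringsAsFactors = FALSE)
  # latent scalar is centered at 1; loadings act on the deviation so group
  # means stay at their configured values
  for (s in rownames(cp$mean)) {
    val <- cp$mean[s, grp_of] + cp$loading[s] * (latents - 1) +
      rnorm(n, 0, cp$sd[s, grp_of])
    df[[s]] <- pmax(0, val)
  }
  rownames(df) <- NULL
  df
}
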
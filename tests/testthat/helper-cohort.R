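# Shared fixture builders. Everything is generated in code; "tiny"
# configurations keep the montage and epoch small so unit tests stay fast.

tiny_config <- function(...) {
  defaults <- list(n_per_group = 2, n_channels = 5,
                   channel_names = c("Fz", "Cz", "Pz", "O1", "O2"),
                   fs = 100, n_standard = 8, n_target = 8, n_states = 3,
                   activation_curves = list(
                     "TD" = tiny_curves(1, 1),
                     "ADHD-I" = tiny_curves(0.8, 0.4),
                     "ADHD-C" = tiny_curves(1.5, 1)),
                   trial_noise_sd = 0.5, latency_jitter_sd = 0,
                   subject_sd = 0, ramp_ms = 0, seed = 42L)
  do.call(generator_config, modifyList(defaults, list(...)))
}

tiny_curves <- function(excursion = 1, separation = 1) {
  full <- default_activation_curves(excursion, separation)
  lapply(full, function(m) m[, 1:3])
}

# deterministic epoch_set built from explicit values
manual_epochs <- function(data, fs = 100, t0 = -200,
                          channel_names = NULL, ...) {
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[1]))
  epoch_set(data, channel_names = channel_names, fs = fs,
            t0_offset_ms = t0, ...)
}

# a topo_sequence with arbitrary topography columns
manual_toposeq <- function(topos, ...) {
  topo_sequence(topos, channel_names = paste0("ch", seq_len(nrow(topos))),
                ...)
}

# noiseless single-subject ERP driven by given templates and 6 x K curves
template_erp <- function(templates, curves, fs = 500, ramp_ms = 0,
                         condition = "standard", group = "TD") {
  t_ms <- seq(-200, 798, by = 1000 / fs)
  a <- vapply(seq_len(ncol(curves)),
              function(k) erpdyn:::activation_at(curves[, k], t_ms, ramp_ms),
              numeric(length(t_ms)))
  erp(t(templates) %*% t(a), channel_names = paste0("ch", seq_len(ncol(templates))),
      fs = fs, t0_offset_ms = -200, subject_id = "S1", group = group,
      condition = condition, n_trials_used = 1L)
}

# small cohort of ERPs (preprocessed averages), 19 channels at 500 Hz
erp_cohort <- function(n_per_group = 3, n_standard = 10, n_target = 10,
                       trial_noise_sd = 1, seed = 7L, ...) {
  cfg <- generator_config(n_per_group = n_per_group, n_standard = n_standard,
                          n_target = n_target, trial_noise_sd = trial_noise_sd,
                          seed = seed, ...)
  simulate_cohort(cfg, return = "erps")
}
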
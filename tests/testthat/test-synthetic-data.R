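# Synthetic-cohort generator: template construction, signal model,
# cohort assembly, clinical covariate linkage.

test_that("state templates are orthonormal, channel-centered, deterministic", {
  tmpl <- make_state_templates(19, 4, seed = 1)
  expect_equal(dim(tmpl), c(4, 19))
  expect_lt(max(abs(rowMeans(tmpl))), 1e-10)
  expect_lt(max(abs(tmpl %*% t(tmpl) - diag(4))), 1e-10)
  expect_identical(tmpl, make_state_templates(19, 4, seed = 1))
  expect_false(identical(tmpl, make_state_templates(19, 4, seed = 2)))

  small <- make_state_templates(3, 2, seed = 9)
  expect_lt(abs(sum(small[1, ] * small[2, ])), 1e-10)
  expect_lt(max(abs(rowMeans(small))), 1e-10)

  expect_error(make_state_templates(4, 4), class = "erpdyn_invalid_argument")
})

test_that("zero-noise zero-jitter subjects are deterministic and recover curves", {
  cfg <- tiny_config(trial_noise_sd = 0)
  tmpl <- make_state_templates(cfg$n_channels, cfg$n_states, seed = cfg$seed)
  es <- simulate_subject(cfg, "TD", "standard", tmpl, subject_seed = 11)

  # every trial identical; average equals any single trial
  for (tr in 2:dim(es$data)[3])
    expect_equal(es$data[, , tr], es$data[, , 1])
  avg <- condition_average(es)
  expect_equal(avg$data, es$data[, , 1])
  expect_equal(avg$n_trials_used, dim(es$data)[3])

  # pre-stimulus activation exactly zero
  t_ms <- seq(cfg$epoch_window[1], cfg$epoch_window[2] - 1000 / cfg$fs,
              by = 1000 / cfg$fs)
  expect_true(all(avg$data[, t_ms < 0] == 0))

  # window means projected back onto templates reproduce the curves
  ts <- window_means(avg)
  recovered <- t(tmpl %*% ts$topos)
  expect_lt(max(abs(recovered - cfg$activation_curves$TD$standard)), 1e-9)
})

test_that("unknown group or condition are rejected", {
  cfg <- tiny_config()
  tmpl <- make_state_templates(cfg$n_channels, cfg$n_states, seed = 1)
  expect_error(simulate_subject(cfg, "XX", "standard", tmpl, 1),
               class = "erpdyn_invalid_argument")
  expect_error(simulate_subject(cfg, "TD", "oddball", tmpl, 1),
               class = "erpdyn_invalid_argument")
})

test_that("trial averaging obeys the 1/sqrt(n) law", {
  # Monte-Carlo over replicate cohorts: SD of the trial-averaged value at a
  # fixed channel/sample across replicates ~ noise_sd / sqrt(n_trials).
  n_trials <- 278
  cfg <- tiny_config(n_standard = n_trials, trial_noise_sd = 1,
                     n_per_group = 1)
  tmpl <- make_state_templates(cfg$n_channels, cfg$n_states, seed = 1)
  vals <- vapply(seq_len(100), function(rep) {
    es <- simulate_subject(cfg, "TD", "standard", tmpl, subject_seed = rep)
    mean(es$data[2, 50, ]) # fixed (channel, sample), averaged over trials
  }, numeric(1))
  expect_equal(sd(vals), 1 / sqrt(n_trials), tolerance = 0.2)
})

test_that("doubling trial noise leaves the trial-average expectation unbiased", {
  cfg1 <- tiny_config(trial_noise_sd = 1, n_standard = 20, n_per_group = 1)
  cfg2 <- tiny_config(trial_noise_sd = 2, n_standard = 20, n_per_group = 1)
  tmpl <- make_state_templates(cfg1$n_channels, cfg1$n_states, seed = 1)
  noiseless <- simulate_subject(tiny_config(trial_noise_sd = 0), "TD",
                                "standard", tmpl, subject_seed = 1)$data[, , 1]
  grand <- function(cfg) {
    acc <- 0
    for (rep in seq_len(100))
      acc <- acc + rowMeans(simulate_subject(cfg, "TD", "standard", tmpl,
                                             subject_seed = rep)$data,
                            dims = 2)
    acc / 100
  }
  # both noise levels agree with the noiseless expectation within MC error
  se1 <- 1 / sqrt(20 * 100); se2 <- 2 / sqrt(20 * 100)
  expect_lt(max(abs(grand(cfg1) - noiseless)), 6 * se1)
  expect_lt(max(abs(grand(cfg2) - noiseless)), 6 * se2)
})

test_that("cohorts have the right shape and are seed-reproducible", {
  cfg <- tiny_config(n_per_group = 2)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$clinical), 6)
  expect_length(co$epochs, 12)
  expect_setequal(unique(co$clinical$group), c("TD", "ADHD-I", "ADHD-C"))

  co2 <- simulate_cohort(cfg)
  expect_identical(co$epochs, co2$epochs)
  expect_identical(co$clinical, co2$clinical)
})

test_that("clinical loadings drive the latent-subscale correlation", {
  cfg <- tiny_config(subject_sd = 0.1)
  # empirical SD of the latent scalar under subject_sd = 0.1
  lat_sd <- sd(vapply(1:2000, function(i)
    erpdyn:::subject_latents(cfg, i)$latent, numeric(1)))

  # zero loading: |r| small at n = 60
  run_rep <- function(loading, rep) {
    set.seed(rep)
    lat <- vapply(seq_len(60), function(i)
      erpdyn:::subject_latents(cfg, derive_seed(rep, i))$latent, numeric(1))
    noise_sd <- 0.4
    y <- 1 + loading * (lat - 1) + rnorm(60, 0, noise_sd)
    cor(lat, y)
  }
  expect_lt(abs(run_rep(0, 1)), 0.3)

  # loading targeting population r = 0.6: recovered within +/-0.2 in >= 95%
  lam <- loading_for_r(0.6, lat_sd, 0.4)
  rs <- vapply(seq_len(200), function(rep) run_rep(lam, rep), numeric(1))
  expect_gte(mean(abs(rs - 0.6) <= 0.2), 0.95)
})

test_that("cohort clinical table reflects configured loadings end to end", {
  cp <- default_clinical_params()
  cp$loading["snap_attention"] <- -3 # strong planted link
  co <- simulate_cohort(tiny_config(n_per_group = 10, subject_sd = 0.15,
                                    clinical_params = cp, n_standard = 2,
                                    n_target = 2), return = "erps")
  td <- co$clinical[co$clinical$group == "TD", ]
  expect_lt(cor(td$latent_separation, td$snap_attention), 0)
})

test_that("config invariants are enforced", {
  expect_error(tiny_config(n_states = 5), class = "erpdyn_invalid_argument")
  expect_error(tiny_config(fs = -1), class = "erpdyn_invalid_argument")
  expect_error(tiny_config(epoch_window = c(-200, 500)),
               class = "erpdyn_invalid_argument")
  expect_error(tiny_config(n_standard = 0), class = "erpdyn_invalid_argument")
  expect_error(tiny_config(trial_noise_sd = -0.1),
               class = "erpdyn_invalid_argument")
})
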
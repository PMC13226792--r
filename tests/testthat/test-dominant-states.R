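# Dominant-state extraction and time-resolved projections.

recovery_cohort <- function(n_per_group = 2, noise = 0, seed = 13) {
  rc <- recovery_activation_curves()
  cfg <- generator_config(
    n_per_group = n_per_group, n_standard = 6, n_target = 6,
    trial_noise_sd = noise, latency_jitter_sd = 0, subject_sd = 0,
    ramp_ms = 0, seed = seed,
    activation_curves = list("TD" = rc, "ADHD-I" = rc, "ADHD-C" = rc))
  simulate_cohort(cfg, return = "erps")
}

test_that("noiseless planted cohorts are recovered exactly", {
  co <- recovery_cohort()
  basis <- extract_states(group_average_erps(co$erps), K = 4)
  expect_equal(sum(basis$explained_var[1:4]), 1, tolerance = 1e-9)
  cc <- abs(cor(t(basis$templates), t(co$ground_truth$templates)))
  expect_true(all(apply(cc, 2, max) >= 0.999))
  # rows orthonormal, centered
  expect_lt(max(abs(basis$templates %*% t(basis$templates) - diag(4))), 1e-9)
  expect_lt(max(abs(rowMeans(basis$templates))), 1e-9)
})

test_that("K = 1 on single-template data explains everything", {
  tmpl <- make_state_templates(8, 1, seed = 3)
  curves <- matrix(c(1, 3, 5, 4, 2, 1), 6, 1)
  e <- template_erp(tmpl, curves)
  b <- extract_states(list(e), K = 1)
  expect_equal(b$explained_var[1], 1, tolerance = 1e-9)
  expect_error(extract_states(list(e), K = 3),
               class = "erpdyn_invalid_argument")
})

test_that("timecourse projection is the centered dot product", {
  tmpl <- make_state_templates(10, 4, seed = 4)
  b <- structure(list(templates = tmpl, explained_var = rep(0.25, 4), K = 4,
                      channel_names = paste0("ch", 1:10),
                      window_ms = c(0, 600)), class = "state_basis")
  rownames(b$templates) <- paste0("PC", 1:4)

  # ERP equal to 3 x template 2 (plus channel constant) at all samples
  n <- 500
  e <- erp(matrix(3 * tmpl[2, ] + 7, 10, n), channel_names = b$channel_names,
           fs = 500, t0_offset_ms = -200)
  tc <- project_timecourse(e, b)
  expect_equal(dim(tc$coeffs), c(4, 300))
  expect_true(all(abs(tc$coeffs[2, ] - 3) < 1e-9))
  expect_true(all(abs(tc$coeffs[-2, ]) < 1e-9))

  z <- erp(matrix(0, 10, n), channel_names = b$channel_names, fs = 500,
           t0_offset_ms = -200)
  expect_equal(max(abs(project_timecourse(z, b)$coeffs)), 0)

  set.seed(14)
  r <- erp(matrix(rnorm(10 * n), 10, n), channel_names = b$channel_names,
           fs = 500, t0_offset_ms = -200)
  tcr <- project_timecourse(r, b)
  t_ms <- -200 + (0:(n - 1)) * 2
  sel <- t_ms >= 0 & t_ms < 600
  centered <- sweep(r$data[, sel], 2, colMeans(r$data[, sel]))
  expect_lt(max(abs(tcr$coeffs - tmpl %*% centered)), 1e-12)
})

test_that("projection differences are antisymmetric and shape-checked", {
  a <- list(coeffs = matrix(1:12, 4, 3))
  b <- list(coeffs = matrix(0, 4, 3))
  expect_equal(projection_difference(a, a), matrix(0, 4, 3))
  expect_equal(projection_difference(a, b), a$coeffs)
  expect_equal(projection_difference(b, a), -a$coeffs)
  bad <- list(coeffs = matrix(0, 4, 5))
  expect_error(projection_difference(a, bad),
               class = "erpdyn_invalid_argument")
})

test_that("template-group correlations ignore polarity", {
  tmpl <- make_state_templates(12, 4, seed = 5)
  b <- structure(list(templates = tmpl, K = 4,
                      channel_names = paste0("ch", 1:12),
                      window_ms = c(0, 600)), class = "state_basis")
  rownames(b$templates) <- paste0("PC", 1:4)
  topos <- matrix(rnorm(12 * 6), 12, 6)
  topos[, 2] <- -tmpl[3, ]
  ts <- manual_toposeq(topos)
  res <- template_group_correlation(b, ts)
  expect_equal(res$r[3, 2], 1, tolerance = 1e-9)
  expect_true(res$significant[3, 2])
  # orthogonal template ~ near-zero |r|
  expect_lt(res$r[1, 2], 0.05 + abs(cor(tmpl[1, ], tmpl[3, ])))

  # brute-force |r| agreement on the random windows
  for (k in 1:4) for (w in c(1, 3, 6))
    expect_equal(res$r[k, w], abs(cor(tmpl[k, ], topos[, w])),
                 tolerance = 1e-12)
})

test_that("subject variance fractions partition the response energy", {
  tmpl <- make_state_templates(10, 4, seed = 6)
  b <- structure(list(templates = tmpl, K = 4,
                      channel_names = paste0("ch", 1:10),
                      window_ms = c(0, 600)), class = "state_basis")
  rownames(b$templates) <- paste0("PC", 1:4)

  curves <- cbind(c(1, 3, 5, 4, 2, 1), matrix(0, 6, 3))
  e1 <- template_erp(tmpl, curves)
  e1$channel_names <- b$channel_names
  fr <- subject_variance_explained(e1, b)
  expect_equal(unname(fr), c(1, 0, 0, 0), tolerance = 1e-9)

  # response orthogonal to all templates
  extra <- make_state_templates(10, 5, seed = 6)[5, ]
  e2 <- e1
  e2$data <- outer(extra, erpdyn:::activation_at(curves[, 1],
                                                 seq(-200, 798, 2), 0))
  fr2 <- subject_variance_explained(e2, b)
  expect_lt(max(fr2), 1e-9)

  # random ERP: fractions equal the brute-force ratio and sum <= 1
  set.seed(15)
  e3 <- e1
  e3$data <- matrix(rnorm(10 * 500), 10, 500)
  fr3 <- subject_variance_explained(e3, b)
  t_ms <- seq(-200, 798, 2)
  sel <- t_ms >= 0 & t_ms < 600
  centered <- sweep(e3$data[, sel], 2, colMeans(e3$data[, sel]))
  brute <- rowSums((tmpl %*% centered)^2) / sum(centered^2)
  expect_lt(max(abs(fr3 - brute)), 1e-12)
  expect_lte(sum(fr3), 1)

  z <- e1; z$data[] <- 0
  expect_error(subject_variance_explained(z, b),
               class = "erpdyn_undefined_value")
})

test_that("projections are invariant to channel constants; extraction to sample order", {
  co <- recovery_cohort()
  gavg <- group_average_erps(co$erps)
  b <- extract_states(gavg, K = 4)
  e <- co$erps[[1]]
  tc1 <- project_timecourse(e, b)
  e2 <- e; e2$data <- e$data + 4.2
  tc2 <- project_timecourse(e2, b)
  expect_equal(tc1$coeffs, tc2$coeffs, tolerance = 1e-9)

  # permuting the concatenation order changes templates at most by sign
  b2 <- extract_states(rev(gavg), K = 4)
  agreement <- abs(rowSums(b$templates * b2$templates))
  expect_true(all(agreement > 1 - 1e-9))
})
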
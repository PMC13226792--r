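# Pipeline driver: simulate -> preprocess -> ERP components -> topography
# dynamics -> trajectories -> dominant states -> transitions ->
# classification -> group statistics, with one declarative configuration
# and a master seed split per stage.

#' Build a pipeline run configuration
#'
#' @param generator A [generator_config()] (used when `simulate = TRUE`).
#' @param simulate Generate the cohort instead of reading `in_dir`.
#' @param in_dir Epoch-container directory when `simulate = FALSE`.
#' @param filter,reject_uv,baseline_window_ms Preprocessing options.
#' @param K Number of dominant states.
#' @param alpha Per-sample significance for state assignment.
#' @param folds,repeats Cross-validation layout.
#' @param boot_iterations,boot_n_per_group Bootstrap settings.
#' @param window_average_features Use K x 6 window-mean features for
#'   classification instead of the full K x T flattening.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(n_per_group = 5,
                                                    n_standard = 20,
                                                    n_target = 20),
                       simulate = TRUE, in_dir = NULL, filter = FALSE,
                       reject_uv = 500, baseline_window_ms = c(-200, 0),
                       K = 4, alpha = 0.05, folds = 10, repeats = 20,
                       boot_iterations = 100, boot_n_per_group = 15,
                       window_average_features = TRUE, seed = 1L) {
  structure(list(generator = generator, simulate = simulate, in_dir = in_dir,
                 filter = filter, reject_uv = reject_uv,
                 baseline_window_ms = baseline_window_ms, K = K,
                 alpha = alpha, folds = folds, repeats = repeats,
                 boot_iterations = boot_iterations,
                 boot_n_per_group = boot_n_per_group,
                 window_average_features = window_average_features,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or on-disk cohort and writes tidy
#' CSV/JSON outputs plus a summary with per-file MD5 checksums, so a rerun
#' with the same configuration and seed is verifiably identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_msg <- function(...) message(sprintf(...))

  # --- stage 1: cohort -------------------------------------------------
  if (config$simulate) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 1L)
    cohort <- simulate_cohort(gen)
    epochs <- cohort$epochs
    clinical <- cohort$clinical
    write.csv(clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(templates = cohort$ground_truth$templates,
           latents = cohort$ground_truth$latents),
      file.path(out_dir, "ground_truth.json"), digits = NA)
    log_msg("simulate: %d subjects, %d epoch sets", nrow(clinical),
            length(epochs))
  } else {
    recs <- list_container(config$in_dir)
    if (!nrow(recs)) abort_format("no records found in in_dir")
    epochs <- list()
    for (i in seq_len(nrow(recs))) {
      key <- paste(recs$subject_id[i], recs$condition[i], sep = "_")
      epochs[[key]] <- read_container(config$in_dir, recs$subject_id[i],
                                      recs$condition[i])
    }
    clin_path <- file.path(config$in_dir, "clinical.csv")
    clinical <- if (file.exists(clin_path))
      read.csv(clin_path, stringsAsFactors = FALSE) else NULL
    log_msg("load: %d epoch sets", length(epochs))
  }

  # --- stage 2: preprocess + average ----------------------------------
  erps <- list()
  dropped <- character()
  for (key in names(epochs)) {
    es <- tryCatch(
      preprocess_epochs(epochs[[key]], filter = config$filter,
                        baseline_window_ms = config$baseline_window_ms,
                        reject_uv = config$reject_uv),
      erpdyn_empty_result = function(e) NULL)
    if (is.null(es)) { dropped <- c(dropped, key); next }
    erps[[key]] <- condition_average(es)
  }
  # drop subjects missing either condition
  subj_all <- unique(vapply(erps, function(e) e$subject_id, character(1)))
  keep <- vapply(subj_all, function(s)
    all(paste(s, c("standard", "target"), sep = "_") %in% names(erps)),
    logical(1))
  incomplete <- subj_all[!keep]
  if (length(incomplete))
    log_msg("excluded %d subject(s) missing a condition: %s",
            length(incomplete), paste(incomplete, collapse = ", "))
  subjects <- subj_all[keep]
  erps <- erps[unlist(lapply(subjects, paste,
                             c("standard", "target"), sep = "_"))]
  log_msg("preprocess: %d ERPs (%d epoch sets dropped)", length(erps),
          length(dropped))

  meta <- data.frame(
    subject_id = vapply(erps, function(e) e$subject_id, character(1)),
    group = vapply(erps, function(e) e$group, character(1)),
    condition = vapply(erps, function(e) e$condition, character(1)),
    n_trials = vapply(erps, function(e) e$n_trials_used, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL

  # --- stage 3: ERP components ----------------------------------------
  comp_rows <- list()
  specs <- standard_components()
  for (key in names(erps)) {
    e <- erps[[key]]
    for (sp in specs) {
      if (sp$condition != e$condition) next
      amp <- component_amplitude(e, sp)
      lat <- component_latency(e, sp)
      comp_rows[[paste(key, sp$name)]] <- data.frame(
        subject_id = e$subject_id, group = e$group, condition = e$condition,
        component = sp$name, channel = e$channel_names,
        amplitude = as.numeric(amp), latency = as.numeric(lat),
        stringsAsFactors = FALSE)
    }
  }
  components <- do.call(rbind, comp_rows)
  rownames(components) <- NULL
  write.csv(components, file.path(out_dir, "components.csv"),
            row.names = FALSE)

  # --- stage 4: topographic dynamics ----------------------------------
  toposeqs <- lapply(erps, window_means)
  gc_key <- vapply(toposeqs, function(ts) paste(ts$group, ts$condition,
                                                sep = "|"), character(1))
  group_means <- lapply(split(toposeqs, gc_key), group_mean_toposequence)
  topo_rows <- list()
  for (cond in c("standard", "target")) {
    td <- group_means[[paste("TD", cond, sep = "|")]]
    for (g in c("ADHD-I", "ADHD-C")) {
      cm <- cross_corr_matrix(group_means[[paste(g, cond, sep = "|")]], td)
      topo_rows[[paste(g, cond)]] <- data.frame(
        group = g, condition = cond,
        row = rep(rownames(cm$r), 6), col = rep(colnames(cm$r), each = 6),
        r = as.vector(cm$r), p = as.vector(cm$p),
        significant = as.vector(cm$significant), stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, topo_rows), file.path(out_dir, "topo_corr.csv"),
            row.names = FALSE)

  # --- stage 5: trajectories + bootstrap ------------------------------
  basis2 <- fit_basis(group_means)
  traj_rows <- list()
  for (key in names(group_means)) {
    tr <- project_trajectory(group_means[[key]], basis2)
    traj_rows[[key]] <- data.frame(
      group = group_means[[key]]$group,
      condition = group_means[[key]]$condition,
      window = rownames(tr$points), pc1 = tr$points[, 1],
      pc2 = tr$points[, 2], stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, traj_rows), file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
  n_grp_min <- min(table(meta$group[meta$condition == "standard"]))
  if (n_grp_min >= 2) {
    npg <- max(2L, min(config$boot_n_per_group, n_grp_min - 1L))
    boot <- suppressWarnings(
      bootstrap_metrics(toposeqs, n_per_group = npg,
                        iterations = config$boot_iterations,
                        seed = derive_seed(config$seed, 5L)))
    boot_summary <- lapply(boot$metrics, function(m)
      list(mean = colMeans(m), sd = apply(m, 2, sd)))
  } else {
    log_msg("bootstrap skipped: a group has fewer than 2 subjects")
    boot_summary <- NULL
  }

  # --- stage 6: dominant states ---------------------------------------
  basis <- extract_states(group_average_erps(erps), K = config$K)
  write.csv(data.frame(state = rownames(basis$templates), basis$templates),
            file.path(out_dir, "state_templates.csv"), row.names = FALSE)

  # --- stage 7: sequences + transitions -------------------------------
  trans_rows <- list()
  for (key in names(erps)) {
    e <- erps[[key]]
    sq <- assign_states(e, basis, alpha = config$alpha)
    tm <- transition_matrix(sq)
    trans_rows[[key]] <- data.frame(
      subject_id = e$subject_id, group = e$group, condition = e$condition,
      other_proportion = other_proportion(sq),
      stability = I(list(state_stability(tm))),
      p41 = tryCatch(transition_probability(tm, paste0("PC", config$K), "PC1"),
                     erpdyn_undefined_value = function(err) NA_real_),
      stringsAsFactors = FALSE)
  }
  trans <- do.call(rbind, lapply(trans_rows, function(d) {
    st <- d$stability[[1]]
    cbind(d[c("subject_id", "group", "condition", "other_proportion", "p41")],
          as.data.frame(as.list(st)))
  }))
  rownames(trans) <- NULL
  write.csv(trans, file.path(out_dir, "transitions.csv"), row.names = FALSE)

  # --- stage 8: classification ----------------------------------------
  diffs <- lapply(subjects, function(s) {
    tt <- project_timecourse(erps[[paste(s, "target", sep = "_")]], basis)
    ss <- project_timecourse(erps[[paste(s, "standard", sep = "_")]], basis)
    projection_difference(tt, ss)
  })
  names(diffs) <- subjects
  feats <- build_features(diffs, window_average = config$window_average_features)
  labels <- meta$group[match(subjects, meta$subject_id)]
  folds_eff <- min(config$folds, min(table(labels)))
  if (folds_eff >= 2) {
    cv <- cross_validate(feats, labels, folds = folds_eff,
                         repeats = config$repeats,
                         seed = derive_seed(config$seed, 8L))
    shuf <- shuffled_baseline(feats, labels, folds = folds_eff,
                              repeats = config$repeats,
                              seed = derive_seed(config$seed, 9L), real = cv)
  } else {
    log_msg("classification skipped: smallest group supports < 2 folds")
    cv <- list(accuracy = NA_real_)
    shuf <- list(accuracy = NA_real_, p_vs_real = NA_real_)
  }

  # --- stage 9: group statistics --------------------------------------
  stat_rows <- list()
  for (cond in c("standard", "target")) {
    sub <- trans[trans$condition == cond, ]
    grps <- split(sub$other_proportion, sub$group)
    kw <- kruskal_wallis(grps)
    dn <- dunn_sidak(grps)
    stat_rows[[cond]] <- data.frame(
      metric = "other_proportion", condition = cond, test = "kruskal_wallis",
      statistic = kw$statistic, p = kw$p,
      pair = paste(dn$group1, dn$group2, sep = "-"), p_adj = dn$p_adj,
      stringsAsFactors = FALSE)
  }
  stats_df <- do.call(rbind, stat_rows)
  rownames(stats_df) <- NULL
  write.csv(stats_df, file.path(out_dir, "stats.csv"), row.names = FALSE)

  # --- summary ---------------------------------------------------------
  outputs <- c("components.csv", "topo_corr.csv", "trajectories.csv",
               "state_templates.csv", "transitions.csv", "stats.csv")
  if (config$simulate) outputs <- c("clinical.csv", outputs)
  sums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(sums) <- outputs
  summary <- list(
    seed = config$seed,
    n_subjects = length(subjects),
    excluded_subjects = incomplete,
    dropped_epoch_sets = dropped,
    explained_var_top_k = sum(basis$explained_var[seq_len(config$K)]),
    cv_accuracy_mean = mean(cv$accuracy),
    shuffled_accuracy_mean = mean(shuf$accuracy),
    rank_sum_p = shuf$p_vs_real,
    bootstrap = boot_summary,
    checksums = sums,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline complete in %.1f s", summary$elapsed_s)
  invisible(summary)
}
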
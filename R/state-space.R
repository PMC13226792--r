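# Two-dimensional PCA state space: basis fitting on pooled window
# topographies, trajectory projection, geometry metrics, and bootstrap
# pseudo-population inference.

#' Fit the 2-D principal-component basis on pooled window topographies
#'
#' Every window topography is centered across channels; the pooled set
#' (all groups, both conditions) is decomposed by SVD. Component signs are
#' fixed by making each loading's largest-magnitude element positive.
#'
#' @param toposequences List of [topo_sequence()] objects to pool.
#' @return A `basis2d`: `loadings` (2 x channels), `explained_var`
#'   (fractions of total centered variance), `channel_names`.
#' @export
fit_basis <- function(toposequences) {
  if (!length(toposequences)) abort_invalid("no toposequences given")
  ref <- toposequences[[1]]
  X <- do.call(rbind, lapply(toposequences, function(ts) {
    match_montage(ref$channel_names, ts$channel_names)
    t(ts$topos)
  })) # (n_seq * 6) x channels
  if (nrow(X) < 2) abort_invalid("need >= 2 pooled topographies")
  X <- X - rowMeans(X) # center each topography across channels
  sv <- svd(X)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2)
    abort_invalid("pooled topographies have rank < 2")
  loadings <- t(sv$v[, 1:2, drop = FALSE])
  sgn <- apply(loadings, 1L, function(v) sign(v[which.max(abs(v))]))
  loadings <- loadings * sgn
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(loadings = loadings, explained_var = ev[1:2],
                 channel_names = ref$channel_names),
            class = "basis2d")
}

#' Project a topography sequence into the 2-D basis
#'
#' Each window topography is centered across channels and mapped through
#' the loadings, giving one 2-D point per window (T1-T6).
#'
#' @param ts A [topo_sequence()].
#' @param basis A `basis2d` with matching montage.
#' @return A `trajectory`: `points` (windows x 2), labels.
#' @export
project_trajectory <- function(ts, basis) {
  match_montage(ts$channel_names, basis$channel_names)
  topos <- sweep(ts$topos, 2L, colMeans(ts$topos))
  pts <- t(basis$loadings %*% topos) # windows x 2
  rownames(pts) <- colnames(ts$topos)
  colnames(pts) <- c("PC1", "PC2")
  structure(list(points = pts, group = ts$group, condition = ts$condition),
            class = "trajectory")
}

#' Euclidean distance between paired trajectory points
#'
#' @param trajA,trajB `trajectory` objects with the same window count.
#' @return List with `total` (sum over windows) and `per_window`.
#' @export
trajectory_distance <- function(trajA, trajB) {
  if (nrow(trajA$points) != nrow(trajB$points))
    abort_invalid("trajectories have different window counts")
  d <- sqrt(rowSums((trajA$points - trajB$points)^2))
  list(total = sum(d), per_window = d)
}

#' Angular separation between trajectories relative to the T1 anchor
#'
#' For windows w >= 2, the angle between `A(w) - A(T1)` and
#' `B(w) - B(T1)`, in degrees within [0, 180]. Windows where either
#' displacement is numerically zero return NA (flagged via attribute).
#'
#' @param trajA,trajB `trajectory` objects in the same basis.
#' @return Numeric vector of length windows - 1 (T2..T6 by default).
#' @export
angular_separation <- function(trajA, trajB) {
  nA <- nrow(trajA$points)
  if (nA != nrow(trajB$points))
    abort_invalid("trajectories have different window counts")
  u <- sweep(trajA$points[-1, , drop = FALSE], 2L, trajA$points[1, ])
  v <- sweep(trajB$points[-1, , drop = FALSE], 2L, trajB$points[1, ])
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang[nu < 1e-12 | nv < 1e-12] <- NA_real_
  names(ang) <- rownames(trajA$points)[-1]
  attr(ang, "undefined") <- which(is.na(ang))
  ang
}

#' Trajectory path length
#'
#' @param traj A `trajectory` with >= 2 points.
#' @return List with `total` length and per-step distances (`steps`).
#' @export
trajectory_length <- function(traj) {
  p <- traj$points
  if (nrow(p) < 2) abort_invalid("trajectory needs >= 2 points")
  steps <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  list(total = sum(steps), steps = steps)
}

#' Bootstrap pseudo-population trajectory metrics
#'
#' Per iteration: sample `n_per_group` subjects per group (without
#' replacement by default; with replacement, flagged, when a group is
#' smaller), average their toposequences per group x condition, refit the
#' 2-D basis on the pooled averages, sign-align it to the full-sample
#' reference basis, project, and compute the geometry metrics. Metrics are
#' invariant to basis rotation/reflection, so sign alignment only keeps
#' component labels consistent.
#'
#' @param subject_toposequences List of [topo_sequence()] objects, one per
#'   subject x condition, each carrying `group` and `condition` labels.
#' @param n_per_group Pseudo-population size per group (default 15).
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return A `bootstrap_result`: per-iteration matrices (iterations x
#'   groups) for `distance_total`, `angle_mean`, `length_standard`,
#'   `length_target`, plus settings.
#' @export
bootstrap_metrics <- function(subject_toposequences, n_per_group = 15,
                              iterations = 1000, seed = 1L) {
  groups <- c("TD", "ADHD-I", "ADHD-C")
  by_gc <- split(subject_toposequences,
                 vapply(subject_toposequences,
                        function(ts) paste(ts$group, ts$condition, sep = "|"),
                        character(1)))
  subj_of <- lapply(by_gc, function(l)
    vapply(l, function(ts) ts$subject_id, character(1)))
  replace_flag <- FALSE
  for (g in groups) {
    ns <- length(unique(subj_of[[paste(g, "standard", sep = "|")]]))
    if (ns < 2) abort_invalid(sprintf("group %s has < 2 subjects", g))
    if (ns < n_per_group) replace_flag <- TRUE
  }
  if (replace_flag)
    warning("a group is smaller than n_per_group; sampling with replacement")

  # full-sample reference basis for sign alignment
  full_means <- lapply(by_gc, group_mean_toposequence)
  ref_basis <- fit_basis(full_means)

  mk <- function() matrix(NA_real_, iterations, length(groups),
                          dimnames = list(NULL, groups))
  out <- list(distance_total = mk(), angle_mean = mk(),
              length_standard = mk(), length_target = mk())

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 300L))
  for (it in seq_len(iterations)) {
    means <- list()
    for (g in groups) {
      ids <- unique(subj_of[[paste(g, "standard", sep = "|")]])
      take <- sample(ids, n_per_group, replace = replace_flag)
      for (cond in c("standard", "target")) {
        key <- paste(g, cond, sep = "|")
        pool <- by_gc[[key]]
        sel <- pool[match(take, subj_of[[key]])]
        means[[key]] <- group_mean_toposequence(sel)
      }
    }
    basis <- align_basis(fit_basis(means), ref_basis)
    for (g in groups) {
      tr_s <- project_trajectory(means[[paste(g, "standard", sep = "|")]], basis)
      tr_t <- project_trajectory(means[[paste(g, "target", sep = "|")]], basis)
      out$distance_total[it, g] <- trajectory_distance(tr_s, tr_t)$total
      out$angle_mean[it, g] <- mean(angular_separation(tr_s, tr_t), na.rm = TRUE)
      out$length_standard[it, g] <- trajectory_length(tr_s)$total
      out$length_target[it, g] <- trajectory_length(tr_t)$total
    }
  }
  structure(list(metrics = out, n_per_group = n_per_group,
                 iterations = iterations, seed = seed,
                 reference_basis = ref_basis,
                 with_replacement = replace_flag),
            class = "bootstrap_result")
}

# Sign-flip each component of `basis` to positive correlation with its
# counterpart in `ref`.
align_basis <- function(basis, ref) {
  for (k in 1:2) {
    if (cor(basis$loadings[k, ], ref$loadings[k, ]) < 0)
      basis$loadings[k, ] <- -basis$loadings[k, ]
  }
  basis
}
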
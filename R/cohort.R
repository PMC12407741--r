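# Synthetic multi-subject cohort: structural connectomes, graph-smooth
# BOLD-like regional time courses, a 2-day x 2-phase-encoding session design
# and a head-motion confound. The generator provides the statistical structure
# the downstream comparison assumes (subject fingerprints in both structure
# and spectral content, session effects, motion coupling) so every stage of
# the pipeline can be exercised without restricted neuroimaging data.

SC_PROPERTIES <- c("NFD", "NF", "MFL", "MFA")

#' Configuration of a synthetic cohort
#'
#' Defines the study conditions of the simulated dataset: cohort size, graph
#' size and community structure, the strength of subject-specific structure
#' (connectome jitter) and function (spectral signature), day and
#' phase-encoding session effects, measurement noise, and the head-motion
#' model (per-scan mean framewise displacement drawn from a truncated normal,
#' coupled linearly into the signals).
#'
#' @param n_subjects number of subjects (>= 2). Each subject contributes four
#'   scans: two acquisition days x two phase-encoding directions (LR, RL).
#' @param n_regions number of brain regions R (>= 2 * `n_communities`).
#' @param n_timepoints number of time points T per scan.
#' @param n_communities number of structural communities in the connectome.
#' @param subject_sc_jitter log-scale sd of the multiplicative edge
#'   perturbation that turns the group connectome into subject connectomes.
#' @param subject_signature_strength log-scale sd of the subject-specific
#'   spectral signature applied to the generative envelope (0 = no functional
#'   fingerprint).
#' @param day_effect,phase_effect amplitudes of fixed spatial patterns shared
#'   across subjects that differ by acquisition day / phase encoding.
#' @param noise_sd sd of additive white measurement noise.
#' @param motion_coupling scalar in \[0, 1\] scaling the motion regressor
#'   contribution (multiplied by the scan's mean FD).
#' @param fd_mean,fd_sd,fd_min,fd_max mean, sd and truncation bounds (mm) of
#'   the per-scan mean framewise displacement distribution.
#' @param seed integer master seed; a fixed seed makes every generated
#'   artifact bit-reproducible.
#' @param test_mode logical; if `TRUE` the white driver of each subject's
#'   scans is frozen per subject, so that with all effect and noise amplitudes
#'   at zero a subject's four scans are identical (used for exact-repeat
#'   oracle tests of reliability and fingerprinting).
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 20,
                          n_regions = 60,
                          n_timepoints = 200,
                          n_communities = 4,
                          subject_sc_jitter = 0.2,
                          subject_signature_strength = 0.5,
                          day_effect = 0.1,
                          phase_effect = 0.1,
                          noise_sd = 0.5,
                          motion_coupling = 0.3,
                          fd_mean = 0.13,
                          fd_sd = 0.02,
                          fd_min = 0.08,
                          fd_max = 0.18,
                          seed = 1,
                          test_mode = FALSE) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    n_communities = as.integer(n_communities),
    subject_sc_jitter = subject_sc_jitter,
    subject_signature_strength = subject_signature_strength,
    day_effect = day_effect,
    phase_effect = phase_effect,
    noise_sd = noise_sd,
    motion_coupling = motion_coupling,
    fd_mean = fd_mean, fd_sd = fd_sd, fd_min = fd_min, fd_max = fd_max,
    seed = as.numeric(seed),
    test_mode = isTRUE(test_mode)
  )
  counts <- c(cfg$n_subjects, cfg$n_regions, cfg$n_timepoints, cfg$n_communities)
  if (any(counts < 2)) stop("all counts must be >= 2")
  if (cfg$n_regions < 2 * cfg$n_communities) {
    stop("n_regions must be at least 2 * n_communities")
  }
  nonneg <- c(cfg$subject_sc_jitter, cfg$subject_signature_strength,
              cfg$day_effect, cfg$phase_effect, cfg$noise_sd)
  if (any(nonneg < 0)) stop("effect strengths must be nonnegative")
  if (cfg$motion_coupling < 0 || cfg$motion_coupling > 1) {
    stop("motion_coupling must lie in [0, 1]")
  }
  if (!(cfg$fd_min < cfg$fd_mean && cfg$fd_mean < cfg$fd_max)) {
    stop("fd_min < fd_mean < fd_max is required")
  }
  structure(cfg, class = "cohort_config")
}

#' Structural connectome container
#'
#' Wraps a symmetric nonnegative region-by-region edge-weight matrix with its
#' edge-property label and scope. Symmetry is enforced by averaging
#' `(A + t(A))/2`; asymmetries beyond 1e-10 are rejected.
#'
#' @param weights square numeric matrix of edge weights.
#' @param property one of `"NFD"`, `"NF"`, `"MFL"`, `"MFA"`.
#' @param scope `"group"` or a subject identifier.
#' @param region_labels optional character vector of region names.
#' @return an object of class `structural_connectome`.
#' @export
structural_connectome <- function(weights, property = "NFD", scope = "group",
                                  region_labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-10 * max(1, max(abs(weights)))) {
    stop("weights matrix is not symmetric within tolerance")
  }
  weights <- (weights + t(weights)) / 2
  if (any(weights < 0)) stop("edge weights must be nonnegative")
  diag(weights) <- 0
  property <- match.arg(property, SC_PROPERTIES)
  structure(
    list(weights = weights, property = property, scope = scope,
         region_labels = region_labels),
    class = "structural_connectome"
  )
}

# Shared latent topology from which all four edge-property variants are
# derived (so that their zero/nonzero supports match, mirroring four edge
# weightings of a single tractogram). Community-structured support via a
# stochastic block model; log-normal latent weight scores.
group_latent <- function(config) {
  R <- config$n_regions
  K <- config$n_communities
  membership <- sort(rep_len(seq_len(K), R))
  with_seed(child_seed(config$seed, 1), {
    p_in <- 0.75
    p_out <- 0.25
    support <- NULL
    for (attempt in seq_len(50)) {
      prob <- ifelse(outer(membership, membership, "=="), p_in, p_out)
      draw <- matrix(0, R, R)
      ut <- upper.tri(draw)
      draw[ut] <- stats::rbinom(sum(ut), 1, prob[ut])
      draw <- draw + t(draw)
      g <- igraph::graph_from_adjacency_matrix(draw, mode = "undirected")
      if (igraph::is_connected(g)) {
        support <- draw
        break
      }
    }
    if (is.null(support)) {
      stop("failed to draw a connected connectome support in 50 attempts")
    }
    ut <- upper.tri(support) & support > 0
    n_edges <- sum(ut)
    z_count <- stats::rnorm(n_edges)
    z_len <- stats::rnorm(n_edges)
    z_fa <- stats::rnorm(n_edges)
    sizes <- exp(stats::rnorm(R, 0, 0.3))
    list(support = support, edge_idx = which(ut), membership = membership,
         z_count = z_count, z_len = z_len, z_fa = z_fa, sizes = sizes)
  })
}

edge_matrix <- function(latent, values) {
  R <- nrow(latent$support)
  m <- matrix(0, R, R)
  m[latent$edge_idx] <- values
  m + t(m)
}

#' Generate a group-level structural connectome
#'
#' Draws a community-structured (weighted stochastic block model) connectome
#' and derives the requested edge property deterministically from one shared
#' latent topology: `NF` (number of fibers, positive integers), `NFD`
#' (fiber count rescaled by region-pair size factors), `MFL` (median fiber
#' length, positive continuous, anti-correlated with fiber count) or `MFA`
#' (median fractional anisotropy in (0, 1)). Within-community edges are
#' stochastically denser than between-community edges, which gives the
#' low-frequency harmonics the large-scale contrasts the analysis assumes.
#' Disconnected draws are rejected (at most 50 retries).
#'
#' @param config a [cohort_config()].
#' @param property edge-property variant to emit.
#' @return a [structural_connectome()] with scope `"group"`.
#' @export
generate_group_sc <- function(config, property = c("NFD", "NF", "MFL", "MFA")) {
  property <- match.arg(property)
  latent <- group_latent(config)
  within <- outer(latent$membership, latent$membership, "==")[latent$edge_idx]
  nf <- pmax(1, round_half_away(exp(log(20) + 0.9 * latent$z_count + 0.6 * within)))
  vals <- switch(property,
    NF = nf,
    NFD = {
      size_pair <- (latent$sizes %o% latent$sizes)[latent$edge_idx]
      nf / size_pair
    },
    MFL = exp(log(40) + 0.45 * latent$z_len - 0.25 * latent$z_count),
    MFA = stats::plogis(stats::qlogis(0.45) + 0.6 * latent$z_fa)
  )
  structural_connectome(edge_matrix(latent, vals), property = property,
                        scope = "group")
}

#' Generate a subject-specific structural connectome
#'
#' Perturbs each existing edge of the group connectome by a symmetric
#' log-normal multiplicative jitter (log-scale sd `subject_sc_jitter`),
#' preserving the support pattern, symmetry and nonnegativity. With jitter 0
#' the subject connectome equals the group connectome exactly.
#'
#' @param group_sc a group-scope [structural_connectome()].
#' @param config a [cohort_config()].
#' @param subject integer subject index (drives the subject's private seed).
#' @return a [structural_connectome()] with subject scope.
#' @export
generate_subject_sc <- function(group_sc, config, subject) {
  stopifnot(inherits(group_sc, "structural_connectome"))
  A <- group_sc$weights
  ut <- upper.tri(A) & A > 0
  jit <- with_seed(child_seed(config$seed, 100 + subject),
                   exp(stats::rnorm(sum(ut), 0, config$subject_sc_jitter)))
  J <- matrix(1, nrow(A), ncol(A))
  J[ut] <- jit
  J[lower.tri(J)] <- t(J)[lower.tri(J)]
  structural_connectome(A * J, property = group_sc$property,
                        scope = paste0("sub-", subject))
}

#' Sample per-scan mean framewise displacement values
#'
#' Draws mean-FD values (mm) from a normal distribution truncated to
#' `[fd_min, fd_max]` by rejection sampling, reproducibly from the config
#' seed.
#'
#' @param config a [cohort_config()].
#' @param n number of values to draw.
#' @return numeric vector of length `n`.
#' @export
sample_mean_fd <- function(config, n) {
  with_seed(child_seed(config$seed, 3), {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(2 * n, 100), config$fd_mean, config$fd_sd)
      out <- c(out, draw[draw >= config$fd_min & draw <= config$fd_max])
    }
    out[seq_len(n)]
  })
}

# Smoothed white-noise motion trace of unit sd, shared across regions.
motion_trace <- function(T) {
  m <- as.numeric(stats::filter(stats::rnorm(T), rep(1, 5) / 5, circular = TRUE))
  m / stats::sd(m)
}

#' Generate regional time courses for every scan of the cohort
#'
#' For each scan the signal is built on the subject's own connectome
#' harmonics (unnormalized Laplacian of the subject's NFD connectome):
#' `X = U diag(g * a_s) E + day_effect * D_day + phase_effect * D_phase +
#' noise_sd * N + motion_coupling * mean_fd * m_t`, where `g_k = 1/(1+lambda_k)`
#' is a fixed low-pass spectral envelope, `a_s` a subject-specific log-normal
#' spectral signature shared across that subject's four scans, `E` and `N`
#' independent white matrices, `D_day`/`D_phase` fixed random spatial patterns
#' shared across subjects, and `m_t` a smoothed white motion trace added to
#' all regions in proportion to the scan's mean FD.
#'
#' @param subject_scs list (by subject) of NFD-property
#'   [structural_connectome()] objects.
#' @param config a [cohort_config()].
#' @return list with `timeseries` (list of R x T matrices, one per scan, in
#'   meta row order) and `meta` (data.frame: subject, day, phase, mean_fd).
#' @export
generate_timecourses <- function(subject_scs, config) {
  S <- config$n_subjects
  R <- config$n_regions
  T <- config$n_timepoints
  stopifnot(length(subject_scs) == S)

  patterns <- with_seed(child_seed(config$seed, 2), {
    list(day = matrix(stats::rnorm(R * 2), R, 2),
         phase = matrix(stats::rnorm(R * 2), R, 2))
  })
  fd <- sample_mean_fd(config, 4 * S)

  meta <- data.frame(
    subject = rep(seq_len(S), each = 4),
    day = rep(rep(1:2, each = 2), S),
    phase = rep(c("LR", "RL"), 2 * S),
    mean_fd = fd,
    stringsAsFactors = FALSE
  )

  timeseries <- vector("list", nrow(meta))
  for (s in seq_len(S)) {
    spec <- eigendecompose(build_shift_operator(subject_scs[[s]], "L_U"))
    g <- 1 / (1 + spec$lam)
    a_s <- with_seed(child_seed(config$seed, 500 + s),
                     exp(stats::rnorm(R, 0, config$subject_signature_strength)))
    for (scan in 1:4) {
      i <- (s - 1) * 4 + scan
      day <- meta$day[i]
      phase_i <- if (meta$phase[i] == "LR") 1L else 2L
      E <- if (config$test_mode) {
        with_seed(child_seed(config$seed, 700 + s), matrix(stats::rnorm(R * T), R, T))
      } else {
        with_seed(child_seed(config$seed, 10000 + 3 * i), matrix(stats::rnorm(R * T), R, T))
      }
      N <- with_seed(child_seed(config$seed, 10000 + 3 * i + 1),
                     matrix(stats::rnorm(R * T), R, T))
      m_t <- with_seed(child_seed(config$seed, 10000 + 3 * i + 2), motion_trace(T))
      X <- spec$U %*% ((g * a_s) * E) +
        config$day_effect * patterns$day[, day] +
        config$phase_effect * patterns$phase[, phase_i] +
        config$noise_sd * N +
        config$motion_coupling * meta$mean_fd[i] * matrix(m_t, R, T, byrow = TRUE)
      if (!all(is.finite(X))) stop("non-finite time courses generated; check config")
      timeseries[[i]] <- X
    }
  }
  list(timeseries = timeseries, meta = meta)
}

#' Parcellation-variant maps
#'
#' Emits region-index maps for the three parcellation variants used in the
#' generalizability analysis: `S3` (identity), `S3minus` (drop the trailing
#' `ceiling(0.21 * R)` regions, mirroring the removal of subcortical and
#' cerebellar areas, 274 -> 216), and `S1` (merge regions pairwise within
#' communities, mirroring downscaling to a coarser atlas, 274 -> 126; edge
#' weights are summed and time courses averaged when the map is applied).
#'
#' @param config a [cohort_config()].
#' @return named list of maps, each a list with a `type` field (`"identity"`,
#'   `"keep"` with kept indices, or `"merge"` with index groups).
#' @export
generate_parcellation_variants <- function(config) {
  R <- config$n_regions
  n_drop <- ceiling(0.21 * R)
  if (n_drop >= R) stop("S3minus drop would remove all regions")
  membership <- group_latent(config)$membership
  groups <- list()
  for (k in sort(unique(membership))) {
    idx <- which(membership == k)
    n_pairs <- floor(length(idx) / 2)
    for (p in seq_len(n_pairs)) {
      groups[[length(groups) + 1L]] <- idx[c(2 * p - 1, 2 * p)]
    }
    if (length(idx) %% 2 == 1) {
      groups[[length(groups) + 1L]] <- idx[length(idx)]
    }
  }
  list(
    S3 = list(type = "identity"),
    S3minus = list(type = "keep", keep = seq_len(R - n_drop)),
    S1 = list(type = "merge", groups = groups)
  )
}

# Apply a variant map to one SC weight matrix (sum of merged edge weights).
map_sc <- function(weights, map) {
  switch(map$type,
    identity = weights,
    keep = weights[map$keep, map$keep, drop = FALSE],
    merge = {
      n <- length(map$groups)
      out <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i != j) out[i, j] <- sum(weights[map$groups[[i]], map$groups[[j]]])
        }
      }
      out
    }
  )
}

# Apply a variant map to one time-series matrix (mean of merged rows).
map_ts <- function(X, map) {
  switch(map$type,
    identity = X,
    keep = X[map$keep, , drop = FALSE],
    merge = {
      rows <- lapply(map$groups, function(g) colMeans(X[g, , drop = FALSE]))
      do.call(rbind, rows)
    }
  )
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model: group connectomes for all four edge
#' properties, subject-specific connectomes, regional time courses for the
#' 4 x S scans, scan metadata, and parcellation-variant maps.
#'
#' @param config a [cohort_config()].
#' @return an object of class `gsp_cohort`: list with `config`, `group_sc`
#'   (named by property), `subject_scs` (`subject_scs[[s]][[property]]`),
#'   `timeseries`, `meta` and `variants`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  group_sc <- lapply(SC_PROPERTIES, function(p) generate_group_sc(config, p))
  names(group_sc) <- SC_PROPERTIES
  subject_scs <- lapply(seq_len(config$n_subjects), function(s) {
    scs <- lapply(group_sc, function(gsc) generate_subject_sc(gsc, config, s))
    names(scs) <- SC_PROPERTIES
    scs
  })
  tc <- generate_timecourses(lapply(subject_scs, `[[`, "NFD"), config)
  structure(
    list(config = config,
         group_sc = group_sc,
         subject_scs = subject_scs,
         timeseries = tc$timeseries,
         meta = tc$meta,
         variants = generate_parcellation_variants(config)),
    class = "gsp_cohort"
  )
}

#' Apply a parcellation variant to a cohort
#'
#' Produces a reduced cohort whose connectomes and time courses have been
#' transformed by the requested variant map (`S3` identity, `S3minus` region
#' dropping, `S1` pairwise merging: edge weights summed, time courses
#' averaged).
#'
#' @param cohort a `gsp_cohort`.
#' @param variant `"S3"`, `"S3minus"` or `"S1"`.
#' @return a `gsp_cohort` with mapped matrices (metadata unchanged).
#' @export
apply_variant <- function(cohort, variant = c("S3", "S3minus", "S1")) {
  variant <- match.arg(variant)
  map <- cohort$variants[[variant]]
  if (map$type == "identity") return(cohort)
  out <- cohort
  out$group_sc <- lapply(cohort$group_sc, function(sc) {
    structural_connectome(map_sc(sc$weights, map), sc$property, sc$scope)
  })
  out$subject_scs <- lapply(cohort$subject_scs, function(scs) {
    lapply(scs, function(sc) {
      structural_connectome(map_sc(sc$weights, map), sc$property, sc$scope)
    })
  })
  out$timeseries <- lapply(cohort$timeseries, map_ts, map = map)
  out
}

#' @export
print.gsp_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic GSP cohort: %d subjects x 4 scans, R = %d regions, T = %d\n",
    cfg$n_subjects, cfg$n_regions, cfg$n_timepoints))
  cat(sprintf("  mean FD: %.3f +/- %.3f mm (range %.3f-%.3f)\n",
              mean(x$meta$mean_fd), stats::sd(x$meta$mean_fd),
              min(x$meta$mean_fd), max(x$meta$mean_fd)))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Dense matrices are written whitespace-delimited; scan metadata as CSV.
#'
#' @param cohort a `gsp_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) utils::write.table(m, file.path(dir, f),
                                          row.names = FALSE, col.names = FALSE)
  for (p in names(cohort$group_sc)) {
    wm(cohort$group_sc[[p]]$weights, sprintf("group_sc_%s.txt", p))
  }
  for (s in seq_along(cohort$subject_scs)) {
    for (p in names(cohort$subject_scs[[s]])) {
      wm(cohort$subject_scs[[s]][[p]]$weights, sprintf("subject_sc_%03d_%s.txt", s, p))
    }
  }
  for (i in seq_along(cohort$timeseries)) {
    m <- cohort$meta[i, ]
    wm(cohort$timeseries[[i]],
       sprintf("ts_%03d_day%d_%s.txt", m$subject, m$day, m$phase))
  }
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
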
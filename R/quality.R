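# Six quality criteria per feature type x parameter combination, and the
# consensus ranking:
#   1. robustness to acquisition settings (percentage of incongruent
#      subjects, with the penalty Omega as an intermediate),
#   2. sensitivity to head motion (variance explained by mean FD within the
#      selected coefficients),
#   3. test-retest reliability (ICC(A,1) within the selected coefficients),
#   4. fingerprinting accuracy after ICC-ranked feature selection,
#   5. parsimony (percentage of coefficients needed for the best accuracy),
#   6. generalizability to parcellation changes.

# --- table helpers ----------------------------------------------------------

# S x R matrix of feature values for one (day, phase, combo), rows ordered
# by subject.
scan_matrix <- function(table, combo_id, day, phase) {
  sel <- table$combo_id == combo_id & table$day == day & table$phase == phase
  sub <- table[sel, ]
  sub <- sub[order(sub$subject), ]
  list(values = do.call(rbind, sub$values), mean_fd = sub$mean_fd,
       subjects = sub$subject)
}

# --- criterion 1: robustness to acquisition settings ------------------------

#' Same-day versus different-day similarity statistics
#'
#' For each subject, Pearson correlations between feature vectors of the two
#' same-day scan pairs (day 1 LR-RL, day 2 LR-RL) form `R_same`, and of the
#' two different-day same-phase pairs (LR day1-day2, RL day1-day2) form
#' `R_diff`. Their per-subject means give `deltaR = Rbar_same - Rbar_diff`; a
#' negative value means a subject looked more similar across days than within
#' a day, which a robust feature should never produce. The penalty is
#' `Omega = sum(max(0, -deltaR))` (sum of incongruence magnitudes;
#' `omega_variant = "count"` gives the Heaviside count instead), and
#' `pct_incongruent` is the percentage of subjects with negative `deltaR`.
#' Subjects with a constant (undefined-correlation) feature vector in any
#' required pair are excluded with a warning.
#'
#' @param table a [compute_feature_table()] result.
#' @param combo_id combination to evaluate.
#' @param omega_variant `"magnitude"` (default) or `"count"`.
#' @return list with `R_same`, `R_diff` (S x 2), `Rbar_same`, `Rbar_diff`,
#'   `deltaR`, `omega`, `pct_incongruent`.
#' @export
session_similarity_stats <- function(table, combo_id,
                                     omega_variant = c("magnitude", "count")) {
  omega_variant <- match.arg(omega_variant)
  sub <- table[table$combo_id == combo_id, ]
  subjects <- sort(unique(sub$subject))
  vec <- function(s, day, phase) {
    sub$values[[which(sub$subject == s & sub$day == day & sub$phase == phase)]]
  }
  R_same <- matrix(NA_real_, length(subjects), 2)
  R_diff <- matrix(NA_real_, length(subjects), 2)
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    R_same[i, 1] <- safe_cor(vec(s, 1, "LR"), vec(s, 1, "RL"))
    R_same[i, 2] <- safe_cor(vec(s, 2, "LR"), vec(s, 2, "RL"))
    R_diff[i, 1] <- safe_cor(vec(s, 1, "LR"), vec(s, 2, "LR"))
    R_diff[i, 2] <- safe_cor(vec(s, 1, "RL"), vec(s, 2, "RL"))
  }
  Rbar_same <- rowMeans(R_same)
  Rbar_diff <- rowMeans(R_diff)
  deltaR <- Rbar_same - Rbar_diff
  if (anyNA(deltaR)) {
    warning(sum(is.na(deltaR)),
            " subject(s) with undefined correlations excluded from deltaR")
    deltaR <- deltaR[!is.na(deltaR)]
  }
  omega <- switch(omega_variant,
    magnitude = sum(pmax(0, -deltaR)),
    count = sum(deltaR < 0)
  )
  list(R_same = R_same, R_diff = R_diff,
       Rbar_same = Rbar_same, Rbar_diff = Rbar_diff, deltaR = deltaR,
       omega = omega, pct_incongruent = 100 * mean(deltaR < 0))
}

# --- criterion 2: sensitivity to head motion --------------------------------

#' Variance in feature coefficients explained by mean framewise displacement
#'
#' For each scan (day x phase) and each feature coefficient, mean FD is
#' correlated (Pearson) across subjects with the coefficient's values; the
#' squared correlation times 100 is the percentage of explained variance.
#' These are averaged over the coefficient subset, then over the four scans.
#' Coefficients with zero variance across subjects are excluded with a
#' warning.
#'
#' @param table a [compute_feature_table()] result.
#' @param combo_id combination to evaluate.
#' @param subset coefficient indices to average over (default: all).
#' @return mean percentage of explained variance.
#' @export
movement_variance <- function(table, combo_id, subset = NULL) {
  scans <- expand.grid(day = 1:2, phase = c("LR", "RL"),
                       stringsAsFactors = FALSE)
  per_scan <- numeric(nrow(scans))
  warned <- FALSE
  for (i in seq_len(nrow(scans))) {
    sm <- scan_matrix(table, combo_id, scans$day[i], scans$phase[i])
    F <- sm$values
    if (is.null(subset)) subset <- seq_len(ncol(F))
    r2 <- vapply(subset, function(j) {
      r <- safe_cor(F[, j], sm$mean_fd)
      if (is.na(r)) NA_real_ else 100 * r^2
    }, numeric(1))
    if (anyNA(r2) && !warned) {
      warning("zero-variance coefficient(s) excluded from FD variance")
      warned <- TRUE
    }
    per_scan[i] <- mean(r2, na.rm = TRUE)
  }
  mean(per_scan)
}

# --- criterion 3: reliability -----------------------------------------------

#' Intraclass correlation ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA mean squares (rows = subjects, columns = repeated
#' measurements): `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#'
#' @param values n x k numeric matrix (n subjects, k measurements).
#' @return the ICC estimate; `NA` with a warning if total variance is zero.
#' @export
icc_a1 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2 || k < 2) stop("ICC requires at least 2 subjects and 2 measurements")
  gm <- mean(values)
  if (all(values == values[1])) {
    warning("zero total variance; ICC undefined")
    return(NA_real_)
  }
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- sweep(sweep(values, 1, rm_), 2, cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# --- criterion 4: fingerprinting --------------------------------------------

#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' O(n^3) potentials-based implementation; used for the one-to-one subject
#' matching underlying fingerprinting accuracy.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `match` with `match[i]` the column assigned to row
#'   `i`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  # columns are shifted by one: index 1 is the dummy column of the classical
  # formulation, real columns live at 2..n+1
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) match[p[j]] <- j - 1L
  match
}

#' Fingerprinting accuracy between two sessions
#'
#' Builds the subject-by-subject Pearson similarity matrix between the rows
#' of `features_a` (session A) and `features_b` (session B), solves the
#' one-to-one assignment maximizing total similarity with the Hungarian
#' algorithm, and reports the percentage of correct (diagonal) assignments.
#' Constant rows yield undefined correlations; those similarity entries are
#' set to 0 with a warning. With a single coefficient (p = 1) Pearson
#' correlation is undefined, so the negative absolute difference is used as
#' the similarity instead (the degenerate first step of the selection sweep).
#'
#' @param features_a,features_b S x p matrices, same subjects in the same
#'   row order.
#' @return accuracy in percent.
#' @export
fingerprint_accuracy <- function(features_a, features_b) {
  A <- as.matrix(features_a)
  B <- as.matrix(features_b)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  S <- nrow(A)
  sim <- matrix(NA_real_, S, S)
  if (ncol(A) == 1) {
    sim <- -abs(outer(A[, 1], B[, 1], "-"))
  } else {
    for (i in seq_len(S)) {
      for (j in seq_len(S)) sim[i, j] <- safe_cor(A[i, ], B[j, ])
    }
  }
  if (anyNA(sim)) {
    warning("constant feature vector(s): undefined similarities set to 0")
    sim[is.na(sim)] <- 0
  }
  match <- solve_assignment(-sim)
  100 * mean(match == seq_len(S))
}

#' Full-feature fingerprinting accuracy for one combination
#'
#' Computes accuracy on both different-day same-phase session pairs
#' (day 1 LR vs day 2 LR, and day 1 RL vs day 2 RL) and averages them.
#'
#' @param table a [compute_feature_table()] result.
#' @param combo_id combination to evaluate.
#' @param subset optional coefficient subset.
#' @return list with `accuracy` (mean) and `per_pair` (length 2: LR, RL).
#' @export
fingerprint_accuracy_pairs <- function(table, combo_id, subset = NULL) {
  acc <- vapply(c("LR", "RL"), function(ph) {
    A <- scan_matrix(table, combo_id, 1, ph)$values
    B <- scan_matrix(table, combo_id, 2, ph)$values
    if (!is.null(subset)) {
      A <- A[, subset, drop = FALSE]
      B <- B[, subset, drop = FALSE]
    }
    fingerprint_accuracy(A, B)
  }, numeric(1))
  list(accuracy = mean(acc), per_pair = acc)
}

#' ICC-ranked feature selection for fingerprinting
#'
#' Ranks coefficients by ICC(A,1) computed with k = 2 on the two
#' left-right-encoded scans (session 1 of each day), then sweeps nested
#' top-m subsets (m = 1..R, configurable stride) and evaluates fingerprinting
#' accuracy on the right-left-encoded day pair only, so that selection and
#' evaluation use disjoint sessions (no double dipping). Returns the maximal
#' accuracy, the smallest percentage of coefficients attaining it, the
#' selected set and the sweep curve. Coefficients with undefined ICC are
#' ranked last.
#'
#' @param table a [compute_feature_table()] result.
#' @param combo_id combination to evaluate.
#' @param stride sweep granularity (1 = every subset size).
#' @return list with `accuracy_max`, `pct_coeffs_used`, `selected`,
#'   `icc_ses1`, `order`, `sweep` (data.frame m, accuracy).
#' @export
select_features_by_icc <- function(table, combo_id, stride = 1) {
  ses1_a <- scan_matrix(table, combo_id, 1, "LR")$values
  ses1_b <- scan_matrix(table, combo_id, 2, "LR")$values
  R <- ncol(ses1_a)
  iccs <- vapply(seq_len(R), function(j) {
    m <- cbind(ses1_a[, j], ses1_b[, j])
    if (all(m == m[1])) return(NA_real_)
    icc_a1(m)
  }, numeric(1))
  ord <- order(-iccs, na.last = TRUE)
  A <- scan_matrix(table, combo_id, 1, "RL")$values
  B <- scan_matrix(table, combo_id, 2, "RL")$values
  ms <- unique(c(seq(1, R, by = stride), R))
  acc <- vapply(ms, function(m) {
    idx <- ord[seq_len(m)]
    suppressWarnings(fingerprint_accuracy(A[, idx, drop = FALSE],
                                          B[, idx, drop = FALSE]))
  }, numeric(1))
  best <- max(acc)
  m_best <- ms[which(acc == best)[1]]
  list(accuracy_max = best,
       pct_coeffs_used = 100 * m_best / R,
       selected = ord[seq_len(m_best)],
       icc_ses1 = iccs,
       order = ord,
       sweep = data.frame(m = ms, accuracy = acc))
}

# --- criterion 6: generalizability ------------------------------------------

#' Change in fingerprinting accuracy under parcellation switches
#'
#' Mean absolute change in accuracy when switching from the reference
#' parcellation (S3) to the reduced (S3minus) or coarser (S1) variant;
#' smaller is better. `signed = TRUE` averages the signed differences
#' instead.
#'
#' @param acc_s3,acc_s3minus,acc_s1 accuracies in percent.
#' @param signed logical.
#' @return the average change.
#' @export
generalization_delta <- function(acc_s3, acc_s3minus, acc_s1, signed = FALSE) {
  stopifnot(all(c(acc_s3, acc_s3minus, acc_s1) >= 0),
            all(c(acc_s3, acc_s3minus, acc_s1) <= 100))
  d1 <- acc_s3minus - acc_s3
  d2 <- acc_s1 - acc_s3
  if (signed) (d1 + d2) / 2 else (abs(d1) + abs(d2)) / 2
}

# --- orchestration ----------------------------------------------------------

#' Quality report for a set of parameter combinations
#'
#' Computes the six quality criteria (plus intermediates) for each requested
#' combination of one feature type. Reliability (`icc_selected`) is the mean
#' over the selected coefficients of the all-scan ICC(A,1) (k = 4
#' measurements per subject). Generalizability requires feature tables of
#' the same combinations computed on the S3minus and S1 variants; if either
#' is missing the criterion is `NA`.
#'
#' @param table a [compute_feature_table()] result (S3 variant).
#' @param combo_ids combinations to evaluate (default: all in the table).
#' @param table_s3minus,table_s1 optional variant tables.
#' @param stride selection-sweep stride, see [select_features_by_icc()].
#' @param omega_variant passed to [session_similarity_stats()].
#' @return data.frame, one row per combination, with the combination columns
#'   and criteria `omega`, `pct_incongruent`, `pfd_all`, `pfd_selected`,
#'   `icc_selected`, `accuracy_full`, `accuracy_max`, `pct_coeffs_used`,
#'   `generalization_change`.
#' @export
quality_report <- function(table, combo_ids = NULL,
                           table_s3minus = NULL, table_s1 = NULL,
                           stride = 1, omega_variant = "magnitude") {
  combos <- attr(table, "combos")
  if (is.null(combo_ids)) combo_ids <- sort(unique(table$combo_id))
  rows <- lapply(combo_ids, function(id) {
    ss <- session_similarity_stats(table, id, omega_variant)
    sel <- select_features_by_icc(table, id, stride = stride)
    pfd_all <- movement_variance(table, id)
    pfd_sel <- movement_variance(table, id, subset = sel$selected)
    icc_all <- all_scan_icc(table, id)
    icc_sel <- mean(icc_all[sel$selected], na.rm = TRUE)
    acc_full <- fingerprint_accuracy_pairs(table, id)$accuracy
    gen <- NA_real_
    if (!is.null(table_s3minus) && !is.null(table_s1)) {
      acc_m <- fingerprint_accuracy_pairs(table_s3minus, id)$accuracy
      acc_1 <- fingerprint_accuracy_pairs(table_s1, id)$accuracy
      gen <- generalization_delta(acc_full, acc_m, acc_1)
    }
    data.frame(combo_id = id, omega = ss$omega,
               pct_incongruent = ss$pct_incongruent,
               pfd_all = pfd_all, pfd_selected = pfd_sel,
               icc_selected = icc_sel,
               accuracy_full = acc_full,
               accuracy_max = sel$accuracy_max,
               pct_coeffs_used = sel$pct_coeffs_used,
               generalization_change = gen)
  })
  report <- do.call(rbind, rows)
  merge(combos, report, by = "combo_id", sort = TRUE)
}

# Per-coefficient ICC(A,1) across all four scans (k = 4).
all_scan_icc <- function(table, combo_id) {
  m1 <- scan_matrix(table, combo_id, 1, "LR")$values
  m2 <- scan_matrix(table, combo_id, 1, "RL")$values
  m3 <- scan_matrix(table, combo_id, 2, "LR")$values
  m4 <- scan_matrix(table, combo_id, 2, "RL")$values
  vapply(seq_len(ncol(m1)), function(j) {
    m <- cbind(m1[, j], m2[, j], m3[, j], m4[, j])
    if (all(m == m[1])) return(NA_real_)
    icc_a1(m)
  }, numeric(1))
}

#' Consensus ranking of candidate pipelines
#'
#' Takes quality reports (possibly concatenated across feature types),
#' min-max normalizes each of the six criteria to \[0, 100\] over all cases
#' with the orientation flipped where lower is better (incongruence, FD
#' sensitivity, parsimony, generalization change), and averages them into a
#' consensus score. A criterion constant across all cases is set to 50 with
#' a warning. The `top20_accuracy` flag marks the 20 cases (per feature
#' type) with the highest selected-subset accuracy, for spider-plot export.
#'
#' @param reports data.frame from [quality_report()] (rows = cases).
#' @return the input with `norm_*` columns, `consensus`, and
#'   `top20_accuracy`.
#' @export
rank_pipelines <- function(reports) {
  if (nrow(reports) < 2) stop("ranking requires at least 2 cases")
  crit <- c(pct_incongruent = -1, pfd_selected = -1, icc_selected = 1,
            accuracy_max = 1, pct_coeffs_used = -1, generalization_change = -1)
  norm <- matrix(NA_real_, nrow(reports), length(crit),
                 dimnames = list(NULL, paste0("norm_", names(crit))))
  for (i in seq_along(crit)) {
    x <- reports[[names(crit)[i]]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("criterion '", names(crit)[i], "' constant across cases; set to 50")
      norm[, i] <- 50
    } else {
      scaled <- 100 * (x - rng[1]) / diff(rng)
      norm[, i] <- if (crit[i] < 0) 100 - scaled else scaled
    }
  }
  out <- cbind(reports, as.data.frame(norm))
  out$consensus <- rowMeans(norm)
  out$top20_accuracy <- FALSE
  for (ft in unique(out$feature_type)) {
    idx <- which(out$feature_type == ft)
    top <- idx[order(-out$accuracy_max[idx])][seq_len(min(20, length(idx)))]
    out$top20_accuracy[top] <- TRUE
  }
  out[order(-out$consensus), ]
}
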
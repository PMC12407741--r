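# Two-dimensional spectral embedding of feature-pattern similarity across
# parameter combinations: cosine distances between feature vectors, a
# row-adaptive Gaussian kernel, averaging across scans then subjects, and a
# spectral-clustering style eigendecomposition whose second and third
# eigenvectors summarize the combination space.

# Pairwise cosine distance between the rows of a matrix; rows with zero norm
# give NA distances.
cosine_distance <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  d <- 1 - (M %*% t(M)) / (nrm %o% nrm)
  d[nrm == 0, ] <- NA_real_
  d[, nrm == 0] <- NA_real_
  diag(d) <- 0
  # numerical guard: cosine similarity can exceed 1 by rounding
  pmax(d, 0)
}

# Row-adaptive Gaussian kernel: S(i,j) = exp(-d_ij^2 / sigma_i^2), sigma_i =
# mean distance from i to all others; diagonal set to 0.
adaptive_kernel <- function(d) {
  np <- nrow(d)
  S <- matrix(0, np, np)
  for (i in seq_len(np)) {
    others <- d[i, -i]
    sigma <- mean(others[is.finite(others)])
    if (!is.finite(sigma) || sigma == 0) {
      # all remaining distances zero (identical vectors): kernel is 1
      S[i, -i] <- ifelse(is.finite(others), 1, 0)
    } else {
      S[i, -i] <- ifelse(is.finite(others), exp(-(others^2) / sigma^2), 0)
    }
  }
  S
}

#' Affinity matrix across parameter combinations
#'
#' For each scan of each subject, computes pairwise cosine distances between
#' the feature vectors of all combinations, converts them with the
#' row-adaptive Gaussian kernel `S(i,j) = exp(-d_ij^2 / sigma_i^2)` (with
#' `sigma_i` the mean distance from vector `i` to all others and a zero
#' diagonal), then averages the per-scan matrices first across scans and
#' second across subjects. Zero-norm feature vectors have undefined cosine
#' distances; their kernel entries are set to 0 with a warning.
#'
#' @param table a [compute_feature_table()] result.
#' @return list with `S_mat` (np x np affinity) and `combos` (the
#'   combination index).
#' @export
build_affinity <- function(table) {
  combos <- attr(table, "combos")
  subjects <- sort(unique(table$subject))
  scans <- expand.grid(day = 1:2, phase = c("LR", "RL"), stringsAsFactors = FALSE)
  dropped <- FALSE
  subj_mats <- lapply(subjects, function(s) {
    scan_mats <- lapply(seq_len(nrow(scans)), function(i) {
      sel <- table$subject == s & table$day == scans$day[i] &
        table$phase == scans$phase[i]
      sub <- table[sel, ]
      sub <- sub[order(sub$combo_id), ]
      M <- do.call(rbind, sub$values)
      d <- cosine_distance(M)
      if (anyNA(d)) dropped <<- TRUE
      adaptive_kernel(d)
    })
    Reduce(`+`, scan_mats) / length(scan_mats)
  })
  if (dropped) {
    warning("zero-norm feature vector(s): undefined distances dropped from kernel")
  }
  S_mat <- Reduce(`+`, subj_mats) / length(subj_mats)
  list(S_mat = S_mat, combos = combos)
}

#' Two-dimensional spectral embedding of an affinity matrix
#'
#' Eigendecomposes the affinity (symmetrized as `(S + t(S))/2` by default,
#' since the row-adaptive kernel is asymmetric; `mode = "raw"` decomposes
#' the asymmetric matrix and takes real parts), orders eigenvectors by
#' descending eigenvalue, applies the package-wide sign convention, and
#' returns the second and third eigenvectors as the two summarizing
#' dimensions.
#'
#' @param affinity a [build_affinity()] result or a plain np x np matrix.
#' @param mode `"symmetric"` or `"raw"`.
#' @return list with `coords` (np x 2 matrix, columns u2 and u3) and
#'   `eigenvalues` (the full descending spectrum).
#' @export
spectral_embed <- function(affinity, mode = c("symmetric", "raw")) {
  mode <- match.arg(mode)
  S <- if (is.list(affinity)) affinity$S_mat else as.matrix(affinity)
  if (!all(is.finite(S))) stop("affinity has non-finite entries")
  if (mode == "symmetric") {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vectors <- e$vectors
    values <- e$values
  } else {
    e <- eigen(S)
    ord <- order(-Re(e$values))
    vectors <- Re(e$vectors[, ord, drop = FALSE])
    values <- Re(e$values[ord])
  }
  vectors <- fix_signs(vectors)
  coords <- vectors[, 2:3, drop = FALSE]
  colnames(coords) <- c("u2", "u3")
  list(coords = coords, eigenvalues = values)
}
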
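# Shared fixtures and independent oracles used across test files.

# Small cohort reused by feature/quality tests (kept tiny so the full grid
# sweeps stay fast).
small_config <- function(seed = 5, ...) {
  cohort_config(n_subjects = 4, n_regions = 24, n_timepoints = 60,
                n_communities = 3, seed = seed, ...)
}

small_cohort_cache <- new.env()
small_cohort <- function() {
  if (is.null(small_cohort_cache$coh)) {
    small_cohort_cache$coh <- generate_cohort(small_config())
  }
  small_cohort_cache$coh
}

# A random connected symmetric nonnegative adjacency matrix.
random_adjacency <- function(R, density = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, R, R)
    ut <- upper.tri(A)
    A[ut] <- stats::rbinom(sum(ut), 1, density) * stats::runif(sum(ut), 0.2, 2)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}

# All permutations of 1..n (exhaustive-search oracle for the assignment).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Best total similarity over all one-to-one assignments, by brute force.
brute_force_best <- function(sim) {
  n <- nrow(sim)
  best <- -Inf
  for (p in all_perms(n)) {
    tot <- sum(sim[cbind(seq_len(n), p)])
    if (tot > best) best <- tot
  }
  best
}

# ICC(A,1) oracle: mean squares extracted from a stats::aov two-way fit,
# plugged into the absolute-agreement single-measurement formula.
icc_a1_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   meas = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ meas + subj, data = df))[[1]][["Mean Sq"]]
  msc <- ms[1]; msr <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force graph filter: build the projector U H U' explicitly and
# multiply matrices.
filter_feature_oracle <- function(spectrum, X, side, nH) {
  R <- nrow(spectrum$U)
  h <- numeric(R)
  if (side == "alignment") h[seq_len(nH)] <- 1 else h[seq(R - nH + 1, R)] <- 1
  V <- if (is.null(spectrum$inner_product_weight)) t(spectrum$U) else
    t(spectrum$U) %*% diag(spectrum$inner_product_weight)
  Xf <- spectrum$U %*% diag(h) %*% V %*% X
  sqrt(rowSums(Xf^2))
}
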
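# GSP feature extraction: transforms, filters, cutoffs and the grid.

test_that("temporal z-scoring standardizes rows under the population-sd convention", {
  X <- rbind(c(1, 2, 3), c(4, 4, 4) + c(-2, 0, 2))
  Z <- preprocess_timecourses(X, zscore = TRUE)
  expect_equal(Z[1, ], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(rowMeans(Z), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(Z^2) / 3), c(1, 1), tolerance = 1e-12)
  # sample-sd variant
  Zs <- preprocess_timecourses(X, zscore = TRUE, sd_type = "sample")
  expect_equal(Zs[1, ], c(-1, 0, 1), tolerance = 1e-12)
  expect_identical(preprocess_timecourses(X, zscore = FALSE), X)
  expect_warning(Zc <- preprocess_timecourses(rbind(c(1, 1, 1), c(1, 2, 3))),
                 "constant")
  expect_equal(Zc[1, ], c(0, 0, 0))
})

test_that("the GFT is the adjoint projection and satisfies Parseval", {
  A <- random_adjacency(10, seed = 5)
  spec <- eigendecompose(build_shift_operator(A, "L_U"))
  X <- matrix(stats::rnorm(10 * 7), 10, 7)
  Xhat <- gft(spec, X)
  expect_equal(colSums(Xhat^2), colSums(X^2), tolerance = 1e-8)  # Parseval
  expect_equal(igft(spec, Xhat), X, tolerance = 1e-8)
  # basis vector maps to a coordinate vector
  expect_equal(gft(spec, spec$U[, 3, drop = FALSE]),
               matrix(as.numeric(1:10 == 3)), tolerance = 1e-8)
  # constant signal on a connected graph lives in harmonic 1 of L_U
  ch <- gft(spec, matrix(1, 10, 1))
  expect_lt(max(abs(ch[-1, ])), 1e-8)
  # identity basis passes signals through
  spec_id <- list(U = diag(10), lam = rep(0, 10), orthonormal = TRUE,
                  inner_product_weight = NULL)
  expect_equal(gft(spec_id, X), X)
})

test_that("the degree-weighted adjoint makes the random-walk GFT invertible", {
  A <- random_adjacency(9, seed = 8)
  spec <- eigendecompose(build_shift_operator(A, "L_RW"))
  X <- matrix(stats::rnorm(9 * 5), 9, 5)
  expect_equal(gft(spec, igft(spec, gft(spec, X))), gft(spec, X),
               tolerance = 1e-8)
  expect_equal(igft(spec, gft(spec, X)), X, tolerance = 1e-8)
  # strict mode uses the plain projection
  expect_equal(gft(spec, X, adjoint = FALSE), crossprod(spec$U, X))
})

test_that("spectral normalization equalizes energy across time and is idempotent", {
  M <- cbind(c(3, 4), c(0.6, 0.8))
  N1 <- spectral_normalize(M)
  expect_equal(N1[, 1], c(0.6, 0.8))
  expect_equal(spectral_normalize(N1), N1, tolerance = 1e-12)
  expect_equal(colSums(N1^2), c(1, 1), tolerance = 1e-10)  # PSD column sums
  expect_warning(Z <- spectral_normalize(cbind(c(1, 2), c(0, 0))), "zero")
  expect_equal(Z[, 2], c(0, 0))
})

test_that("PSD and energy features follow their printed per-timepoint forms", {
  coeffs <- matrix(c(2, -3), 2, 1)
  expect_equal(spectral_feature(coeffs, c(1, 1), "PSD"), c(4, 9))
  expect_equal(spectral_feature(matrix(c(5, 1), 2, 1), c(0, 2), "energy"),
               c(0, 2))
  expect_equal(spectral_feature(matrix(c(5, 2), 2, 1), c(0, 2), "energy",
                                energy_form = "squared"), c(0, 8))
  # multi-timepoint reduction is the L2 norm over time of the representation
  co <- matrix(stats::rnorm(8), 2, 4)
  expect_equal(spectral_feature(co, c(1, 2), "PSD"), sqrt(rowSums((co^2)^2)))
  expect_true(all(spectral_feature(co, c(1, 2), "PSD") >= 0))
})

test_that("graph filters split signals into complementary aligned/liberal parts", {
  A <- random_adjacency(8, seed = 12)
  spec <- eigendecompose(build_shift_operator(A, "L_U"))
  Xconst <- matrix(2, 8, 5)
  expect_equal(graph_filter_feature(spec, Xconst, "alignment", 1),
               sqrt(rowSums(Xconst^2)), tolerance = 1e-8)
  expect_lt(max(graph_filter_feature(spec, Xconst, "liberality", 1)), 1e-8)
  X <- matrix(stats::rnorm(40), 8, 5)
  expect_equal(graph_filter_feature(spec, X, "alignment", 8),
               sqrt(rowSums(X^2)), tolerance = 1e-8)
  # complementarity: alignment(a) + liberality(R - a) reconstruct X
  for (a in c(2, 5)) {
    idx_lo <- 1:a
    lo <- spec$U[, idx_lo] %*% gft(spec, X)[idx_lo, ]
    hi <- spec$U[, -idx_lo] %*% gft(spec, X)[-idx_lo, ]
    expect_equal(lo + hi, X, tolerance = 1e-8)
  }
  expect_error(graph_filter_feature(spec, X, "alignment", 0), "range")
})

test_that("filter features match the brute-force projector oracle", {
  for (kind in c("L_U", "L_N", "L_Q", "L_RW")) {
    A <- random_adjacency(8, seed = 30 + match(kind, c("L_U", "L_N", "L_Q", "L_RW")))
    spec <- eigendecompose(build_shift_operator(A, kind))
    X <- matrix(stats::rnorm(8 * 6), 8, 6)
    for (side in c("alignment", "liberality")) {
      for (nH in c(1, 3, 8)) {
        expect_equal(graph_filter_feature(spec, X, side, nH),
                     filter_feature_oracle(spec, X, side, nH),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("the retained-harmonic grid spans 5-20% of R in 10 steps", {
  expect_equal(coefficients_grid(274),
               as.integer(round(seq(0.05, 0.20, length.out = 10) * 274)))
  expect_identical(coefficients_grid(274),
                   c(14L, 18L, 23L, 27L, 32L, 37L, 41L, 46L, 50L, 55L))
  g100 <- coefficients_grid(100)
  expect_equal(g100[1], 5L)
  expect_equal(g100[10], 20L)
  expect_equal(coefficients_grid(20)[1], 1L)
  expect_length(coefficients_grid(60), 10)
  expect_error(coefficients_grid(8), "nH < 1")
})

test_that("cutoff schemes implement the printed energy-split rules", {
  expect_equal(cutoff_frequency(R = 274, scheme = "f1"), 137)
  psd <- matrix(c(0.4, 0.2, 0.2, 0.2), 4, 1)
  expect_equal(cutoff_frequency(psd, scheme = "f2"), 1)
  # mode over per-timepoint cutoffs, smallest on ties
  psd2 <- cbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.2, 0.3, 0.3),
                c(0.2, 0.2, 0.3, 0.3), c(0.1, 0.1, 0.4, 0.4))
  f2 <- cutoff_frequency(psd2, scheme = "f2")
  expect_equal(f2, c(1, 2, 2, 2))
  expect_equal(cutoff_frequency(psd2, scheme = "f3"), 2)
  # flat PSD: all schemes agree with the half-half split
  flat <- matrix(1, 10, 6)
  expect_equal(cutoff_frequency(flat, scheme = "f2"), rep(5, 6))
  expect_equal(cutoff_frequency(flat, scheme = "f3"), 5)
  expect_equal(cutoff_frequency(flat, scheme = "f4"), 5)
  expect_equal(cutoff_frequency(R = 10, scheme = "f1"), 5)
  expect_warning(fz <- cutoff_frequency(cbind(c(1, 1), c(0, 0)), scheme = "f2"),
                 "all-zero")
  expect_equal(fz[2], 1)  # falls back to floor(R/2) = 1 for R = 2
})

test_that("the SDI contrasts liberal and aligned temporal norms", {
  A <- random_adjacency(8, seed = 14)
  spec <- eigendecompose(build_shift_operator(A, "L_U"))
  # constant signal: no liberal component anywhere
  expect_equal(suppressWarnings(sdi(spec, matrix(3, 8, 4), 2)), rep(0, 8))
  X <- matrix(stats::rnorm(8 * 6), 8, 6)
  for (cutoff in c(1, 4, 7)) {
    idx <- seq_len(cutoff)
    XA <- spec$U[, idx, drop = FALSE] %*% gft(spec, X)[idx, , drop = FALSE]
    XL <- spec$U[, -idx, drop = FALSE] %*% gft(spec, X)[-idx, , drop = FALSE]
    expect_equal(XA + XL, X, tolerance = 1e-8)  # complementary projectors
    expect_equal(sdi(spec, X, cutoff), sqrt(rowSums(XL^2)) / sqrt(rowSums(XA^2)),
                 tolerance = 1e-10)
  }
  expect_true(all(sdi(spec, X, 4) >= 0))
  # per-timepoint cutoffs filter each column with its own split
  cuts <- c(2, 2, 5, 5, 3, 3)
  manual_lib <- matrix(0, 8, 6)
  manual_al <- matrix(0, 8, 6)
  for (t in 1:6) {
    idx <- seq_len(cuts[t])
    manual_al[, t] <- spec$U[, idx] %*% gft(spec, X[, t, drop = FALSE])[idx, ]
    manual_lib[, t] <- spec$U[, -idx] %*% gft(spec, X[, t, drop = FALSE])[-idx, ]
  }
  expect_equal(sdi(spec, X, cuts),
               sqrt(rowSums(manual_lib^2)) / sqrt(rowSums(manual_al^2)),
               tolerance = 1e-10)
  expect_error(sdi(spec, X, 8), "range")
})

test_that("the parameter grid has the expected cardinality per feature type", {
  expect_equal(nrow(enumerate_combinations("PSD", 274)), 128)
  expect_equal(nrow(enumerate_combinations("energy", 274)), 128)
  expect_equal(nrow(enumerate_combinations("alignment", 274)), 1280)
  expect_equal(nrow(enumerate_combinations("liberality", 274)), 1280)
  expect_equal(nrow(enumerate_combinations("SDI", 274)), 512)
})

test_that("feature tables are complete, deterministic and degenerate-consistent", {
  coh <- small_cohort()
  combos <- enumerate_combinations("PSD", coh$config$n_regions)
  tab <- compute_feature_table(coh, "PSD")
  expect_equal(nrow(tab), 4 * 4 * 128)  # S x scans x combos
  expect_true(all(lengths(tab$values) == coh$config$n_regions))
  tab2 <- compute_feature_table(coh, "PSD")
  expect_identical(tab$values, tab2$values)
  # with zero connectome jitter, group and individual SCs give identical features
  coh0 <- generate_cohort(small_config(subject_sc_jitter = 0))
  sub_combos <- combos[combos$operator == "L_U" & combos$zscore &
                         !combos$normalize, ]
  tab0 <- compute_feature_table(coh0, "PSD", combos = sub_combos)
  for (p in unique(sub_combos$property)) {
    ids <- sub_combos$combo_id[sub_combos$property == p]
    vg <- tab0$values[tab0$combo_id == ids[1]]
    vi <- tab0$values[tab0$combo_id == ids[2]]
    expect_equal(vg, vi, tolerance = 1e-10)
  }
})
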
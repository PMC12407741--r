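# Graph shift operators and connectome harmonics.
#
# Four operators are supported, all built from a symmetric nonnegative
# connectome A with degree vector k = rowSums(A) and total weight M = sum(k):
#   L_U  = D - A                      (unnormalized Laplacian)
#   L_N  = D^{+1/2} L D^{+1/2}        (normalized Laplacian, pseudo-inverse
#                                      degrees so isolated nodes are handled)
#   L_RW = D^{+} L                    (random-walk Laplacian)
#   L_Q  = A - k k' / (2 M)           (modularity matrix; an optional flag
#                                      switches to the Newman scaling k k'/M)
# Eigenvalues are always reported in ascending order; harmonics with the
# smallest eigenvalues vary smoothly over the graph.

#' Average subject connectomes into a group connectome
#'
#' @param subject_scs list of [structural_connectome()] objects sharing the
#'   same dimension and property.
#' @return element-wise mean connectome with scope `"group"`.
#' @export
build_group_sc <- function(subject_scs) {
  stopifnot(length(subject_scs) >= 1)
  props <- vapply(subject_scs, function(s) s$property, character(1))
  dims <- vapply(subject_scs, function(s) nrow(s$weights), integer(1))
  if (length(unique(props)) != 1 || length(unique(dims)) != 1) {
    stop("subject connectomes must share property and dimension")
  }
  W <- Reduce(`+`, lapply(subject_scs, `[[`, "weights")) / length(subject_scs)
  structural_connectome(W, property = props[1], scope = "group")
}

#' Build a graph shift operator from a structural connectome
#'
#' @param sc a [structural_connectome()] or a plain symmetric nonnegative
#'   matrix.
#' @param kind operator kind: `"L_U"`, `"L_N"`, `"L_RW"` or `"L_Q"`.
#' @param modularity_scale for `L_Q` only: `"half"` uses `k k'/(2M)` (the
#'   default), `"newman"` the standard modularity scaling `k k'/M` (whose row
#'   sums are exactly zero).
#' @return an object of class `shift_operator` with fields `matrix`, `kind`,
#'   `degree` and `total_weight`.
#' @export
build_shift_operator <- function(sc, kind = c("L_U", "L_N", "L_RW", "L_Q"),
                                 modularity_scale = c("half", "newman")) {
  kind <- match.arg(kind)
  modularity_scale <- match.arg(modularity_scale)
  A <- if (inherits(sc, "structural_connectome")) sc$weights else as.matrix(sc)
  if (any(A < 0)) stop("negative edge weights are invalid")
  A <- (A + t(A)) / 2
  diag(A) <- 0
  k <- rowSums(A)
  M <- sum(k)
  L <- diag(k) - A
  inv_sqrt <- ifelse(k > 0, 1 / sqrt(k), 0)  # Moore-Penrose inverse of D
  inv <- ifelse(k > 0, 1 / k, 0)
  mat <- switch(kind,
    L_U = L,
    L_N = {
      Ln <- inv_sqrt * t(inv_sqrt * L)  # D^{+1/2} L D^{+1/2}
      (Ln + t(Ln)) / 2
    },
    L_RW = inv * L,
    L_Q = A - (k %o% k) / switch(modularity_scale, half = 2 * M, newman = M)
  )
  structure(
    list(matrix = mat, kind = kind, degree = k, total_weight = M,
         modularity_scale = if (kind == "L_Q") modularity_scale else NULL),
    class = "shift_operator"
  )
}

# Deterministic sign convention: flip each column so its largest-magnitude
# entry (first such entry on ties) is positive.
fix_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Eigendecompose a shift operator into connectome harmonics
#'
#' Returns the eigenvector basis U (column k = harmonic k) with eigenvalues
#' sorted in ascending order. For the symmetric kinds (`L_U`, `L_N`, `L_Q`)
#' the basis is orthonormal. `L_RW` is not symmetric; it is solved as the
#' generalized symmetric problem `L u = lambda D u` restricted to
#' positive-degree nodes, which yields real eigenvalues identical to those of
#' `L_N` and a basis orthonormal under the degree-weighted inner product
#' (recorded in `inner_product_weight`). Isolated nodes contribute indicator
#' harmonics at eigenvalue 0. Eigenvector signs follow a fixed convention
#' (largest-magnitude entry positive); eigenvalue ties keep stable order.
#'
#' @param op a `shift_operator`.
#' @return an object of class `graph_spectrum`: list with `U`, `lam`, `kind`,
#'   `orthonormal`, `inner_product_weight` (degrees, for `L_RW` only) and
#'   `degree`.
#' @export
eigendecompose <- function(op) {
  stopifnot(inherits(op, "shift_operator"))
  if (!all(is.finite(op$matrix))) stop("operator has non-finite entries")
  R <- nrow(op$matrix)
  if (op$kind != "L_RW") {
    e <- eigen((op$matrix + t(op$matrix)) / 2, symmetric = TRUE)
    ord <- rev(seq_len(R))  # eigen() returns descending; flip to ascending
    spec <- list(U = fix_signs(e$vectors[, ord, drop = FALSE]),
                 lam = e$values[ord], kind = op$kind, orthonormal = TRUE,
                 inner_product_weight = NULL, degree = op$degree)
  } else {
    k <- op$degree
    pos <- which(k > 0)
    iso <- which(k == 0)
    A <- diag(k) - (op$matrix * k)  # recover L = D * L_RW, then A = D - L
    # normalized Laplacian on the positive-degree subgraph
    Ap <- A[pos, pos, drop = FALSE]
    kp <- k[pos]
    Lp <- diag(kp) - Ap
    s <- 1 / sqrt(kp)
    Ln <- s * t(s * Lp)
    e <- eigen((Ln + t(Ln)) / 2, symmetric = TRUE)
    ordp <- rev(seq_along(pos))
    Up <- s * e$vectors[, ordp, drop = FALSE]  # D^{-1/2} transform back
    lamp <- e$values[ordp]
    U <- matrix(0, R, R)
    lam <- numeric(R)
    U[pos, seq_along(pos)] <- Up
    lam[seq_along(pos)] <- lamp
    if (length(iso) > 0) {
      for (j in seq_along(iso)) U[iso[j], length(pos) + j] <- 1
      lam[length(pos) + seq_along(iso)] <- 0
    }
    ord <- order(lam)  # stable on ties
    spec <- list(U = fix_signs(U[, ord, drop = FALSE]), lam = lam[ord],
                 kind = op$kind, orthonormal = FALSE,
                 inner_product_weight = k, degree = op$degree)
  }
  structure(spec, class = "graph_spectrum")
}
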
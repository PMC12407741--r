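# GSP feature extraction: temporal z-scoring, graph Fourier transform,
# spectral normalization, and the five structure/function coupling feature
# types (PSD, energy, alignment, liberality, SDI) across the full grid of
# pipeline parameters. Every R x T representation is reduced to a length-R
# feature vector by the L2-norm over time.

#' Temporal preprocessing of regional time courses
#'
#' Optionally z-scores each regional time course to mean 0 and sd 1. The sd
#' convention is the population sd (divide by T) by default, matching common
#' fMRI practice; `sd_type = "sample"` divides by T - 1. Constant rows cannot
#' be standardized and are set to zero with a warning.
#'
#' @param X R x T numeric matrix of regional time courses.
#' @param zscore logical; if `FALSE`, `X` is passed through unchanged.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return matrix of the same dimension.
#' @export
preprocess_timecourses <- function(X, zscore = TRUE,
                                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("time courses contain non-finite values")
  if (!zscore) return(X)
  T <- ncol(X)
  if (T < 2) stop("z-scoring requires at least 2 time points")
  mu <- rowMeans(X)
  Xc <- X - mu
  denom <- if (sd_type == "population") T else T - 1
  s <- sqrt(rowSums(Xc^2) / denom)
  const <- s <= 1e-14 * max(1, max(abs(X)))
  if (any(const)) {
    warning(sum(const), " constant row(s) set to zero during z-scoring")
    s[const] <- 1
    Xc[const, ] <- 0
  }
  Xc / s
}

#' Graph Fourier transform
#'
#' Projects regional signals onto the harmonic basis: `Xhat = U' X` for
#' orthonormal bases. For the random-walk Laplacian the basis is orthonormal
#' under the degree-weighted inner product, so the analysis step uses the
#' adjoint `U' diag(k) X` (guaranteeing `gft(igft(Y)) = Y`); set
#' `adjoint = FALSE` to use the plain `U' X` projection for all kinds.
#'
#' @param spectrum a [eigendecompose()] result.
#' @param X R x T matrix.
#' @param adjoint logical, see above.
#' @return R x T matrix of spectral coefficients (row k = harmonic k).
#' @export
gft <- function(spectrum, X, adjoint = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(spectrum$U)) stop("basis/signal dimension mismatch")
  w <- spectrum$inner_product_weight
  if (adjoint && !is.null(w)) {
    crossprod(spectrum$U, w * X)
  } else {
    crossprod(spectrum$U, X)
  }
}

#' Inverse graph Fourier transform
#'
#' @param spectrum a [eigendecompose()] result.
#' @param coeffs R x T matrix of spectral coefficients.
#' @return R x T matrix in the region domain (`U %*% coeffs`).
#' @export
igft <- function(spectrum, coeffs) {
  spectrum$U %*% as.matrix(coeffs)
}

#' Spectral energy normalization
#'
#' Divides each time-point column of the spectral coefficients by its L2
#' norm, so that signal energy is equal throughout time. Zero columns are
#' left unchanged with a warning.
#'
#' @param coeffs R x T matrix of spectral coefficients.
#' @return normalized matrix.
#' @export
spectral_normalize <- function(coeffs) {
  coeffs <- as.matrix(coeffs)
  nrm <- sqrt(colSums(coeffs^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero column(s) left unnormalized")
    nrm[zero] <- 1
  }
  sweep(coeffs, 2, nrm, "/")
}

#' Spectral-domain feature vectors: PSD and energy
#'
#' PSD is the squared spectral coefficient per harmonic and time point,
#' `P[t,k] = xhat[t,k]^2`; energy weights the coefficient by its eigenvalue,
#' `E[t,k] = lambda_k * xhat[t,k]` (the default printed form), with
#' `energy_form = "squared"` providing the variant `lambda_k * xhat[t,k]^2`.
#' The R x T representation is reduced by the L2 norm over time per harmonic.
#'
#' @param coeffs R x T spectral coefficients.
#' @param lam length-R eigenvalues (ascending).
#' @param mode `"PSD"` or `"energy"`.
#' @param energy_form `"linear"` (as printed) or `"squared"`.
#' @return length-R feature vector over harmonics.
#' @export
spectral_feature <- function(coeffs, lam, mode = c("PSD", "energy"),
                             energy_form = c("linear", "squared")) {
  mode <- match.arg(mode)
  energy_form <- match.arg(energy_form)
  coeffs <- as.matrix(coeffs)
  stopifnot(length(lam) == nrow(coeffs))
  rep_mat <- switch(mode,
    PSD = coeffs^2,
    energy = switch(energy_form,
      linear = lam * coeffs,
      squared = lam * coeffs^2
    )
  )
  row_l2(rep_mat)
}

# Indices of the retained harmonics for one filter side.
filter_index <- function(R, side, nH) {
  if (nH < 1 || nH > R) stop("nH out of range [1, R]")
  if (side == "alignment") seq_len(nH) else seq(R - nH + 1, R)
}

#' Graph-filtered regional feature vectors: alignment and liberality
#'
#' Filters the signal in the spectral domain with an ideal 0/1 filter H and
#' reconstructs `X_F = U H Uᵀ X`. Alignment retains the `nH` lowest-index
#' harmonics (low-pass: the component in line with structure); liberality
#' retains the `nH` highest-index harmonics (high-pass: activity decoupled
#' from structure). Reduced by the L2 norm over time per region.
#'
#' @param spectrum a [eigendecompose()] result.
#' @param X R x T matrix (already preprocessed as desired).
#' @param side `"alignment"` or `"liberality"`.
#' @param nH number of harmonics to retain, in `[1, R]`.
#' @param normalize logical; apply [spectral_normalize()] to the coefficients
#'   before filtering.
#' @return length-R feature vector over regions.
#' @export
graph_filter_feature <- function(spectrum, X, side = c("alignment", "liberality"),
                                 nH, normalize = FALSE) {
  side <- match.arg(side)
  idx <- filter_index(nrow(spectrum$U), side, nH)
  Xhat <- gft(spectrum, X)
  if (normalize) Xhat <- spectral_normalize(Xhat)
  Xf <- spectrum$U[, idx, drop = FALSE] %*% Xhat[idx, , drop = FALSE]
  row_l2(Xf)
}

#' Grid of retained-harmonic counts
#'
#' The number of harmonics `nH` for alignment/liberality ranges from 5% to
#' 20% of R in 10 uniform steps; each percentage is converted to a count by
#' nearest-integer rounding (half away from zero). Duplicates are kept so the
#' grid size is always 10.
#'
#' @param R number of regions (must give `nH >= 1` at 5%).
#' @return integer vector of length 10.
#' @export
coefficients_grid <- function(R) {
  pct <- seq(0.05, 0.20, length.out = 10)
  nH <- round_half_away(pct * R)
  if (any(nH < 1)) stop("R too small: the 5% grid point gives nH < 1")
  as.integer(nH)
}

#' Cutoff frequency for the structural decoupling index
#'
#' Partitions the harmonics into a low-frequency (aligned) and a
#' high-frequency (liberal) set. Four schemes: `f1 = floor(R/2)` (half-half
#' split); `f2` equates energy per time point on the cumulative PSD (largest
#' `f` with cumulative `P_t(f) <= 0.5`, one cutoff per time point, clamped to
#' `[1, R-1]`); `f3 = mode(f2)` (smallest on ties); `f4` applies the `f2`
#' rule to the time-averaged cumulative PSD.
#'
#' @param psd R x T matrix of per-harmonic, per-time-point PSD values
#'   (required for `f2`-`f4`; may be `NULL` for `f1`).
#' @param R number of harmonics.
#' @param scheme one of `"f1"`, `"f2"`, `"f3"`, `"f4"`.
#' @return a scalar cutoff, or a length-T vector for `f2`.
#' @export
cutoff_frequency <- function(psd = NULL, R = nrow(psd),
                             scheme = c("f1", "f2", "f3", "f4")) {
  scheme <- match.arg(scheme)
  f1 <- floor(R / 2)
  if (scheme == "f1") return(f1)
  if (is.null(psd) || nrow(psd) == 0) stop("schemes f2-f4 require a PSD matrix")
  psd <- as.matrix(psd)
  half_split <- function(p) {
    tot <- sum(p)
    if (tot == 0) return(NA_integer_)
    cum <- cumsum(p) / tot
    f <- max(0, which(cum <= 0.5), na.rm = TRUE)
    min(max(f, 1L), R - 1L)
  }
  if (scheme == "f4") {
    f <- half_split(rowMeans(psd))
    if (is.na(f)) {
      warning("all-zero PSD; falling back to the half-half split")
      f <- f1
    }
    return(f)
  }
  f2 <- apply(psd, 2, half_split)
  if (anyNA(f2)) {
    warning(sum(is.na(f2)), " all-zero PSD time point(s) set to the half-half split")
    f2[is.na(f2)] <- f1
  }
  if (scheme == "f2") f2 else stat_mode(f2)
}

#' Structural decoupling index
#'
#' Per-region ratio of the temporal L2 norms of the liberal (high-pass) and
#' aligned (low-pass) signal components, `SDI_r = ||X_L[r,]|| / ||X_A[r,]||`,
#' where the low set comprises harmonics `1..cutoff`. With a per-time-point
#' cutoff vector (scheme `f2`) each column is filtered with its own split
#' before the temporal norms. A zero aligned norm with nonzero liberal norm
#' yields `Inf`; 0/0 yields 0 (both with a warning).
#'
#' @param spectrum a [eigendecompose()] result.
#' @param X R x T matrix (already preprocessed as desired).
#' @param cutoff scalar in `[1, R-1]`, or length-T integer vector.
#' @param normalize logical; apply [spectral_normalize()] before filtering.
#' @return length-R feature vector over regions.
#' @export
sdi <- function(spectrum, X, cutoff, normalize = FALSE) {
  R <- nrow(spectrum$U)
  T <- ncol(as.matrix(X))
  if (!(length(cutoff) == 1 || length(cutoff) == T)) {
    stop("cutoff must be scalar or one value per time point")
  }
  if (any(cutoff < 1 | cutoff > R - 1)) stop("cutoff out of range [1, R-1]")
  Xhat <- gft(spectrum, X)
  if (normalize) Xhat <- spectral_normalize(Xhat)
  out <- sdi_from_coeffs(spectrum, Xhat, cutoff)
  n00 <- attr(out, "n_zero_zero")
  ninf <- attr(out, "n_inf")
  if (n00 > 0) warning(n00, " region(s) with 0/0 SDI set to 0")
  if (ninf > 0) warning(ninf, " region(s) with zero aligned norm set to Inf")
  as.numeric(out)
}

#' Enumerate the parameter-combination grid for one feature type
#'
#' The base grid crosses edge property (4) x structural individuality (2) x
#' operator (4) x temporal z-scoring (2) x spectral normalization (2) = 128
#' combinations. Alignment and liberality extend it by the 10 retained-
#' harmonic counts (1280); the SDI by the 4 cutoff schemes (512).
#'
#' @param feature_type one of `"PSD"`, `"energy"`, `"alignment"`,
#'   `"liberality"`, `"SDI"`.
#' @param R number of regions (used to resolve the `nH` grid).
#' @return data.frame of combinations with a `combo_id` column.
#' @export
enumerate_combinations <- function(feature_type = c("PSD", "energy", "alignment",
                                                    "liberality", "SDI"),
                                   R = 274) {
  feature_type <- match.arg(feature_type)
  base <- expand.grid(
    property = SC_PROPERTIES,
    individuality = c("group", "individual"),
    operator = c("L_U", "L_N", "L_RW", "L_Q"),
    zscore = c(TRUE, FALSE),
    normalize = c(TRUE, FALSE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  combos <- if (feature_type %in% c("alignment", "liberality")) {
    grid <- data.frame(nH_pct = seq(0.05, 0.20, length.out = 10),
                       nH = coefficients_grid(R))
    merge(base, grid, by = NULL)
  } else if (feature_type == "SDI") {
    merge(base, data.frame(cutoff_scheme = c("f1", "f2", "f3", "f4")), by = NULL)
  } else {
    base
  }
  combos$feature_type <- feature_type
  combos$combo_id <- seq_len(nrow(combos))
  combos
}

#' Compute the full feature table for a cohort
#'
#' Orchestrates the pipeline for every scan and parameter combination:
#' select the group or subject connectome of the requested property, build
#' the shift operator, eigendecompose (cached per connectome x operator),
#' preprocess the time courses, apply the GFT and optional spectral
#' normalization, and compute the requested feature vector.
#'
#' @param cohort a `gsp_cohort`.
#' @param feature_type one of the five feature types.
#' @param combos combination grid (default: the full
#'   [enumerate_combinations()] grid for the variant's region count). If a
#'   grid with an `nH_pct` column is supplied, `nH` is re-resolved for the
#'   variant's region count.
#' @param variant parcellation variant to apply first.
#' @return data.frame with one row per scan x combination: scan metadata,
#'   the combination columns, and a `values` list column holding the
#'   length-R feature vector.
#' @export
compute_feature_table <- function(cohort, feature_type,
                                  combos = NULL,
                                  variant = c("S3", "S3minus", "S1")) {
  variant <- match.arg(variant)
  cohort <- apply_variant(cohort, variant)
  R <- nrow(cohort$group_sc[[1]]$weights)
  if (is.null(combos)) {
    combos <- enumerate_combinations(feature_type, R)
  } else if (!is.null(combos$nH_pct)) {
    combos$nH <- as.integer(round_half_away(combos$nH_pct * R))
  }
  meta <- cohort$meta
  n_scans <- nrow(meta)

  spectra <- new.env(parent = emptyenv())
  get_spectrum <- function(scope, property, operator, subject) {
    key <- paste(scope, property, operator, sep = "|")
    if (!is.null(spectra[[key]])) return(spectra[[key]])
    sc <- if (scope == "group") cohort$group_sc[[property]] else
      cohort$subject_scs[[subject]][[property]]
    spec <- eigendecompose(build_shift_operator(sc, operator))
    spectra[[key]] <- spec
    spec
  }

  out <- vector("list", n_scans * nrow(combos))
  row <- 0L
  for (i in seq_len(n_scans)) {
    subject <- meta$subject[i]
    X_raw <- cohort$timeseries[[i]]
    Xz_cache <- list(`TRUE` = NULL, `FALSE` = X_raw)
    coef_cache <- new.env(parent = emptyenv())
    for (ci in seq_len(nrow(combos))) {
      cmb <- combos[ci, ]
      scope <- if (cmb$individuality == "group") "group" else paste0("sub-", subject)
      spec <- get_spectrum(scope, cmb$property, cmb$operator, subject)
      zkey <- as.character(cmb$zscore)
      if (is.null(Xz_cache[[zkey]])) {
        Xz_cache[[zkey]] <- preprocess_timecourses(X_raw, zscore = TRUE)
      }
      Xz <- Xz_cache[[zkey]]
      ckey <- paste(scope, cmb$property, cmb$operator, cmb$zscore, cmb$normalize,
                    sep = "|")
      if (is.null(coef_cache[[ckey]])) {
        Xhat <- gft(spec, Xz)
        if (cmb$normalize) Xhat <- spectral_normalize(Xhat)
        coef_cache[[ckey]] <- Xhat
      }
      Xhat <- coef_cache[[ckey]]
      values <- switch(feature_type,
        PSD = spectral_feature(Xhat, spec$lam, "PSD"),
        energy = spectral_feature(Xhat, spec$lam, "energy"),
        alignment = ,
        liberality = {
          idx <- filter_index(R, feature_type, cmb$nH)
          row_l2(spec$U[, idx, drop = FALSE] %*% Xhat[idx, , drop = FALSE])
        },
        SDI = {
          cut <- if (cmb$cutoff_scheme == "f1") {
            cutoff_frequency(R = R, scheme = "f1")
          } else {
            cutoff_frequency(Xhat^2, R = R, scheme = cmb$cutoff_scheme)
          }
          cut <- pmin(pmax(cut, 1L), R - 1L)
          as.numeric(sdi_from_coeffs(spec, Xhat, cut))
        }
      )
      row <- row + 1L
      out[[row]] <- list(subject = subject, day = meta$day[i],
                         phase = meta$phase[i], mean_fd = meta$mean_fd[i],
                         combo_id = cmb$combo_id, values = values)
    }
  }
  tab <- data.frame(
    subject = vapply(out, `[[`, numeric(1), "subject"),
    day = vapply(out, `[[`, numeric(1), "day"),
    phase = vapply(out, `[[`, character(1), "phase"),
    mean_fd = vapply(out, `[[`, numeric(1), "mean_fd"),
    combo_id = vapply(out, `[[`, numeric(1), "combo_id"),
    stringsAsFactors = FALSE
  )
  tab$values <- I(lapply(out, `[[`, "values"))
  attr(tab, "combos") <- combos
  attr(tab, "feature_type") <- feature_type
  attr(tab, "n_coefficients") <- R
  tab
}

# SDI from precomputed spectral coefficients (shared by sdi() and the table
# sweep); cutoff may be scalar or per time point.
sdi_from_coeffs <- function(spectrum, Xhat, cutoff) {
  R <- nrow(spectrum$U)
  T <- ncol(Xhat)
  aligned_sq <- numeric(R)
  liberal_sq <- numeric(R)
  for (f in unique(cutoff)) {
    cols <- if (length(cutoff) == 1) seq_len(T) else which(cutoff == f)
    low <- seq_len(f)
    XA <- spectrum$U[, low, drop = FALSE] %*% Xhat[low, cols, drop = FALSE]
    XL <- spectrum$U[, -low, drop = FALSE] %*% Xhat[-low, cols, drop = FALSE]
    aligned_sq <- aligned_sq + rowSums(XA^2)
    liberal_sq <- liberal_sq + rowSums(XL^2)
  }
  out <- sqrt(liberal_sq) / sqrt(aligned_sq)
  zero_zero <- aligned_sq == 0 & liberal_sq == 0
  inf_case <- aligned_sq == 0 & liberal_sq > 0
  out[zero_zero] <- 0
  out[inf_case] <- Inf
  structure(out, n_zero_zero = sum(zero_zero), n_inf = sum(inf_case))
}

#' Write a feature table to plain-text files
#'
#' Writes `index.csv` (scan metadata and combination columns) and
#' `values.csv` (one row of feature values per index row).
#'
#' @param table a [compute_feature_table()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_feature_table <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  combos <- attr(table, "combos")
  idx <- merge(table[, c("subject", "day", "phase", "mean_fd", "combo_id")],
               combos, by = "combo_id", sort = FALSE)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  vals <- do.call(rbind, table$values)
  utils::write.table(vals, file.path(dir, "values.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
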
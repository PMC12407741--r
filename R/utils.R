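# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for all index grids (`round()` in R rounds half
#' to even, which is platform-stable but surprising for grid construction).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a reproducible child seed (< 2^31) from a master seed and an index.
# Plain integer arithmetic on doubles; exact for the magnitudes involved.
child_seed <- function(seed, index) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 9973) %% 2147483647
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so cohort generation does not perturb
# user-level randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Pearson correlation that returns NA (without a warning flood) when either
# input has zero or undefined variance.
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# L2 norm of each row of a matrix.
row_l2 <- function(m) {
  sqrt(rowSums(m^2))
}

# Statistical mode; smallest value on ties.
stat_mode <- function(x) {
  ux <- sort(unique(x))
  counts <- vapply(ux, function(v) sum(x == v), numeric(1))
  ux[which.max(counts)]
}
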
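# Internal helpers shared across the package.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Column-wise midranks (average ranks for ties). For the small participant
# counts used here (n <= 40) an O(n^2 m) counting scheme beats m calls to
# rank(); larger inputs fall back to apply().
col_ranks <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n > 40L) return(apply(x, 2L, rank))
  r <- matrix(0, n, m)
  for (i in seq_len(n)) {
    xi <- rep(x[i, ], each = n)
    r[i, ] <- colSums(x < xi) + (colSums(x == xi) + 1) / 2
  }
  r
}

# Projection matrix removing the column space of [1, z_ranks] (or just the
# intercept when the covariate ranks are constant).
rank_residual_projector <- function(z_ranks) {
  n <- length(z_ranks)
  z <- if (stats::var(z_ranks) > 0) cbind(1, z_ranks) else matrix(1, n, 1L)
  diag(n) - z %*% solve(crossprod(z), t(z))
}

# Two-sided p for a (partial) correlation on df degrees of freedom.
rho_pvalue <- function(rho, df) {
  t <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df)
}

# |rho| threshold equivalent to a two-sided p < alpha at df degrees of freedom.
rho_critical <- function(alpha, df) {
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(df + tc^2)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
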
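#' Age-partialed Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariate `z` (midranks for ties),
#' residualizes the ranks of `x` and of `y` on `[1, ranks(z)]` by least
#' squares, and correlates the residuals. The two-sided p-value uses a t
#' reference distribution on `n - 3` degrees of freedom. When the covariate
#' is constant the statistic reduces to the plain Spearman correlation of
#' `x` and `y` (the p-value keeps `n - 3` df for consistency across the map).
#'
#' @param x,y Numeric vectors, length n >= 5, no missing values.
#' @param z Covariate vector (default constant, i.e. no partialing).
#' @return List with `rho` and `p`.
#' @export
partial_spearman <- function(x, y, z = rep(0, length(x))) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 5L) stopf("need at least 5 observations")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stopf("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stopf("constant input after ranking; correlation undefined")
  proj <- rank_residual_projector(rank(z))
  ex <- drop(proj %*% rx)
  ey <- drop(proj %*% ry)
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  rho <- max(-1, min(1, rho))
  list(rho = rho, p = rho_pvalue(rho, n - 3L))
}

#' Node x frequency correlation maps
#'
#' Applies the age-partialed Spearman correlation independently at every
#' (node, frequency-step) cell of a post/pre ratio tensor against the CPT
#' commission ratio. Cells whose power ratio is constant across participants
#' have an undefined correlation and are returned as `NA`; a map whose cells
#' are all undefined is flagged invalid.
#'
#' @param ratio A ratio `power_tensor` (participants x nodes x steps).
#' @param cpt_ratio Per-participant behavioural ratio, in tensor participant
#'   order.
#' @param age Per-participant covariate (years).
#' @return A `correlation_map`: matrices `rho` and `pval` (nodes x steps),
#'   `covariate_name`, `freq_axis`, `n`, and a `valid` flag.
#' @export
correlation_maps <- function(ratio, cpt_ratio, age) {
  eng <- pcorr_engine(ratio, age)
  rho <- eng$rho(rank(cpt_ratio))
  n <- eng$n
  map <- structure(list(
    rho = matrix(rho, eng$n_nodes, eng$n_steps),
    pval = matrix(rho_pvalue(rho, n - 3L), eng$n_nodes, eng$n_steps),
    covariate_name = "age", freq_axis = ratio$freq_axis, n = n,
    valid = !all(is.na(rho))), class = "correlation_map")
  if (!map$valid)
    warnf("all cells are constant across participants; correlation map is invalid")
  map
}

# Precomputes everything reusable across permutations of the behavioural
# ratio: column ranks of the ratio tensor, the rank-residual projector for
# the covariate, and the residualized, column-standardized rank matrix. The
# returned rho(q_ranks) evaluates the full partial-Spearman map for one
# (possibly permuted) behavioural rank vector as a single matrix product.
pcorr_engine <- function(ratio, age) {
  v <- ratio$values
  p <- dim(v)[1]; n_nodes <- dim(v)[2]; n_steps <- dim(v)[3]
  if (length(age) != p) stopf("age must have one value per participant")
  if (p < 5L) stopf("need at least 5 participants")
  m <- matrix(v, p, n_nodes * n_steps)
  rk <- col_ranks(m)
  proj <- rank_residual_projector(rank(age))
  pm <- proj %*% rk
  norms <- sqrt(colSums(pm^2))
  ok <- norms > 1e-10
  pm[, ok] <- sweep(pm[, ok, drop = FALSE], 2L, norms[ok], "/")
  pm[, !ok] <- 0
  list(
    n = p, n_nodes = n_nodes, n_steps = n_steps, ok = ok,
    rho = function(q_ranks) {
      q <- drop(proj %*% q_ranks)
      qn <- sqrt(sum(q^2))
      if (qn < 1e-10) return(rep(NA_real_, length(ok)))
      r <- drop(crossprod(pm, q)) / qn
      r[!ok] <- NA_real_
      pmax(-1, pmin(1, r))
    })
}
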
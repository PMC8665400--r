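# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's computational paths.

# midranks by counting
oracle_rank <- function(v) {
  vapply(seq_along(v), function(i)
    1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2, numeric(1))
}

# age-partialed Spearman via explicit rank regression (normal equations)
oracle_partial_spearman <- function(x, y, z) {
  rx <- oracle_rank(x); ry <- oracle_rank(y); rz <- oracle_rank(z)
  n <- length(x)
  zz <- if (length(unique(rz)) > 1) cbind(1, rz) else cbind(rep(1, n))
  bx <- solve(t(zz) %*% zz, t(zz) %*% rx)
  by <- solve(t(zz) %*% zz, t(zz) %*% ry)
  ex <- rx - zz %*% bx
  ey <- ry - zz %*% by
  r <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  tt <- r * sqrt((n - 3) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tt), n - 3))
}

# connected components by boolean transitive closure on an explicit cell
# adjacency matrix; cells is a k x 2 (node, step) matrix, edges a spatial
# edge list. Returns a list of sorted member-index vectors, one per component.
oracle_components <- function(cells, edges, n_nodes) {
  k <- nrow(cells)
  a <- diag(k) > 0
  edge_set <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    same_step <- cells[i, 2] == cells[j, 2]
    spatial <- paste(min(cells[i, 1], cells[j, 1]),
                     max(cells[i, 1], cells[j, 1])) %in% edge_set
    temporal <- cells[i, 1] == cells[j, 1] && abs(cells[i, 2] - cells[j, 2]) == 1
    if ((same_step && spatial) || temporal) a[i, j] <- TRUE
  }
  repeat {
    a2 <- (a %*% a) > 0 | a
    if (identical(a2, a)) break
    a <- a2
  }
  unique(lapply(seq_len(k), function(i) sort(which(a[i, ]))))
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# regular 2D grid graph (rows x cols), spacing 10 mm, z = 0
grid_graph <- function(nr, nc, spacing = 10) {
  coords <- as.matrix(expand.grid(x = seq_len(nr) * spacing,
                                  y = seq_len(nc) * spacing, z = 0))
  build_spatial_adjacency(coords, d_max = 1.05 * spacing)
}

# minimal valid cohort data.frame with n participants
tiny_cohort <- function(n = 8, seed = 42) {
  with_seed_local(seed, {
    arm <- rep(c("experimental", "control"), length.out = n)
    pre <- stats::rnorm(n, 50, 8)
    cohort_table(data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      arm = arm, age = stats::runif(n, 8, 11),
      sex = sample(c("M", "F"), n, replace = TRUE),
      medicated = sample(c(TRUE, FALSE), n, replace = TRUE),
      psych_treatment = FALSE,
      cpt_commission_pre = pre,
      cpt_commission_post = pre + stats::rnorm(n, -2, 4)))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# correlation_map built directly from matrices (for hand-made fixtures)
manual_map <- function(rho, pval, freq_axis = seq_len(ncol(rho))) {
  structure(list(rho = rho, pval = pval, covariate_name = "age",
                 freq_axis = freq_axis, n = 29, valid = TRUE),
            class = "correlation_map")
}
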
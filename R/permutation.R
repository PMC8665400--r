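#' Spatio-spectral cluster permutation test
#'
#' The package's core inference: node x frequency age-partialed Spearman
#' correlation maps between the post/pre power ratio and the behavioural
#' (CPT commission) post/pre ratio, sign-consistent spatio-spectral
#' clustering, and max-statistic permutation control of the familywise error
#' rate at the cluster level.
#'
#' Observed clusters are formed once from the unshuffled data. For each of
#' `params$n_permutations` permutations the behavioural ratio is shuffled
#' across participants (power and age stay with their participant), the full
#' map-to-cluster pipeline is re-run, and the maximum absolute surrogate
#' cluster mass is recorded (0 when no surrogate cluster survives, a
#' conservative standard convention). Each observed cluster's p-value is
#' `(count of null maxima >= |mass| + 1) / (n_permutations + 1)`.
#'
#' @param ratio A ratio `power_tensor` (see [compute_ratio_tensor()]).
#' @param cpt_ratio Per-participant behavioural ratio, in tensor participant
#'   order (see [compute_cpt_ratio()]).
#' @param age Per-participant covariate (years).
#' @param graph A `source_graph`.
#' @param params A [cluster_params()].
#' @param shuffle_age If `TRUE`, age is shuffled jointly with the behavioural
#'   ratio; default `FALSE` (age stays paired with the power data).
#' @return A `spectral_cluster_test` object: `clusters`, `p_values`,
#'   `null_max_mass`, `map` (observed correlation map), `n_permutations`,
#'   `seed`, `params`.
#' @export
spectral_cluster_test <- function(ratio, cpt_ratio, age, graph,
                                  params = cluster_params(),
                                  shuffle_age = FALSE) {
  stopifnot(inherits(ratio, "power_tensor"), inherits(graph, "source_graph"),
            inherits(params, "cluster_params"))
  p <- dim(ratio$values)[1]
  if (length(cpt_ratio) != p || length(age) != p)
    stopf("cpt_ratio and age must have one value per participant")
  if (dim(ratio$values)[2] != n_nodes(graph))
    stopf("tensor has %d nodes but graph has %d",
          dim(ratio$values)[2], n_nodes(graph))
  adj <- adjacency_list(graph)
  eng <- pcorr_engine(ratio, age)
  nn <- eng$n_nodes; ns <- eng$n_steps
  df <- p - 3L
  rho_crit <- rho_critical(params$alpha_node, df)
  r_cpt <- rank(cpt_ratio)
  r_age <- rank(age)

  cluster_pass <- function(rho_vec) {
    rho <- matrix(rho_vec, nn, ns)
    sig <- !is.na(rho) & abs(rho) > rho_crit
    cluster_from_mask(rho, sig, adj, params, nn, ns)
  }

  rho_obs <- eng$rho(r_cpt)
  clusters <- cluster_pass(rho_obs)

  null_max <- with_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(b) {
      idx <- sample.int(p)
      rho_vec <- if (shuffle_age) permuted_joint_rho(ratio, r_cpt, r_age, idx)
                 else eng$rho(r_cpt[idx])
      surr <- cluster_pass(rho_vec)
      if (length(surr)) max(abs(vapply(surr, `[[`, numeric(1), "mass"))) else 0
    }, numeric(1))
  })

  p_values <- vapply(clusters, function(cl)
    (sum(null_max >= abs(cl$mass)) + 1) / (params$n_permutations + 1),
    numeric(1))

  structure(list(clusters = clusters, p_values = p_values,
                 null_max_mass = null_max, map = structure(list(
                   rho = matrix(rho_obs, nn, ns),
                   pval = matrix(rho_pvalue(rho_obs, df), nn, ns),
                   covariate_name = "age", freq_axis = ratio$freq_axis,
                   n = p, valid = !all(is.na(rho_obs))),
                   class = "correlation_map"),
                 n_permutations = params$n_permutations,
                 seed = params$seed, params = params,
                 freq_axis = ratio$freq_axis),
            class = "spectral_cluster_test")
}

# Joint (behaviour, age) shuffle: both the behavioural ranks and the covariate
# ranks move together, so the projector must be rebuilt per permutation.
permuted_joint_rho <- function(ratio, r_cpt, r_age, idx) {
  v <- ratio$values
  p <- dim(v)[1]
  m <- matrix(v, p, dim(v)[2] * dim(v)[3])
  rk <- col_ranks(m)
  proj <- rank_residual_projector(r_age[idx])
  pm <- proj %*% rk
  norms <- sqrt(colSums(pm^2))
  q <- drop(proj %*% r_cpt[idx])
  qn <- sqrt(sum(q^2))
  r <- drop(crossprod(pm, q)) / (norms * qn)
  r[norms < 1e-10 | qn < 1e-10] <- NA_real_
  pmax(-1, pmin(1, r))
}

#' @export
print.spectral_cluster_test <- function(x, ...) {
  cat("Spatio-spectral cluster permutation test\n")
  cat(sprintf("  %d permutations (seed %d), alpha_node = %g, min run = %d steps, min extent = %g\n",
              x$n_permutations, x$seed, x$params$alpha_node,
              x$params$min_consecutive_steps, x$params$min_extent_fraction))
  if (!length(x$clusters)) {
    cat("  no clusters survive the filters\n")
    return(invisible(x))
  }
  cat(sprintf("  %d cluster(s):\n", length(x$clusters)))
  s <- summary(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.spectral_cluster_test <- function(object, ...) {
  if (!length(object$clusters))
    return(data.frame(cluster = integer(0), sign = integer(0), cells = integer(0),
                      nodes = integer(0), f_lo_hz = numeric(0), f_hi_hz = numeric(0),
                      mass = numeric(0), p_value = numeric(0)))
  fx <- object$freq_axis
  data.frame(
    cluster = seq_along(object$clusters),
    sign = vapply(object$clusters, `[[`, numeric(1), "sign"),
    cells = vapply(object$clusters, function(cl) nrow(cl$members), integer(1)),
    nodes = vapply(object$clusters, function(cl)
      length(unique(cl$members[, "node"])), integer(1)),
    f_lo_hz = round(fx[vapply(object$clusters, function(cl) cl$freq_span[1], numeric(1))], 3),
    f_hi_hz = round(fx[vapply(object$clusters, function(cl) cl$freq_span[2], numeric(1))], 3),
    mass = round(vapply(object$clusters, `[[`, numeric(1), "mass"), 3),
    p_value = round(object$p_values, 5))
}

#' Plot the extent profile of a fitted cluster test
#'
#' Node extent per frequency step for each surviving cluster (the shape of
#' the cluster across frequency).
#'
#' @param x A `spectral_cluster_test`.
#' @param which Indices of clusters to draw (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spectral_cluster_test <- function(x, which = seq_along(x$clusters), ...) {
  if (!length(x$clusters)) {
    graphics::plot(0, 0, type = "n", xlab = "frequency (Hz)",
                   ylab = "nodes in cluster", main = "no clusters")
    return(invisible(x))
  }
  fx <- x$freq_axis
  ymax <- max(unlist(lapply(x$clusters[which], `[[`, "extent_per_step")))
  graphics::plot(range(fx), c(0, ymax), type = "n", xlab = "frequency (Hz)",
                 ylab = "nodes in cluster", ...)
  for (i in which) {
    cl <- x$clusters[[i]]
    steps <- cl$freq_span[1]:cl$freq_span[2]
    graphics::lines(fx[steps], cl$extent_per_step, type = "b", pch = 16,
                    col = i)
  }
  invisible(x)
}
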
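#' Post hoc summary of a cluster
#'
#' Averages the power ratio over all (node, step) members of a cluster per
#' participant — the cluster's representative MEG marker — and reports its
#' age-partialed Spearman correlation with the CPT commission ratio for the
#' whole sample and for each arm separately, plus the cluster's extent
#' profile and peak-extent step.
#'
#' @param cluster An `ss_cluster`.
#' @param ratio The ratio `power_tensor` the cluster was formed on.
#' @param cohort The matching `cohort_table` (provides arm, age and the CPT
#'   scores).
#' @return A `cluster_summary` list: `mean_ratio` (per participant),
#'   `correlations` (data.frame with rho, p, n per group), `extent_per_step`,
#'   `peak_step`, `peak_freq_hz`.
#' @export
cluster_summary <- function(cluster, ratio, cohort) {
  if (!nrow(cluster$members)) stopf("cluster is empty")
  if (!identical(ratio$participant_order, cohort$participant_id))
    stopf("tensor participant order does not match the cohort")
  v <- ratio$values
  idx <- cbind(rep(seq_len(dim(v)[1]), each = nrow(cluster$members)),
               rep(cluster$members[, "node"], dim(v)[1]),
               rep(cluster$members[, "step"], dim(v)[1]))
  mean_ratio <- rowMeans(matrix(v[idx], ncol = nrow(cluster$members),
                                byrow = TRUE))
  names(mean_ratio) <- cohort$participant_id
  cpt_ratio <- compute_cpt_ratio(cohort)
  groups <- list(whole = seq_len(nrow(cohort)),
                 experimental = which(cohort$arm == "experimental"),
                 control = which(cohort$arm == "control"))
  cors <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    res <- tryCatch(partial_spearman(mean_ratio[i], cpt_ratio[i], cohort$age[i]),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(group = g, rho = res$rho, p = res$p, n = length(i))
  })
  peak <- which.max(cluster$extent_per_step)
  structure(list(
    mean_ratio = mean_ratio,
    correlations = do.call(rbind, cors),
    extent_per_step = cluster$extent_per_step,
    peak_step = as.integer(names(cluster$extent_per_step)[peak]),
    peak_freq_hz = ratio$freq_axis[as.integer(names(cluster$extent_per_step)[peak])]),
    class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster marker: mean power ratio over %d participants; peak extent %d nodes at %.3g Hz\n",
              length(x$mean_ratio), max(x$extent_per_step), x$peak_freq_hz))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' ROI occupancy of a cluster
#'
#' For every labelled region containing at least one cluster node: `N`, the
#' number of sources carrying that label; `n`, how many of them belong to the
#' cluster at any frequency step; and `percent = 100 n / N`. Rows are sorted
#' by decreasing `n` (equivalently `percent * N`), then by region name.
#'
#' @param cluster An `ss_cluster`.
#' @param graph A `source_graph` with `roi_labels`.
#' @return data.frame with columns `roi`, `N`, `n`, `percent`.
#' @export
roi_occupancy <- function(cluster, graph) {
  if (is.null(graph$roi_labels)) stopf("graph carries no ROI labels")
  lab <- graph$roi_labels
  labelled <- lab != "unassigned"
  if (!any(labelled)) stopf("graph carries no ROI labels")
  cl_nodes <- unique(cluster$members[, "node"])
  rois <- sort(unique(lab[labelled]))
  big_n <- vapply(rois, function(r) sum(lab == r), integer(1))
  small_n <- vapply(rois, function(r) sum(lab[cl_nodes] == r), integer(1))
  out <- data.frame(roi = rois, N = big_n, n = small_n,
                    percent = round(100 * small_n / big_n, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n > 0L, , drop = FALSE]
  out <- out[order(-out$n, out$roi), , drop = FALSE]
  rownames(out) <- NULL
  out
}
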
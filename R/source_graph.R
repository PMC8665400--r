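#' Source-space graphs
#'
#' A source graph is the spatial scaffold of the analysis: 3D node coordinates
#' (mm), an undirected spatial adjacency edge list, and optional node-to-ROI
#' labels. Nodes are indexed 1-based everywhere in the package.
#'
#' @param coords Numeric matrix, nodes x 3 (mm).
#' @param edges Integer matrix, edges x 2, each row an undirected node pair.
#' @param roi_labels Optional character vector of length `nrow(coords)`;
#'   unlabeled nodes hold `"unassigned"`.
#' @return A `source_graph` object.
#' @export
source_graph <- function(coords, edges, roi_labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || !is.numeric(coords) || any(!is.finite(coords)))
    stopf("coords must be a finite numeric nodes x 3 matrix")
  n <- nrow(coords)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) stopf("edge references node outside 1..%d", n)
    if (any(edges[, 1] == edges[, 2])) stopf("self-edges are not allowed")
    # canonical order: smaller index first, unique rows
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (!is.null(roi_labels)) {
    if (length(roi_labels) != n) stopf("roi_labels must have one entry per node")
    roi_labels <- as.character(roi_labels)
    if (any(!nzchar(roi_labels))) stopf("ROI names must be nonempty")
  }
  structure(list(coords = coords, edges = edges, roi_labels = roi_labels),
            class = "source_graph")
}

#' @export
print.source_graph <- function(x, ...) {
  cat(sprintf("source_graph: %d nodes, %d edges%s\n", nrow(x$coords),
              nrow(x$edges),
              if (is.null(x$roi_labels)) "" else
                sprintf(", %d labeled nodes",
                        sum(x$roi_labels != "unassigned"))))
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$coords)

# Neighbor list (list of integer vectors), symmetric by construction.
adjacency_list <- function(graph) {
  n <- n_nodes(graph)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  e <- graph$edges
  if (nrow(e)) {
    both <- rbind(e, e[, 2:1, drop = FALSE])
    adj <- split(both[, 2], factor(both[, 1], levels = seq_len(n)))
    adj <- lapply(adj, function(v) sort(as.integer(v)))
  }
  adj
}

#' Build spatial adjacency from node coordinates
#'
#' Connects nodes by a Euclidean distance threshold (default) or by symmetric
#' k-nearest neighbours. The default threshold, 1.05 x the grid spacing,
#' yields 6-connectivity on a regular grid.
#'
#' @param coords Nodes x 3 coordinate matrix (mm), or a `source_graph` whose
#'   coordinates are reused.
#' @param d_max Distance threshold in mm (edge iff distance <= `d_max`).
#' @param k Number of nearest neighbours (alternative rule; the union of
#'   directed k-nearest relations, symmetrized).
#' @return A `source_graph` (ROI labels, if any, are preserved).
#' @export
build_spatial_adjacency <- function(coords, d_max = NULL, k = NULL) {
  labels <- NULL
  if (inherits(coords, "source_graph")) {
    labels <- coords$roi_labels
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stopf("need at least 2 nodes")
  if (is.null(d_max) == is.null(k)) stopf("give exactly one of d_max or k")
  d <- as.matrix(stats::dist(coords))
  if (!is.null(d_max)) {
    if (d_max <= 0) stopf("d_max must be positive")
    hit <- which(d <= d_max & upper.tri(d), arr.ind = TRUE)
    edges <- unname(hit)
  } else {
    if (!is_count(k) || k < 1L || k >= n) stopf("k must be an integer in [1, n_nodes)")
    diag(d) <- Inf
    nb <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
    edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nb)))
  }
  source_graph(coords, edges, roi_labels = labels)
}

#' Attach ROI labels to a source graph
#'
#' @param graph A `source_graph`.
#' @param roi_map data.frame with columns `node_index` (1-based) and `roi_name`.
#' @return The graph with `roi_labels` filled; uncovered nodes are
#'   `"unassigned"`.
#' @export
assign_nodes_to_rois <- function(graph, roi_map) {
  n <- n_nodes(graph)
  labels <- rep("unassigned", n)
  if (nrow(roi_map)) {
    idx <- as.integer(roi_map$node_index)
    if (any(is.na(idx) | idx < 1L | idx > n))
      stopf("roi_map references unknown node index (nodes are 1..%d)", n)
    if (anyDuplicated(idx)) stopf("roi_map assigns a node more than once")
    nm <- as.character(roi_map$roi_name)
    if (any(is.na(nm) | !nzchar(nm))) stopf("ROI names must be nonempty")
    labels[idx] <- nm
  }
  source_graph(graph$coords, graph$edges, roi_labels = labels)
}

#' Read an ROI map
#'
#' Two-column tab-separated file `node_index` / `roi_name` (1-based indices).
#'
#' @param path File path.
#' @return data.frame with columns `node_index`, `roi_name`.
#' @export
load_roi_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Generate a regular source grid clipped to an ellipsoidal mask
#'
#' Places `n_nodes` points of a regular 3D grid inside a head-shaped
#' ellipsoid: grid points are ranked by their ellipsoidal radius (semi-axis
#' aspect `aspect`, default slightly elongated along y, the
#' anterior-posterior axis) and the `n_nodes` innermost are kept, with ties
#' broken lexicographically so the construction is fully deterministic.
#' Edges follow the default distance rule (1.05 x spacing, 6-connectivity).
#'
#' @param n_nodes Number of sources (>= 27; default 1200, so that 1% of the
#'   nodes is 12).
#' @param spacing Grid spacing in mm (default 10).
#' @param seed Integer seed; used only when `jitter > 0`.
#' @param aspect Length-3 positive semi-axis aspect of the mask.
#' @param jitter Optional uniform coordinate jitter in mm (default 0).
#' @return A `source_graph`.
#' @export
generate_source_space <- function(n_nodes = 1200, spacing = 10, seed = 1,
                                  aspect = c(1, 1.2, 1), jitter = 0) {
  if (!is_count(n_nodes) || n_nodes < 27)
    stopf("n_nodes must be an integer >= 27 (achievable minimum is 27)")
  if (spacing <= 0) stopf("spacing must be positive")
  if (length(aspect) != 3L || any(aspect <= 0)) stopf("aspect must be 3 positive values")
  # generous candidate half-extents from the ellipsoid volume
  r <- (1.5 * n_nodes * 3 / (4 * pi * prod(aspect)))^(1 / 3) + 2
  h <- ceiling(r * aspect)
  g <- expand.grid(x = -h[1]:h[1], y = -h[2]:h[2], z = -h[3]:h[3])
  rad <- sqrt((g$x / aspect[1])^2 + (g$y / aspect[2])^2 + (g$z / aspect[3])^2)
  ord <- order(rad, g$x, g$y, g$z)
  if (n_nodes > length(ord))
    stopf("n_nodes = %d unattainable for this mask; achievable maximum is %d",
          n_nodes, length(ord))
  keep <- ord[seq_len(n_nodes)]
  coords <- as.matrix(g[keep, , drop = FALSE]) * spacing
  dimnames(coords) <- NULL
  if (jitter > 0)
    coords <- coords + with_seed(seed,
      matrix(stats::runif(3L * n_nodes, -jitter, jitter), ncol = 3L))
  build_spatial_adjacency(coords, d_max = 1.05 * spacing)
}
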
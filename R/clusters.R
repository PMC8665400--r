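# Sign-consistent spatio-spectral clustering on the node x frequency lattice.
#
# Pipeline per sign: (1) threshold the correlation map cell-wise; (2) per-node
# persistence filter keeping only cells inside runs of >= min_consecutive_steps
# significant steps; (3) connected components where (n1,s) ~ (n2,s) iff
# (n1,n2) is a spatial edge and (n,s) ~ (n,s+1); (4) discard components whose
# node extent at any step of their frequency span falls below
# ceiling(min_extent_fraction * n_nodes); (5) cluster mass = sum of member rho.

#' Clustering and permutation parameters
#'
#' @param alpha_node Cell-wise significance level (two-sided, default 0.05).
#' @param min_consecutive_steps Persistence filter: a node contributes only
#'   cells lying inside runs of at least this many consecutive significant
#'   steps (default 4; on the default 1/3-Hz axis that is a 1-Hz interval).
#' @param min_extent_fraction Minimum node extent per frequency step within a
#'   cluster's span, as a fraction of all nodes (default 0.01; 12 nodes on the
#'   default 1200-node grid).
#' @param n_permutations Number of permutations (default 5000, minimum 100).
#' @param seed Integer seed for the permutation draw.
#' @param extent_rule How to enforce the extent minimum: `"trim"` (default)
#'   removes cells at sub-threshold steps and re-extracts connected
#'   components until every surviving cluster meets the minimum at every step
#'   of its span; `"discard"` drops any component with a thin step outright.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(alpha_node = 0.05, min_consecutive_steps = 4,
                           min_extent_fraction = 0.01, n_permutations = 5000,
                           seed = 1, extent_rule = c("trim", "discard")) {
  extent_rule <- match.arg(extent_rule)
  if (alpha_node <= 0 || alpha_node >= 1) stopf("alpha_node must be in (0, 1)")
  if (!is_count(min_consecutive_steps) || min_consecutive_steps < 1)
    stopf("min_consecutive_steps must be a positive integer")
  if (min_extent_fraction < 0 || min_extent_fraction >= 1)
    stopf("min_extent_fraction must be in [0, 1)")
  if (!is_count(n_permutations) || n_permutations < 100)
    stopf("n_permutations must be an integer >= 100")
  structure(list(alpha_node = alpha_node,
                 min_consecutive_steps = as.integer(min_consecutive_steps),
                 min_extent_fraction = min_extent_fraction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), extent_rule = extent_rule),
            class = "cluster_params")
}

# Persistence filter: keep cells of sig (nodes x steps logical) lying in
# within-node runs of length >= min_steps.
persistence_filter <- function(sig, min_steps) {
  if (min_steps <= 1L) return(sig)
  n <- nrow(sig); s <- ncol(sig)
  if (s < min_steps) return(sig & FALSE)
  fwd <- matrix(0L, n, s); bwd <- matrix(0L, n, s)
  run <- integer(n)
  for (j in seq_len(s)) { run <- (run + 1L) * sig[, j]; fwd[, j] <- run }
  run <- integer(n)
  for (j in rev(seq_len(s))) { run <- (run + 1L) * sig[, j]; bwd[, j] <- run }
  sig & (fwd + bwd - 1L) >= min_steps
}

# Connected components over kept cells of one sign, followed by the
# extent rule. "trim" (default) removes cells at sub-threshold steps and
# re-extracts components until stable, so a chance one-node tail cannot sink
# an otherwise solid cluster; "discard" drops any component with a thin step
# outright.
sign_components <- function(rho, keep, adj, sign, min_extent, n_nodes, n_steps,
                            extent_rule = "trim") {
  cells <- which(keep)
  k <- length(cells)
  if (!k) return(list())
  idmap <- integer(n_nodes * n_steps)
  idmap[cells] <- seq_len(k)
  node <- (cells - 1L) %% n_nodes + 1L
  step <- (cells - 1L) %/% n_nodes + 1L

  # union-find over an index subset of the kept cells
  components_of <- function(subset) {
    insub <- logical(k)
    insub[subset] <- TRUE
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (a in subset) {
      if (step[a] < n_steps) {
        b <- idmap[cells[a] + n_nodes]
        if (b > 0L && insub[b]) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
      nb <- adj[[node[a]]]
      if (length(nb)) {
        j <- idmap[(step[a] - 1L) * n_nodes + nb]
        j <- j[j > a]
        for (b in j) if (insub[b]) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    split(subset, vapply(subset, find, integer(1)))
  }

  queue <- components_of(seq_len(k))
  out <- list()
  while (length(queue)) {
    comp <- queue[[1]]
    queue <- queue[-1]
    st <- step[comp]
    span <- range(st)
    extent <- tabulate(st - span[1] + 1L, nbins = span[2] - span[1] + 1L)
    thin <- extent < min_extent
    if (min_extent > 0L && any(thin)) {
      if (extent_rule == "discard" || all(thin)) next
      kept <- comp[!thin[st - span[1] + 1L]]
      queue <- c(queue, components_of(kept))
      next
    }
    members <- cbind(node = node[comp], step = st)
    members <- members[order(members[, "step"], members[, "node"]), , drop = FALSE]
    out[[length(out) + 1L]] <- structure(list(
      members = members, sign = sign,
      mass = sum(rho[cells[comp]]),
      freq_span = span,
      extent_per_step = stats::setNames(extent, span[1]:span[2])),
      class = "ss_cluster")
  }
  out
}

# Shared driver over both signs, from a rho matrix and significance mask.
cluster_from_mask <- function(rho, sig, adj, params, n_nodes, n_steps) {
  min_extent <- ceiling(params$min_extent_fraction * n_nodes)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- sig & !is.na(rho) & (if (sgn > 0) rho > 0 else rho < 0)
    mask <- persistence_filter(mask, params$min_consecutive_steps)
    out <- c(out, sign_components(rho, mask, adj, sgn, min_extent,
                                  n_nodes, n_steps,
                                  extent_rule = params$extent_rule))
  }
  if (length(out) > 1L) {
    ord <- order(-vapply(out, function(cl) abs(cl$mass), numeric(1)),
                 vapply(out, function(cl) cl$members[1, "step"] * 1e6 +
                          cl$members[1, "node"], numeric(1)))
    out <- out[ord]
  }
  out
}

#' Form sign-consistent spatio-spectral clusters
#'
#' @param map A `correlation_map` from [correlation_maps()].
#' @param graph A `source_graph` matching the map's node dimension.
#' @param params A [cluster_params()].
#' @return List of `ss_cluster` objects (possibly empty), ordered by
#'   decreasing absolute mass.
#' @export
form_clusters <- function(map, graph, params = cluster_params()) {
  if (nrow(map$rho) != n_nodes(graph))
    stopf("map has %d nodes but graph has %d", nrow(map$rho), n_nodes(graph))
  adj <- adjacency_list(graph)
  sig <- !is.na(map$pval) & map$pval < params$alpha_node
  cluster_from_mask(map$rho, sig, adj, params, nrow(map$rho), ncol(map$rho))
}

#' @export
print.ss_cluster <- function(x, ...) {
  cat(sprintf("spatio-spectral cluster: %d cells, sign %+d, mass %.3f, steps %d-%d\n",
              nrow(x$members), x$sign, x$mass, x$freq_span[1], x$freq_span[2]))
  invisible(x)
}
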
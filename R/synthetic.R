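#' Cohort simulation specification
#'
#' Defaults reproduce the two-arm trial conditions the analysis assumes:
#' 15 experimental and 14 control participants aged 8-11, baseline CPT-III
#' commission T scores drawn per arm from Normal(53.87, 8.37) and
#' Normal(48.79, 7.53), and mean post-pre shifts of -6.07 (experimental,
#' improvement) and +0.85 (control).
#'
#' @param n_experimental,n_control Participants per arm (>= 2).
#' @param age_range Age range in years (uniform).
#' @param cpt_pre_mean,cpt_pre_sd Named per-arm baseline mean/SD
#'   (`experimental`, `control`).
#' @param arm_effect Named per-arm mean post-pre shift.
#' @param residual_sd SD of the participant-level post-pre residual (T-score
#'   units); default 5, a plausible short-interval test-retest noise level.
#' @param p_male Probability of male sex (default 25/29 as in the emulated
#'   cohort).
#' @param p_medicated,p_psych Named per-arm probabilities of the medication
#'   and psychological-treatment flags.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_experimental = 15, n_control = 14,
                        age_range = c(8, 11),
                        cpt_pre_mean = c(experimental = 53.87, control = 48.79),
                        cpt_pre_sd = c(experimental = 8.37, control = 7.53),
                        arm_effect = c(experimental = -6.07, control = 0.85),
                        residual_sd = 5,
                        p_male = 25 / 29,
                        p_medicated = c(experimental = 9 / 15, control = 11 / 14),
                        p_psych = c(experimental = 4 / 15, control = 3 / 14),
                        seed = 1) {
  if (!is_count(n_experimental) || n_experimental < 2 ||
      !is_count(n_control) || n_control < 2)
    stopf("each arm needs at least 2 participants")
  if (any(cpt_pre_sd <= 0)) stopf("cpt_pre_sd values must be positive")
  if (residual_sd < 0) stopf("residual_sd must be non-negative")
  structure(list(n_experimental = n_experimental, n_control = n_control,
                 age_range = age_range, cpt_pre_mean = cpt_pre_mean,
                 cpt_pre_sd = cpt_pre_sd, arm_effect = arm_effect,
                 residual_sd = residual_sd, p_male = p_male,
                 p_medicated = p_medicated, p_psych = p_psych, seed = seed),
            class = "cohort_spec")
}

#' Planted-effect specification
#'
#' Describes the spatio-spectral effect injected into the synthetic power
#' data: a spatially compact node set (all nodes within `cluster_radius` of a
#' seed node) over a frequency band, whose post/pre log power ratio is coupled
#' to the z-scored CPT commission ratio so that the age-partialed Spearman
#' correlation of the cluster-average power ratio with the CPT ratio
#' approximates `target_rho`.
#'
#' The noise model has two layers: a participant-level "physiological" change
#' shared across the cluster (`shared_noise_sd`, on the log-ratio scale) and
#' independent per-cell measurement noise (`noise_sd_log_ratio`). Both are
#' present only so far as they are positive; with all noise at zero the
#' coupling is perfectly monotone and the realized correlation is +/-1.
#'
#' @param cluster_seed_node Node index anchoring the cluster; `NULL` picks the
#'   most posterior node (smallest y coordinate) of the graph at generation
#'   time.
#' @param cluster_radius Radius in mm of the planted node set (default 25,
#'   about 65 nodes on the default 10-mm grid).
#' @param band Frequency band in Hz (default `c(35, 40)/3`, i.e. the
#'   11.67-13.33 Hz alpha sub-band; endpoints snap to the nearest axis steps).
#' @param target_rho Target age-partialed Spearman correlation in (-1, 0]
#'   or [0, 1); default -0.56.
#' @param noise_sd_log_ratio Per-cell log-ratio noise SD (default 0.10).
#' @param shared_noise_sd Participant-level shared log-ratio noise SD inside
#'   the cluster (default 0.25).
#' @param ratio_offset Mean log-ratio offset `a` inside the cluster (default
#'   0.15, a mild average alpha-power increase).
#' @param noise_spatial_smoothing Spatially smooth the per-cell log-ratio
#'   noise by one neighbour-averaging pass over the source graph (default
#'   `TRUE`). Source-reconstructed power is spatially correlated (leakage),
#'   and cluster-based inference presumes that coherence; without it the
#'   generator would produce unrealistically fragmented significance maps.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(cluster_seed_node = NULL, cluster_radius = 25,
                        band = c(35, 40) / 3, target_rho = -0.56,
                        noise_sd_log_ratio = 0.10, shared_noise_sd = 0.25,
                        ratio_offset = 0.15, noise_spatial_smoothing = TRUE) {
  if (abs(target_rho) >= 1) stopf("|target_rho| must be < 1")
  if (cluster_radius <= 0) stopf("cluster_radius must be positive")
  if (length(band) != 2L || band[1] > band[2]) stopf("band must be c(f_lo, f_hi)")
  if (noise_sd_log_ratio < 0 || shared_noise_sd < 0) stopf("noise SDs must be >= 0")
  structure(list(cluster_seed_node = cluster_seed_node,
                 cluster_radius = cluster_radius, band = band,
                 target_rho = target_rho,
                 noise_sd_log_ratio = noise_sd_log_ratio,
                 shared_noise_sd = shared_noise_sd,
                 ratio_offset = ratio_offset,
                 noise_spatial_smoothing = isTRUE(noise_spatial_smoothing)),
            class = "effect_spec")
}

#' Simulate a clinical cohort
#'
#' Ages are uniform over the spec's range; baseline commission scores are
#' Normal per arm; post scores are `pre + arm_effect + Normal(0, residual_sd)`.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table`.
#' @export
generate_clinical_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_experimental + spec$n_control
    arm <- rep(c("experimental", "control"),
               c(spec$n_experimental, spec$n_control))
    pre <- stats::rnorm(n, spec$cpt_pre_mean[arm], spec$cpt_pre_sd[arm])
    post <- pre + spec$arm_effect[arm] + stats::rnorm(n, 0, spec$residual_sd)
    cohort_table(data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      arm = arm,
      age = round(stats::runif(n, spec$age_range[1], spec$age_range[2]), 2),
      sex = ifelse(stats::runif(n) < spec$p_male, "M", "F"),
      medicated = stats::runif(n) < spec$p_medicated[arm],
      psych_treatment = stats::runif(n) < spec$p_psych[arm],
      cpt_commission_pre = pre,
      cpt_commission_post = post,
      stringsAsFactors = FALSE
    ), age_range = spec$age_range)
  })
}

# Steps of freq_axis covered by a band; endpoints snap to the nearest axis
# value (within half a step), so printed endpoints like 11.67 Hz select the
# exact 35/3 step.
band_steps <- function(freq_axis, band) {
  df <- if (length(freq_axis) > 1L) freq_axis[2] - freq_axis[1] else 1
  lo <- which.min(abs(freq_axis - band[1]))
  hi <- which.min(abs(freq_axis - band[2]))
  if (abs(freq_axis[lo] - band[1]) > df / 2 + 1e-9 ||
      abs(freq_axis[hi] - band[2]) > df / 2 + 1e-9)
    stopf("band [%g, %g] Hz is outside the frequency axis", band[1], band[2])
  lo:hi
}

#' Simulate pre/post source-space power tensors with a planted effect
#'
#' Baseline spectra are 1/f trends with a Gaussian alpha bump (center 10.5 Hz,
#' width 1.5 Hz) whose amplitude grows toward posterior nodes, times
#' multiplicative log-normal noise. The post/pre log ratio is independent
#' noise everywhere except inside the planted cluster, where (for
#' `target_rho != 0`) it is `a + s*b*zscore(cpt_ratio) + shared + noise`, with
#' `s = sign(target_rho)` and `b` calibrated from the noise budget so that the
#' age-partialed Spearman correlation between the cluster-average power ratio
#' and the CPT ratio approximates `target_rho`.
#'
#' @param cohort A `cohort_table`.
#' @param graph A `source_graph`.
#' @param effect An [effect_spec()].
#' @param freq_axis Frequency axis (Hz), default [default_freq_axis()].
#' @param seed Integer seed.
#' @param baseline_noise_sd Log-scale SD of the baseline spectra (default 0.2).
#' @param normalize If `TRUE`, both tensors are normalized per node to unit
#'   total power across frequencies (relative power) before being returned.
#' @return List with elements `pre`, `post` (power tensors) and `truth` (the
#'   planted member set and calibration details).
#' @export
generate_power_data <- function(cohort, graph, effect = effect_spec(),
                                freq_axis = default_freq_axis(), seed = 1,
                                baseline_noise_sd = 0.2, normalize = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(graph, "source_graph"),
            inherits(effect, "effect_spec"))
  p <- nrow(cohort)
  n <- n_nodes(graph)
  s <- length(freq_axis)
  steps <- band_steps(freq_axis, effect$band)
  seed_node <- effect$cluster_seed_node
  if (is.null(seed_node)) seed_node <- which.min(graph$coords[, 2])[1]
  if (seed_node < 1L || seed_node > n) stopf("cluster_seed_node outside 1..%d", n)
  d2 <- colSums((t(graph$coords) - graph$coords[seed_node, ])^2)
  cl_nodes <- which(d2 <= effect$cluster_radius^2)

  cpt_ratio <- compute_cpt_ratio(cohort)
  z <- as.numeric(scale(cpt_ratio))

  with_seed(seed, {
    # baseline: 1/f trend, posterior-weighted alpha bump, log-normal noise
    y <- graph$coords[, 2]
    post_w <- if (diff(range(y)) > 0) (max(y) - y) / diff(range(y)) else rep(1, n)
    amp <- 0.5 + 1.5 * post_w
    bump <- exp(-(freq_axis - 10.5)^2 / (2 * 1.5^2))
    base_ns <- outer(amp, bump) # nodes x steps
    pre <- array(0, c(p, n, s))
    for (i in seq_len(p)) {
      noise <- matrix(stats::rnorm(n * s, 0, baseline_noise_sd), n, s)
      pre[i, , ] <- rep(freq_axis^-1, each = n) * (1 + base_ns) * exp(noise)
    }
    logratio <- array(stats::rnorm(p * n * s, 0, effect$noise_sd_log_ratio),
                      c(p, n, s))
    if (effect$noise_spatial_smoothing && effect$noise_sd_log_ratio > 0)
      logratio <- smooth_over_graph(logratio, graph)
    m <- length(cl_nodes) * length(steps)
    b <- 0
    if (effect$target_rho != 0) {
      r_p <- 2 * sin(pi * abs(effect$target_rho) / 6) # Spearman -> Pearson
      sig2 <- effect$shared_noise_sd^2 + effect$noise_sd_log_ratio^2 / m
      if (sig2 == 0) {
        warnf("target_rho = %g unreachable with zero noise; achieved correlation is %g",
              effect$target_rho, sign(effect$target_rho))
      } else {
        b <- sqrt(sig2) * r_p / sqrt(1 - r_p^2)
      }
      shared <- stats::rnorm(p, 0, effect$shared_noise_sd)
      delta <- effect$ratio_offset + sign(effect$target_rho) * b * z + shared
      logratio[, cl_nodes, steps] <- logratio[, cl_nodes, steps] +
        rep(delta, length(cl_nodes) * length(steps))
    }
    post <- pre * exp(logratio)
    if (normalize) {
      pre <- normalize_relative_power(pre)
      post <- normalize_relative_power(post)
    }
    truth <- list(
      members = cbind(node = rep(cl_nodes, times = length(steps)),
                      step = rep(steps, each = length(cl_nodes))),
      nodes = cl_nodes, steps = steps, seed_node = seed_node,
      band = effect$band, target_rho = effect$target_rho, b = b)
    list(pre = power_tensor(pre, freq_axis, "pre", cohort$participant_id),
         post = power_tensor(post, freq_axis, "post", cohort$participant_id),
         truth = truth)
  })
}

# One neighbour-averaging pass of a (participants x nodes x steps) field over
# the spatial graph: each node is replaced by the mean of itself and its
# neighbours. Emulates the spatial coherence of source-space estimates.
smooth_over_graph <- function(values, graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  i <- c(seq_len(n), e[, 1], e[, 2])
  j <- c(seq_len(n), e[, 2], e[, 1])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  a <- a / Matrix::rowSums(a)
  d <- dim(values)
  flat <- matrix(aperm(values, c(2, 1, 3)), n, d[1] * d[3])
  sm <- as.matrix(a %*% flat)
  aperm(array(sm, c(n, d[1], d[3])), c(2, 1, 3))
}

normalize_relative_power <- function(values) {
  tot <- apply(values, c(1, 2), sum)
  sweep(values, c(1, 2), tot, "/")
}

#' Write a complete dataset directory
#'
#' Plain-text layout: `cohort.tsv`, `meta.json` (frequency axis, coordinates,
#' edges, participant order), per-participant nodes x steps matrices under
#' `pre/` and `post/` (17 significant digits, so the round trip is exact),
#' optional `roi_map.tsv` and `truth.json`.
#'
#' @param dir Target directory.
#' @param cohort A `cohort_table`.
#' @param pre,post Matching `power_tensor`s.
#' @param graph A `source_graph`.
#' @param truth Optional planted-effect truth record.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, cohort, pre, post, graph, truth = NULL,
                          overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) && !overwrite)
    stopf("directory '%s' exists and is not empty (use overwrite = TRUE)", dir)
  if (!identical(pre$participant_order, cohort$participant_id))
    stopf("tensor participant order does not match the cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(cohort, file.path(dir, "cohort.tsv"))
  meta <- list(freq_axis = pre$freq_axis,
               n_nodes = n_nodes(graph),
               participant_order = cohort$participant_id,
               coords = unname(graph$coords),
               edges = unname(graph$edges))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (session in c("pre", "post")) {
    tensor <- if (session == "pre") pre else post
    sub <- file.path(dir, session)
    dir.create(sub, showWarnings = FALSE)
    for (i in seq_along(tensor$participant_order)) {
      m <- tensor$values[i, , ]
      txt <- apply(matrix(sprintf("%.17g", m), nrow = nrow(m)), 1L,
                   paste, collapse = " ")
      writeLines(txt, file.path(sub, paste0(tensor$participant_order[i], ".txt")))
    }
  }
  if (!is.null(graph$roi_labels)) {
    lab <- which(graph$roi_labels != "unassigned")
    utils::write.table(
      data.frame(node_index = lab, roi_name = graph$roi_labels[lab]),
      file.path(dir, "roi_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a source graph back from a dataset directory
#'
#' @param dir Dataset directory written by [write_dataset()].
#' @return A `source_graph` (with ROI labels if `roi_map.tsv` is present).
#' @export
load_source_graph <- function(dir) {
  meta <- read_dataset_meta(dir)
  g <- source_graph(meta$coords, meta$edges)
  roi_path <- file.path(dir, "roi_map.tsv")
  if (file.exists(roi_path)) g <- assign_nodes_to_rois(g, load_roi_map(roi_path))
  g
}

#' Simulate and optionally persist a full dataset
#'
#' One call producing the cohort, the source grid, the pre/post tensors with
#' the planted effect, and the planted-truth record. All stage seeds derive
#' from `seed`.
#'
#' @param cohort A [cohort_spec()].
#' @param effect An [effect_spec()].
#' @param n_nodes,spacing Source-grid parameters (see
#'   [generate_source_space()]).
#' @param freq_axis Frequency axis in Hz.
#' @param seed Integer master seed.
#' @param dir Optional directory; when given the dataset is written there.
#' @param overwrite Passed to [write_dataset()].
#' @param n_roi When positive, a synthetic ROI partition with this many
#'   regions is attached to the graph.
#' @return List with `cohort`, `graph`, `pre`, `post`, `truth`.
#' @export
simulate_dataset <- function(cohort = cohort_spec(), effect = effect_spec(),
                             n_nodes = 1200, spacing = 10,
                             freq_axis = default_freq_axis(), seed = 1,
                             dir = NULL, overwrite = FALSE, n_roi = 0) {
  cohort$seed <- seed
  tab <- generate_clinical_cohort(cohort)
  graph <- generate_source_space(n_nodes, spacing, seed = seed)
  if (n_roi > 0) graph <- synthetic_roi_partition(graph, n_roi)
  dat <- generate_power_data(tab, graph, effect, freq_axis, seed = seed + 1L)
  out <- list(cohort = tab, graph = graph, pre = dat$pre, post = dat$post,
              truth = dat$truth)
  if (!is.null(dir))
    write_dataset(dir, tab, dat$pre, dat$post, graph, dat$truth, overwrite)
  out
}

#' Synthetic atlas partition of a source grid
#'
#' Deterministically partitions all nodes into `n_roi` contiguous regions by
#' k-means-style assignment to evenly spread anchor nodes (anchors chosen by
#' farthest-point traversal from the most posterior node). Every node gets
#' exactly one label. This stands in for an anatomical atlas in synthetic
#' datasets and is labelled as such.
#'
#' @param graph A `source_graph`.
#' @param n_roi Number of regions (default 12).
#' @return The graph with `roi_labels` like `"Synthetic region 03"`.
#' @export
synthetic_roi_partition <- function(graph, n_roi = 12) {
  n <- n_nodes(graph)
  if (!is_count(n_roi) || n_roi < 1 || n_roi > n)
    stopf("n_roi must be an integer in [1, n_nodes]")
  anchors <- integer(n_roi)
  anchors[1] <- which.min(graph$coords[, 2])[1]
  if (n_roi > 1) {
    dmin <- sqrt(colSums((t(graph$coords) - graph$coords[anchors[1], ])^2))
    for (k in 2:n_roi) {
      anchors[k] <- which.max(dmin)[1]
      dk <- sqrt(colSums((t(graph$coords) - graph$coords[anchors[k], ])^2))
      dmin <- pmin(dmin, dk)
    }
  }
  d <- matrix(0, n, n_roi)
  for (k in seq_len(n_roi))
    d[, k] <- colSums((t(graph$coords) - graph$coords[anchors[k], ])^2)
  lab <- sprintf("Synthetic region %02d", max.col(-d, ties.method = "first"))
  source_graph(graph$coords, graph$edges, roi_labels = lab)
}
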
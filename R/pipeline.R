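#' Run the full analysis pipeline
#'
#' Orchestrates data access (an on-disk dataset directory or an in-run
#' simulation), the trial-level analytics, the spatio-spectral cluster
#' permutation test and the post hoc cluster summaries, writing a consolidated
#' plain-text report. Deterministic given the config seed: all stage seeds
#' derive from it and no timestamps are written.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Fields: exactly one of `dataset_dir` or `simulation` (a list
#'   with optional `cohort`, `effect`, `n_nodes`, `spacing`, `n_roi` entries
#'   mirroring [cohort_spec()] / [effect_spec()] / [simulate_dataset()]
#'   arguments); optional `cluster` (arguments for [cluster_params()]);
#'   optional `power_n_sims` (default 0 = skip the power simulation);
#'   `out_dir`; `seed` (default 1); `quiet` (default `FALSE`).
#' @return Invisibly, a list with the in-memory results (`data`, `baseline`,
#'   `model`, `effects`, `respondents`, `test`, `summaries`, `occupancy`) and
#'   the report directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  has_dir <- !is.null(config$dataset_dir)
  has_sim <- !is.null(config$simulation)
  if (has_dir == has_sim)
    stopf("config needs exactly one of 'dataset_dir' or 'simulation'")
  if (is.null(config$out_dir)) stopf("config needs 'out_dir'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  quiet <- isTRUE(config$quiet)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    say("[%s] ...", name)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  data <- stage("data", {
    if (has_dir) {
      dir <- config$dataset_dir
      list(cohort = load_cohort_table(file.path(dir, "cohort.tsv")),
           graph = load_source_graph(dir),
           pre = load_power_tensor(dir, "pre"),
           post = load_power_tensor(dir, "post"))
    } else {
      sim <- config$simulation
      do.call(simulate_dataset, c(
        list(cohort = do.call(cohort_spec, c(sim$cohort, list(seed = seed))),
             effect = do.call(effect_spec, if (is.null(sim$effect)) list() else sim$effect),
             seed = seed),
        sim[intersect(names(sim), c("n_nodes", "spacing", "n_roi"))]))
    }
  })

  clinical <- stage("trial-stats", {
    cohort <- data$cohort
    exp_i <- cohort$arm == "experimental"
    long <- data.frame(
      participant = rep(cohort$participant_id, 2),
      arm = rep(cohort$arm, 2),
      period = rep(c("pre", "post"), each = nrow(cohort)),
      age = rep(cohort$age, 2),
      score = c(cohort$cpt_commission_pre, cohort$cpt_commission_post))
    sd_ref <- stats::sd(cohort$cpt_commission_pre)
    resp <- lapply(c(experimental = TRUE, control = FALSE), function(e) {
      i <- exp_i == e
      respondent_analysis(cohort$cpt_commission_pre[i],
                          cohort$cpt_commission_post[i], sd_ref = sd_ref)
    })
    effects <- data.frame(
      arm = c("experimental", "control"),
      hedges_g = c(hedges_g_prepost(cohort$cpt_commission_pre[exp_i],
                                    cohort$cpt_commission_post[exp_i]),
                   hedges_g_prepost(cohort$cpt_commission_pre[!exp_i],
                                    cohort$cpt_commission_post[!exp_i])))
    power <- NULL
    if (!is.null(config$power_n_sims) && config$power_n_sims > 0)
      power <- simulate_power(0.64, c(sum(exp_i), sum(!exp_i)),
                              n_sims = config$power_n_sims, seed = seed + 2L)
    list(baseline = baseline_table(cohort),
         model = fit_prepost_mixed_model(long),
         effects = effects, respondents = resp, power = power)
  })

  test <- stage("cluster-test", {
    params <- do.call(cluster_params, c(
      if (is.null(config$cluster)) list() else config$cluster,
      list(seed = seed + 3L)))
    ratio <- compute_ratio_tensor(data$pre, data$post)
    spectral_cluster_test(ratio, compute_cpt_ratio(data$cohort),
                          data$cohort$age, data$graph, params)
  })

  posthoc <- stage("post-hoc", {
    sig <- which(test$p_values <= 0.05)
    summaries <- lapply(sig, function(i) {
      ratio <- compute_ratio_tensor(data$pre, data$post)
      cluster_summary(test$clusters[[i]], ratio, data$cohort)
    })
    occupancy <- NULL
    if (length(sig) && !is.null(data$graph$roi_labels))
      occupancy <- roi_occupancy(test$clusters[[sig[1]]], data$graph)
    list(summaries = summaries, occupancy = occupancy, significant = sig)
  })

  stage("report", {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(clinical$baseline, file.path(out, "baseline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    model <- clinical$model
    jsonlite::write_json(
      model[c("beta_interaction", "se", "t_value", "df", "p", "lr_chi2",
              "lr_p", "aic", "bic", "r2", "r2_adjusted", "age_included",
              "singular")],
      file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(clinical$effects, file.path(out, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    resp <- do.call(rbind, lapply(names(clinical$respondents), function(a)
      data.frame(arm = a, count = clinical$respondents[[a]]$count,
                 n = clinical$respondents[[a]]$n,
                 proportion = clinical$respondents[[a]]$proportion)))
    utils::write.table(resp, file.path(out, "respondents.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(clinical$power))
      jsonlite::write_json(unclass(clinical$power)[c("power", "n_sims", "alpha", "R", "ppv")],
                           file.path(out, "power_ppv.json"),
                           auto_unbox = TRUE, digits = NA)
    clusters_json <- lapply(seq_along(test$clusters), function(i) {
      cl <- test$clusters[[i]]
      list(cluster = i, sign = cl$sign, mass = cl$mass,
           p_value = test$p_values[i],
           freq_span_steps = cl$freq_span,
           freq_span_hz = test$freq_axis[cl$freq_span],
           extent_per_step = unname(cl$extent_per_step),
           members = apply(cl$members, 1L, as.list))
    })
    jsonlite::write_json(clusters_json, file.path(out, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(sprintf("%.17g", test$null_max_mass),
               file.path(out, "null_max.txt"))
    if (length(posthoc$summaries)) {
      tab <- do.call(rbind, lapply(seq_along(posthoc$summaries), function(k) {
        s <- posthoc$summaries[[k]]$correlations
        s$cluster <- posthoc$significant[k]
        s
      }))
      utils::write.table(tab, file.path(out, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(posthoc$occupancy))
      utils::write.table(posthoc$occupancy, file.path(out, "occupancy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(seed = seed,
                     source = if (has_dir) config$dataset_dir else "simulation",
                     simulation = config$simulation,
                     cluster_params = unclass(test$params),
                     power_n_sims = config$power_n_sims,
                     n_participants = nrow(data$cohort),
                     n_nodes = n_nodes(data$graph),
                     n_freq_steps = length(data$pre$freq_axis))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    out
  })

  say("[done] report in %s", config$out_dir)
  invisible(list(data = data, baseline = clinical$baseline,
                 model = clinical$model, effects = clinical$effects,
                 respondents = clinical$respondents, power = clinical$power,
                 test = test, summaries = posthoc$summaries,
                 occupancy = posthoc$occupancy, out_dir = config$out_dir))
}
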
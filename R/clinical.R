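#' Two-sample Student t test
#'
#' Pooled-variance two-sided t test between arms, accepting either raw score
#' vectors or summary triples named `mean`, `sd`, `n` (so printed table rows
#' can be replicated without raw data). Welch's correction is available for
#' raw input via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, or named numeric triples
#'   `c(mean = , sd = , n = )`.
#' @param var_equal Pool variances (default `TRUE`, Student's t).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  as_summary <- function(x) {
    if (!is.null(names(x)) && all(c("mean", "sd", "n") %in% names(x)))
      return(list(m = x[["mean"]], s = x[["sd"]], n = x[["n"]]))
    if (length(x) < 2L) stopf("each sample needs n >= 2")
    list(m = mean(x), s = stats::sd(x), n = length(x))
  }
  sa <- as_summary(a); sb <- as_summary(b)
  if (sa$n < 2 || sb$n < 2) stopf("each sample needs n >= 2")
  if (var_equal) {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$s^2 + (sb$n - 1) * sb$s^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    se <- sqrt(sa$s^2 / sa$n + sb$s^2 / sb$n)
    df <- se^4 / ((sa$s^2 / sa$n)^2 / (sa$n - 1) + (sb$s^2 / sb$n)^2 / (sb$n - 1))
  }
  if (se == 0) {
    if (sa$m == sb$m) return(list(t = 0, df = df, p = 1))
    stopf("zero pooled variance with unequal means; t undefined")
  }
  t <- (sa$m - sb$m) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, as used for baseline categorical
#' comparisons. Equals `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = arms).
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stopf("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("zero marginal; chi-square undefined")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = 1L, p = unname(res$p.value))
}

#' Hedges g for a pre/post contrast
#'
#' `g = J * (mean(post) - mean(pre)) / s_avg` with
#' `s_avg = sqrt((sd_pre^2 + sd_post^2) / 2)` and the small-sample correction
#' `J = 1 - 3 / (4 (n - 1) - 1)`. Accepts raw paired vectors or summary
#' triples named `mean`, `sd` plus `n`.
#'
#' @param pre,post Numeric vectors (paired), or named `c(mean = , sd = )`.
#' @param n Required when summaries are given.
#' @return Numeric `g`.
#' @export
hedges_g_prepost <- function(pre, post, n = NULL) {
  is_sum <- function(x) !is.null(names(x)) && all(c("mean", "sd") %in% names(x))
  if (is_sum(pre) && is_sum(post)) {
    if (is.null(n)) stopf("n is required with summary input")
    m1 <- pre[["mean"]]; s1 <- pre[["sd"]]
    m2 <- post[["mean"]]; s2 <- post[["sd"]]
  } else {
    if (length(pre) != length(post)) stopf("pre and post must be paired")
    n <- length(pre)
    m1 <- mean(pre); s1 <- stats::sd(pre)
    m2 <- mean(post); s2 <- stats::sd(post)
  }
  if (n < 3) stopf("need n >= 3")
  s_avg <- sqrt((s1^2 + s2^2) / 2)
  if (s_avg == 0) stopf("zero spread; effect size undefined")
  (1 - 3 / (4 * (n - 1) - 1)) * (m2 - m1) / s_avg
}

#' Respondent analysis
#'
#' Counts participants whose pre-to-post improvement reaches
#' `threshold_sd` reference SDs. Improvement is a score decrease
#' (commission errors fall as inhibitory control improves); the threshold is
#' inclusive.
#'
#' @param pre,post Paired score vectors.
#' @param threshold_sd Standardized improvement threshold (default 0.64).
#' @param sd_ref Reference SD; default the SD of `pre`.
#' @return List with `count`, `proportion`, `n`.
#' @export
respondent_analysis <- function(pre, post, threshold_sd = 0.64,
                                sd_ref = stats::sd(pre)) {
  if (length(pre) != length(post)) stopf("pre and post must be paired")
  if (!is.numeric(sd_ref) || sd_ref <= 0) stopf("sd_ref must be positive")
  # small tolerance keeps the inclusive boundary robust to float rounding
  hit <- (pre - post) / sd_ref >= threshold_sd - 1e-9
  list(count = sum(hit), proportion = mean(hit), n = length(pre))
}

#' Positive predictive value of a significant finding
#'
#' `PPV = (power * R) / (power * R + alpha)` where `R` is the prestudy odds
#' that a probed effect is real.
#'
#' @param power Statistical power (1 - beta), in (0, 1].
#' @param alpha Significance level, in (0, 1].
#' @param R Prestudy odds, > 0.
#' @return Numeric PPV in (0, 1).
#' @export
ppv <- function(power, alpha, R) {
  if (power <= 0 || power > 1) stopf("power must be in (0, 1]")
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (R <= 0) stopf("R must be positive")
  (power * R) / (power * R + alpha)
}

#' Paired-samples t test
#'
#' Two-sided t test on the post-minus-pre differences of T-score-standardized
#' questionnaire scores.
#'
#' @param pre,post Paired score vectors, n >= 3.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre and post must be paired")
  n <- length(pre)
  if (n < 3) stopf("need n >= 3")
  d <- post - pre
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1))
    stopf("zero variance of differences; paired t degenerate")
  res <- tryCatch(stats::t.test(d), error = function(e)
    stopf("zero variance of differences; paired t degenerate"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Bonferroni adjustment within statistical families
#'
#' Multiplies each p-value by the size of its own family only (e.g. the two
#' questionnaire instruments are independent families, so four tests within
#' each get a factor of 4, not 8).
#'
#' @param p Numeric vector of p-values.
#' @param family Vector assigning each p-value to a family.
#' @return Adjusted p-values, capped at 1, in input order.
#' @export
bonferroni_within_families <- function(p, family) {
  if (length(p) != length(family)) stopf("p and family must have equal length")
  stats::ave(p, family, FUN = function(v) pmin(1, v * length(v)))
}

#' Baseline comparison table
#'
#' Between-arm comparison of age (pooled t test) and of the sex, medication
#' and psychological-treatment proportions (Pearson chi-square without
#' continuity correction).
#'
#' @param cohort A `cohort_table`.
#' @return data.frame with one row per characteristic: per-arm summary,
#'   statistic type, statistic value and p-value.
#' @export
baseline_table <- function(cohort) {
  exp_i <- cohort$arm == "experimental"
  ctl_i <- cohort$arm == "control"
  rows <- list()
  tt <- two_sample_t(cohort$age[exp_i], cohort$age[ctl_i])
  rows[[1]] <- data.frame(
    characteristic = "age_years",
    experimental = sprintf("%.2f (%.2f)", mean(cohort$age[exp_i]),
                           stats::sd(cohort$age[exp_i])),
    control = sprintf("%.2f (%.2f)", mean(cohort$age[ctl_i]),
                      stats::sd(cohort$age[ctl_i])),
    statistic = "t", value = tt$t, p = tt$p)
  flag_row <- function(name, flag) {
    tab <- rbind(c(sum(flag[exp_i]), sum(!flag[exp_i])),
                 c(sum(flag[ctl_i]), sum(!flag[ctl_i])))
    # a degenerate marginal (e.g. an all-male cohort) leaves the test undefined
    cs <- tryCatch(chi_square_2x2(tab),
                   error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(
      characteristic = name,
      experimental = sprintf("%d (%.1f%%)", tab[1, 1], 100 * tab[1, 1] / sum(exp_i)),
      control = sprintf("%d (%.1f%%)", tab[2, 1], 100 * tab[2, 1] / sum(ctl_i)),
      statistic = "chi2", value = cs$chi2, p = cs$p)
  }
  rows[[2]] <- flag_row("male", cohort$sex == "M")
  rows[[3]] <- flag_row("medicated", cohort$medicated)
  rows[[4]] <- flag_row("psych_treatment", cohort$psych_treatment)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
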
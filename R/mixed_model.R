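#' Pre/post random-intercept mixed model
#'
#' Fits the trial's primary model: a linear mixed model on the (optionally
#' standardized) outcome with fixed effects for period, condition and their
#' interaction and a random intercept per participant, estimated by REML.
#' The condition-by-period interaction is the treatment effect of interest;
#' with standardization by the whole-sample baseline mean and SD its
#' coefficient is a standardized mean difference. The model improvement from
#' adding the interaction is assessed by a likelihood-ratio chi-square (df =
#' 1) between maximum-likelihood fits. Age can be added stepwise as a
#' covariate when it lowers the (ML) AIC.
#'
#' @param data Long-format data.frame with columns `participant`, `arm`
#'   (`"experimental"`/`"control"`), `period` (`"pre"`/`"post"`), `score`,
#'   and optionally `age`. A missing post row is tolerated.
#' @param standardize Standardize the outcome by the whole-sample baseline
#'   mean/SD (default `TRUE`).
#' @param stepwise_age Consider `age` as a fixed covariate, kept when it
#'   improves the ML AIC (default `TRUE` when an age column is present).
#' @return A `prepost_lmm` object: `beta_interaction`, `se`, `t_value`, `df`,
#'   `p`, `lr_chi2`, `lr_p`, `aic`, `bic`, `r2`, `r2_adjusted`,
#'   `age_included`, `singular`, and the underlying `fit`.
#' @export
fit_prepost_mixed_model <- function(data, standardize = TRUE,
                                    stepwise_age = "age" %in% names(data)) {
  req <- c("participant", "arm", "period", "score")
  if (!all(req %in% names(data)))
    stopf("data must have columns %s", paste(req, collapse = ", "))
  data <- as.data.frame(data)
  data$arm <- factor(data$arm, levels = c("control", "experimental"))
  data$period <- factor(data$period, levels = c("pre", "post"))
  if (anyNA(data$arm) || anyNA(data$period))
    stopf("unknown arm or period labels")
  per_arm <- tapply(data$participant, data$arm,
                    function(x) length(unique(x)))
  if (any(is.na(per_arm)) || any(per_arm < 3))
    stopf("need at least 3 participants per arm")
  if (standardize) {
    base <- data$score[data$period == "pre"]
    data$score <- (data$score - mean(base)) / stats::sd(base)
  }
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  # degenerate data (e.g. zero residual variance) can break the default
  # optimizer; retry once with bobyqa before giving up
  safe_lmer <- function(fun, formula, reml) {
    tryCatch(quiet(fun(formula, data, REML = reml)),
             error = function(e)
               quiet(fun(formula, data, REML = reml,
                         control = lme4::lmerControl(optimizer = "bobyqa",
                                                     calc.derivs = FALSE))))
  }
  rhs0 <- "period + arm + (1 | participant)"
  rhs1 <- "period * arm + (1 | participant)"
  use_age <- FALSE
  if (isTRUE(stepwise_age) && "age" %in% names(data)) {
    m1 <- safe_lmer(lme4::lmer, stats::as.formula(paste("score ~", rhs1)), FALSE)
    m1a <- safe_lmer(lme4::lmer, stats::as.formula(paste("score ~ age +", rhs1)), FALSE)
    use_age <- stats::AIC(m1a) < stats::AIC(m1)
  }
  age_term <- if (use_age) "age + " else ""
  f0 <- stats::as.formula(paste("score ~", age_term, rhs0))
  f1 <- stats::as.formula(paste("score ~", age_term, rhs1))
  fit <- safe_lmer(lmerTest::lmer, f1, TRUE)
  m0 <- safe_lmer(lme4::lmer, f0, FALSE)
  m1 <- safe_lmer(lme4::lmer, f1, FALSE)
  lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0))))
  co <- stats::coef(summary(fit))
  term <- "periodpost:armexperimental"
  if (!term %in% rownames(co)) stopf("interaction term missing from the fit")
  yhat <- stats::fitted(fit)
  y <- data$score[!is.na(data$score)]
  r2 <- stats::cor(yhat, y)^2
  k <- nrow(co)
  nobs <- length(y)
  structure(list(
    beta_interaction = co[term, "Estimate"],
    se = co[term, "Std. Error"],
    t_value = co[term, "t value"],
    df = co[term, "df"],
    p = co[term, "Pr(>|t|)"],
    lr_chi2 = lr,
    lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    aic = stats::AIC(m1), bic = stats::BIC(m1),
    r2 = r2, r2_adjusted = 1 - (1 - r2) * (nobs - 1) / (nobs - k - 1),
    age_included = use_age,
    singular = lme4::isSingular(fit),
    fit = fit), class = "prepost_lmm")
}

#' @export
print.prepost_lmm <- function(x, ...) {
  cat("Pre/post random-intercept mixed model (REML)\n")
  cat(sprintf("  condition x period interaction: beta = %.3f (SE %.3f), t(%.1f) = %.2f, p = %.4g\n",
              x$beta_interaction, x$se, x$df, x$t_value, x$p))
  cat(sprintf("  LR test for the interaction: chi2(1) = %.3f, p = %.4g\n",
              x$lr_chi2, x$lr_p))
  cat(sprintf("  AIC %.1f, BIC %.1f, R2 %.3f (adj %.3f)%s%s\n", x$aic, x$bic,
              x$r2, x$r2_adjusted,
              if (x$age_included) ", age covariate included" else "",
              if (x$singular) ", singular fit" else ""))
  invisible(x)
}

#' @export
coef.prepost_lmm <- function(object, ...) {
  stats::coef(summary(object$fit))[, "Estimate"]
}

#' Simulate a standardized pre/post cohort in long format
#'
#' Participant intercepts carry a fraction `icc` of the unit total variance;
#' the remainder is occasion noise. The experimental arm receives an
#' additional post-period shift of `interaction_sd` standardized units.
#'
#' @param n_experimental,n_control Participants per arm.
#' @param interaction_sd Standardized condition-by-period interaction effect.
#' @param icc Intraclass correlation (share of participant-level variance,
#'   default 0.5).
#' @param age_range Age range for the simulated covariate.
#' @return Long-format data.frame usable by [fit_prepost_mixed_model()].
#' @export
simulate_prepost_cohort <- function(n_experimental = 15, n_control = 14,
                                    interaction_sd = 0, icc = 0.5,
                                    age_range = c(8, 11)) {
  if (icc < 0 || icc >= 1) stopf("icc must be in [0, 1)")
  n <- n_experimental + n_control
  arm <- rep(c("experimental", "control"), c(n_experimental, n_control))
  u <- stats::rnorm(n, 0, sqrt(icc))
  age <- stats::runif(n, age_range[1], age_range[2])
  e <- matrix(stats::rnorm(2 * n, 0, sqrt(1 - icc)), n, 2)
  pre <- u + e[, 1]
  post <- u + e[, 2] + interaction_sd * (arm == "experimental")
  data.frame(
    participant = rep(sprintf("S%03d", seq_len(n)), 2),
    arm = rep(arm, 2),
    period = rep(c("pre", "post"), each = n),
    age = rep(age, 2),
    score = c(pre, post))
}

#' Simulation-based power (and PPV) for the interaction effect
#'
#' Simulates two-arm pre/post cohorts with a planted standardized interaction
#' effect, fits the primary mixed model to each, and reports the fraction of
#' interaction p-values below `alpha`. The positive predictive value follows
#' from the power, `alpha` and the prestudy odds `R`.
#'
#' @param effect_sd Standardized interaction effect (e.g. 0.64, the a priori
#'   minimum clinically relevant difference).
#' @param n_per_arm Integer pair `(experimental, control)`.
#' @param alpha Significance level.
#' @param n_sims Number of simulated cohorts (>= 50; default 200).
#' @param seed Integer seed.
#' @param icc Intraclass correlation of the simulated scores (default 0.5).
#' @param R Prestudy odds for the PPV (default 0.5).
#' @return A `power_ppv` list: `power`, `n_sims`, `alpha`, `R`, `ppv`,
#'   `rejections`.
#' @export
simulate_power <- function(effect_sd, n_per_arm = c(15, 14), alpha = 0.05,
                           n_sims = 200, seed = 1, icc = 0.5, R = 0.5) {
  if (!is_count(n_sims) || n_sims < 50) stopf("n_sims must be an integer >= 50")
  rej <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    d <- simulate_prepost_cohort(n_per_arm[1], n_per_arm[2], effect_sd, icc)
    fit <- fit_prepost_mixed_model(d, standardize = FALSE, stepwise_age = FALSE)
    fit$p < alpha
  }, logical(1)))
  power <- mean(rej)
  structure(list(power = power, n_sims = n_sims, alpha = alpha, R = R,
                 ppv = ppv(max(power, 1 / n_sims), alpha, R),
                 rejections = sum(rej)), class = "power_ppv")
}

#' @export
print.power_ppv <- function(x, ...) {
  cat(sprintf("simulated power: %.3f (%d/%d rejections at alpha = %g); PPV = %.3f (R = %g)\n",
              x$power, x$rejections, x$n_sims, x$alpha, x$ppv, x$R))
  invisible(x)
}
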
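test_that("pooled t from summary triples replicates the printed age comparison", {
  res <- two_sample_t(c(mean = 9.2, sd = 1.21, n = 15),
                      c(mean = 9.71, sd = 1.33, n = 14))
  expect_equal(res$t, -1.081316, tolerance = 1e-5)
  expect_equal(signif(abs(res$t), 2), 1.1)
  expect_equal(res$df, 27)
  expect_gt(res$p, 0.25)
})

test_that("t statistic handles identical samples and matches t.test on raw data", {
  x <- c(1, 2, 3, 4, 5)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  y <- x + 1
  got <- two_sample_t(x, y)
  want <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p, want$p.value, tolerance = 1e-12)
  # hand-computed pooled formula: sp2 = 2.5, se = 1, t = -1
  expect_equal(got$t, -1, tolerance = 1e-12)

  welch <- two_sample_t(c(1, 2, 3, 9), c(2, 2.5, 3), var_equal = FALSE)
  ref <- t.test(c(1, 2, 3, 9), c(2, 2.5, 3))
  expect_equal(welch$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(ref$parameter), tolerance = 1e-9)
})

test_that("2x2 chi-square replicates the printed baseline comparisons", {
  med <- chi_square_2x2(rbind(c(9, 6), c(11, 3)))
  expect_equal(round(med$chi2, 2), 1.17)
  expect_equal(round(med$p, 2), 0.28)
  psy <- chi_square_2x2(rbind(c(4, 11), c(3, 11)))
  expect_equal(round(psy$chi2, 2), 0.11)
  expect_equal(round(psy$p, 2), 0.74)
  prop <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("chi-square shortcut formula equals the expected-count summation", {
  with_seed_local(8, {
    for (i in 1:20) {
      tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
      a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
      n <- sum(tab)
      shortcut <- n * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
      exp_tab <- outer(rowSums(tab), colSums(tab)) / n
      summation <- sum((tab - exp_tab)^2 / exp_tab)
      expect_lt(abs(shortcut - summation), 1e-12)
      expect_equal(chi_square_2x2(tab)$chi2, shortcut, tolerance = 1e-12)
    }
  })
})

test_that("Hedges g reproduces the printed control-arm effect and flips sign", {
  g_ctl <- hedges_g_prepost(c(mean = 48.79, sd = 7.53),
                            c(mean = 49.64, sd = 7.32), n = 14)
  expect_equal(g_ctl, 0.107733, tolerance = 1e-5)
  expect_equal(round(g_ctl, 1), 0.1)

  with_seed_local(4, {
    pre <- rnorm(12, 50, 6); post <- pre - 4 + rnorm(12)
    g1 <- hedges_g_prepost(pre, post)
    expect_equal(hedges_g_prepost(post, pre), -g1, tolerance = 1e-12)
    # closed form
    J <- 1 - 3 / (4 * 11 - 1)
    expect_equal(g1, J * (mean(post) - mean(pre)) /
                   sqrt((sd(pre)^2 + sd(post)^2) / 2), tolerance = 1e-12)
  })
  expect_equal(hedges_g_prepost(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("respondent analysis counts inclusive standardized improvements", {
  pre <- c(55, 52, 60, 49)
  expect_equal(respondent_analysis(pre, pre, sd_ref = 8)$count, 0)
  post <- pre - 0.64 * 8
  expect_equal(respondent_analysis(pre, post, sd_ref = 8)$count, 4)

  # 8 of 15 beyond threshold, like the emulated respondent table
  pre15 <- rep(50, 15)
  post15 <- pre15 - c(rep(6, 8), rep(1, 7)) # sd_ref 8: 0.75 SD vs 0.125 SD
  res <- respondent_analysis(pre15, post15, sd_ref = 8)
  expect_equal(res$count, 8)
  expect_equal(res$proportion, 8 / 15, tolerance = 1e-12)
  expect_error(respondent_analysis(pre, post, sd_ref = 0), "positive")
})

test_that("PPV follows the prestudy-odds formula and is monotone", {
  expect_equal(round(ppv(0.43, 0.05, 0.5), 2), 0.81)
  expect_equal(ppv(0.8, 0.05, 0.5), 0.888889, tolerance = 1e-5)
  expect_equal(ppv(1, 1e-12, 0.5), 1, tolerance = 1e-9)
  powers <- seq(0.1, 0.9, 0.2)
  expect_true(all(diff(vapply(powers, ppv, numeric(1), alpha = 0.05, R = 0.5)) > 0))
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  expect_true(all(diff(vapply(alphas, function(a) ppv(0.5, a, 0.5), numeric(1))) < 0))
  rs <- c(0.2, 0.5, 1, 2)
  expect_true(all(diff(vapply(rs, function(r) ppv(0.5, 0.05, r), numeric(1))) > 0))
  expect_error(ppv(0, 0.05, 0.5), "power")
})

test_that("paired t matches the closed form and flags degeneracy", {
  with_seed_local(6, {
    pre <- rnorm(10, 60, 9); post <- pre - 3 + rnorm(10, 0, 2)
  })
  got <- paired_t(pre, post)
  d <- post - pre
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_equal(got$df, 9)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_lt(got$t, 0) # sign follows the shift direction
  expect_error(paired_t(pre, pre + 2), "variance")
})

test_that("Bonferroni correction uses the within-family factor", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02, 0.03, 0.04)
  fam <- rep(c("BRIEF", "EDAH"), each = 4)
  adj <- bonferroni_within_families(p, fam)
  expect_equal(adj, pmin(1, p * 4)) # factor 4 within family, not 8
})

test_that("the baseline table assembles arm summaries with the right tests", {
  co <- generate_clinical_cohort(cohort_spec(seed = 31))
  tab <- baseline_table(co)
  expect_equal(tab$characteristic,
               c("age_years", "male", "medicated", "psych_treatment"))
  expect_equal(tab$statistic, c("t", "chi2", "chi2", "chi2"))
  want <- two_sample_t(co$age[co$arm == "experimental"],
                       co$age[co$arm == "control"])
  expect_equal(tab$value[1], want$t, tolerance = 1e-12)
})
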
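# Small planted-effect dataset for permutation tests.
perm_fixture <- function(n = 12, nodes = 36, seed = 31, rho = -0.8) {
  co <- tiny_cohort(n, seed = seed)
  g <- generate_source_space(nodes, 10, seed = 1)
  fx <- seq(10, 15, by = 1 / 3)
  d <- generate_power_data(co, g, effect_spec(band = c(11, 13), target_rho = rho,
                                              cluster_radius = 16),
                           freq_axis = fx, seed = seed + 1)
  list(cohort = co, graph = g, ratio = compute_ratio_tensor(d$pre, d$post),
       cpt = compute_cpt_ratio(co), truth = d$truth)
}

test_that("permutation p-values are deterministic under seed and use the +1 rule", {
  fx <- perm_fixture()
  par <- cluster_params(n_permutations = 100, min_extent_fraction = 0, seed = 4)
  r1 <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, par)
  r2 <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, par)
  expect_identical(r1$null_max_mass, r2$null_max_mass)
  expect_identical(r1$p_values, r2$p_values)
  expect_gt(length(r1$clusters), 0)
  # a planted effect this strong beats every one of the 100 null maxima
  expect_equal(min(r1$p_values), 1 / 101)
  expect_true(all(r1$p_values > 0 & r1$p_values <= 1))
  expect_length(r1$null_max_mass, 100)
})

test_that("doubling the permutations changes only p precision, not the clusters", {
  fx <- perm_fixture()
  p1 <- cluster_params(n_permutations = 100, min_extent_fraction = 0, seed = 4)
  p2 <- cluster_params(n_permutations = 200, min_extent_fraction = 0, seed = 4)
  r1 <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, p1)
  r2 <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, p2)
  expect_equal(lapply(r1$clusters, `[[`, "members"),
               lapply(r2$clusters, `[[`, "members"))
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "mass"),
               vapply(r2$clusters, `[[`, numeric(1), "mass"))
})

test_that("sampled permutation p agrees with exhaustive enumeration at n = 6", {
  n <- 6
  co <- tiny_cohort(n, seed = 77)
  g <- grid_graph(3, 1) # 3-node path
  fx_hz <- seq(10, 11, by = 1 / 3)
  with_seed_local(55, {
    vals <- array(rlnorm(n * 3 * 4), c(n, 3, 4))
    # couple node 1-2 to the behavioural ratio so a cluster tends to form
    cpt <- compute_cpt_ratio(co)
    for (s in 1:4) for (nd in 1:2)
      vals[, nd, s] <- vals[, nd, s] * exp(-1.5 * scale(cpt))
  })
  ratio <- power_tensor(vals, fx_hz, "ratio", co$participant_id)
  cpt <- compute_cpt_ratio(co)
  par <- cluster_params(alpha_node = 0.3, min_consecutive_steps = 2,
                        min_extent_fraction = 0, n_permutations = 720, seed = 9)
  res <- spectral_cluster_test(ratio, cpt, co$age, g, par)
  expect_gt(length(res$clusters), 0)

  # exhaustive null: every one of the 720 orderings once (a couple of
  # orderings make the permuted ranks collinear with age; their maps are
  # all-NA and contribute 0, matching the sampling path)
  map_for <- function(ord) suppressWarnings(correlation_maps(ratio, cpt[ord], co$age))
  all_ord <- all_perms(n)
  null_exact <- vapply(seq_len(nrow(all_ord)), function(i) {
    cl <- form_clusters(map_for(all_ord[i, ]), g, par)
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
  }, numeric(1))
  for (k in seq_along(res$clusters)) {
    p_exact <- mean(null_exact >= abs(res$clusters[[k]]$mass))
    expect_lt(abs(res$p_values[k] - p_exact), 2 / sqrt(720))
  }
})

test_that("observed clusters recover the planted spatio-spectral effect", {
  fx <- perm_fixture(n = 20, nodes = 60, seed = 41, rho = -0.85)
  par <- cluster_params(n_permutations = 100, seed = 2,
                        min_extent_fraction = 0.01)
  res <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, par)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_equal(top$sign, -1)
  truth_keys <- paste(fx$truth$members[, 1], fx$truth$members[, 2])
  got_keys <- paste(top$members[, "node"], top$members[, "step"])
  jac <- length(intersect(got_keys, truth_keys)) /
    length(union(got_keys, truth_keys))
  expect_gt(jac, 0.4)
  # in-band cells carry a consistently negative correlation
  expect_true(all(res$map$rho[top$members] < 0))
})

test_that("cluster summaries report per-group correlations and extent profile", {
  fx <- perm_fixture(n = 16, nodes = 36, seed = 61, rho = -0.9)
  par <- cluster_params(n_permutations = 100, min_extent_fraction = 0, seed = 3)
  res <- spectral_cluster_test(fx$ratio, fx$cpt, fx$cohort$age, fx$graph, par)
  expect_gt(length(res$clusters), 0)
  s <- cluster_summary(res$clusters[[1]], fx$ratio, fx$cohort)
  expect_equal(length(s$mean_ratio), 16L)
  expect_equal(s$correlations$group, c("whole", "experimental", "control"))
  expect_lt(s$correlations$rho[1], 0)
  expect_equal(sum(s$extent_per_step), nrow(res$clusters[[1]]$members))
  expect_true(s$peak_freq_hz >= 10 && s$peak_freq_hz <= 15)

  # constant marker: correlations undefined and flagged as NA
  ones <- power_tensor(array(1, dim(fx$ratio$values)), fx$ratio$freq_axis,
                       "ratio", fx$ratio$participant_order)
  s2 <- cluster_summary(res$clusters[[1]], ones, fx$cohort)
  expect_true(all(is.na(s2$correlations$rho)))
})

test_that("an arm-restricted effect yields a stronger in-arm correlation", {
  co <- tiny_cohort(24, seed = 71)
  g <- grid_graph(4, 4)
  fxh <- seq(10, 12, by = 1 / 3)
  vals <- with_seed_local(72, array(rlnorm(24 * 16 * 7, sdlog = 0.05),
                                    c(24, 16, 7)))
  cpt <- compute_cpt_ratio(co)
  z <- as.numeric(scale(cpt))
  exp_i <- co$arm == "experimental"
  # only experimental participants carry the coupling
  for (nd in 1:4) for (s in 1:7)
    vals[exp_i, nd, s] <- vals[exp_i, nd, s] * exp(-0.8 * z[exp_i])
  ratio <- power_tensor(vals, fxh, "ratio", co$participant_id)
  cl <- structure(list(members = cbind(node = rep(1:4, 7),
                                       step = rep(1:7, each = 4)),
                       sign = -1, mass = -10, freq_span = c(1L, 7L),
                       extent_per_step = setNames(rep(4L, 7), 1:7)),
                  class = "ss_cluster")
  s <- cluster_summary(cl, ratio, co)
  rho_exp <- s$correlations$rho[s$correlations$group == "experimental"]
  rho_ctl <- s$correlations$rho[s$correlations$group == "control"]
  expect_gt(abs(rho_exp), abs(rho_ctl))
})

test_that("ROI occupancy reproduces the printed-percentage arithmetic", {
  g <- generate_source_space(60, 10, seed = 5)
  # one region of 28 nodes with 11 in the cluster, one fully inside, one disjoint
  lab <- rep("unassigned", 60)
  lab[1:28] <- "Left precuneus"
  lab[29:31] <- "Right cuneus"
  lab[32:40] <- "Left thalamus"
  g <- source_graph(g$coords, g$edges, roi_labels = lab)
  members <- cbind(node = c(1:11, 29:31), step = 1L)
  cl <- structure(list(members = members, sign = 1, mass = 5,
                       freq_span = c(1L, 1L),
                       extent_per_step = setNames(nrow(members), 1)),
                  class = "ss_cluster")
  occ <- roi_occupancy(cl, g)
  expect_equal(occ$roi, c("Left precuneus", "Right cuneus"))
  expect_equal(occ$percent[occ$roi == "Left precuneus"], 39.29)
  expect_equal(occ$percent[occ$roi == "Right cuneus"], 100)
  expect_false("Left thalamus" %in% occ$roi)
})
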
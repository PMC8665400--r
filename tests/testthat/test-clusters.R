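# 3x3 spatial grid x 8 frequency steps with a 4-node significant patch,
# same sign, at a controllable run of steps.
patch_fixture <- function(sig_steps, rho_val = -0.5) {
  g <- grid_graph(3, 3)
  rho <- matrix(0.01, 9, 8)
  pval <- matrix(0.5, 9, 8)
  patch <- c(1, 2, 4, 5) # a connected 2x2 corner of the grid
  rho[patch, sig_steps] <- rho_val
  pval[patch, sig_steps] <- 0.01
  list(graph = g, map = manual_map(rho, pval))
}

test_that("a persistent same-sign patch forms exactly one cluster with additive mass", {
  fx <- patch_fixture(2:6)
  cl <- form_clusters(fx$map, fx$graph,
                      cluster_params(min_extent_fraction = 0, seed = 1))
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 20L)
  expect_equal(cl[[1]]$mass, sum(rep(-0.5, 20)), tolerance = 1e-12)
  expect_equal(cl[[1]]$sign, -1)
  expect_equal(cl[[1]]$freq_span, c(2L, 6L))
  expect_equal(unname(cl[[1]]$extent_per_step), rep(4L, 5))
})

test_that("the persistence filter removes runs shorter than four steps", {
  fx <- patch_fixture(2:4) # only 3 consecutive significant steps
  cl <- form_clusters(fx$map, fx$graph,
                      cluster_params(min_extent_fraction = 0, seed = 1))
  expect_length(cl, 0)
  # and an all-nonsignificant map yields no clusters at all
  null_map <- manual_map(matrix(0.01, 9, 8), matrix(0.5, 9, 8))
  expect_length(form_clusters(null_map, fx$graph, cluster_params(seed = 1)), 0)
})

test_that("the extent rule trims thin steps by default and discards on request", {
  fx <- patch_fixture(2:6)
  # drop one patch node at step 4 only: extent profile 4,4,3,4,4
  fx$map$pval[5, 4] <- 0.5
  # (persistence relaxed to 2 steps so node 5's split runs survive to the
  # extent stage: profile is then 4,4,3,4,4)
  cl0 <- form_clusters(fx$map, fx$graph,
                       cluster_params(min_consecutive_steps = 2,
                                      min_extent_fraction = 0, seed = 1))
  expect_length(cl0, 1)
  # requiring 4/9 nodes per step (ceiling(0.4 * 9) = 4): trimming the thin
  # step splits the component into two compliant pieces
  cl1 <- form_clusters(fx$map, fx$graph,
                       cluster_params(min_consecutive_steps = 2,
                                      min_extent_fraction = 0.4, seed = 1))
  expect_length(cl1, 2)
  expect_true(all(vapply(cl1, function(c) all(c$extent_per_step >= 4), logical(1))))
  expect_true(all(vapply(cl1, function(c) nrow(c$members), integer(1)) == 8L))
  expect_equal(vapply(cl1, `[[`, numeric(1), "mass"), c(-4, -4), tolerance = 1e-12)
  # the literal rule drops the whole component
  cl2 <- form_clusters(fx$map, fx$graph,
                       cluster_params(min_consecutive_steps = 2,
                                      min_extent_fraction = 0.4, seed = 1,
                                      extent_rule = "discard"))
  expect_length(cl2, 0)
})

test_that("a one-node tail is trimmed away instead of sinking the cluster", {
  fx <- patch_fixture(2:6)
  # node 5 alone stays significant one step beyond the patch
  fx$map$rho[5, 7] <- -0.5
  fx$map$pval[5, 7] <- 0.01
  cl <- form_clusters(fx$map, fx$graph,
                      cluster_params(min_consecutive_steps = 4,
                                     min_extent_fraction = 0.4, seed = 1))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$freq_span, c(2L, 6L))
  expect_equal(nrow(cl[[1]]$members), 20L)
  expect_equal(cl[[1]]$mass, -10, tolerance = 1e-12)
})

test_that("opposite signs never merge and clusters partition their cells", {
  g <- grid_graph(3, 3)
  rho <- matrix(0, 9, 8)
  pval <- matrix(0.5, 9, 8)
  rho[c(1, 2), 1:8] <- -0.6; pval[c(1, 2), 1:8] <- 0.01
  rho[c(3, 6), 1:8] <- 0.6; pval[c(3, 6), 1:8] <- 0.01 # adjacent column, + sign
  cl <- form_clusters(manual_map(rho, pval), g,
                      cluster_params(min_extent_fraction = 0, seed = 1))
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, numeric(1), "sign"), c(-1, 1))
  keys <- lapply(cl, function(c) paste(c$members[, 1], c$members[, 2]))
  expect_length(intersect(keys[[1]], keys[[2]]), 0)
  # sign consistency within each cluster
  for (c in cl) {
    vals <- rho[c$members]
    expect_true(all(sign(vals) == c$sign))
  }
})

test_that("component finding agrees with a transitive-closure oracle on small lattices", {
  with_seed_local(21, {
    for (rep in 1:6) {
      nr <- sample(2:4, 1); nc <- sample(2:4, 1); ns <- sample(3:6, 1)
      g <- grid_graph(nr, nc)
      n <- nr * nc
      rho <- matrix(0, n, ns); pval <- matrix(0.5, n, ns)
      sig <- matrix(runif(n * ns) < 0.45, n, ns)
      rho[sig] <- 0.5; pval[sig] <- 0.01
      cl <- form_clusters(manual_map(rho, pval), g,
                          cluster_params(min_consecutive_steps = 1,
                                         min_extent_fraction = 0, seed = 1))
      cells <- which(sig, arr.ind = TRUE)
      if (!nrow(cells)) { expect_length(cl, 0); next }
      want <- oracle_components(cells, g$edges, n)
      got <- lapply(cl, function(c)
        sort(match(paste(c$members[, 1], c$members[, 2]),
                   paste(cells[, 1], cells[, 2]))))
      expect_setequal(lapply(want, paste, collapse = ","),
                      vapply(got, paste, character(1), collapse = ","))
    }
  })
})
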
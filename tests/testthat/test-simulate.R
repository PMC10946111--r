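test_that("preferential-attachment networks have tree edge counts at m = 1", {
  a3 <- generate_ba_network(3, 1, seed = 1)
  expect_equal(sum(a3) / 2, 2)
  expect_true(isSymmetric(a3 * 1.0))
  expect_equal(diag(a3), rep(0L, 3), ignore_attr = TRUE)
  a20 <- generate_ba_network(20, 1, seed = 2)
  expect_equal(sum(a20) / 2, 19)
  expect_gte(max(rowSums(a20)), 2)
  expect_error(generate_ba_network(1), ">= 2")
})

test_that("scale-free graphs have heavier-tailed degrees than Erdos-Renyi", {
  set.seed(3)
  ba_max <- replicate(40, max(rowSums(generate_ba_network(200, 1))))
  er_max <- replicate(40, {
    g <- igraph::sample_gnm(200, 199)
    max(igraph::degree(g))
  })
  expect_gt(mean(ba_max), mean(er_max) + 2)
})

test_that("truth perturbation removes spiked neighborhoods and labels them", {
  # star graph: knocking out the hub disconnects every node
  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1L
  hub_removed <- matrix(0L, 6, 6)
  expect_equal(true_dc_labels(star, hub_removed), rep(1L, 6))
  # hand-enumerated 6-node path: remove node 3's edges in group 2 only
  path6 <- matrix(0L, 6, 6)
  for (i in 1:5) path6[i, i + 1] <- path6[i + 1, i] <- 1L
  om2 <- path6
  om2[3, ] <- om2[, 3] <- 0L
  expect_equal(true_dc_labels(path6, om2), c(0L, 1L, 1L, 1L, 0L, 0L))
  # shared spiked sets under equal effect sizes yield the exact null
  base <- generate_ba_network(12, 1, seed = 5)
  tr0 <- perturb_truth(base, 0.25, 0.25, seed = 6, share_spiked = TRUE)
  expect_identical(tr0$spiked1, tr0$spiked2)
  expect_equal(tr0$omega1, tr0$omega2)
  expect_equal(tr0$eta, rep(0L, 12))
})

test_that("spiked sets have ceiling(delta p) members drawn from non-isolated nodes", {
  base <- generate_ba_network(20, 1, seed = 7)
  tr <- perturb_truth(base, 0.05, 0.2, seed = 8)
  expect_length(tr$spiked1, 1)
  expect_length(tr$spiked2, 4)
  expect_true(all(rowSums(base)[c(tr$spiked1, tr$spiked2)] > 0))
  # eta matches a brute-force double loop on every draw
  eta_brute <- vapply(1:20, function(k)
    as.integer(sum(abs(tr$omega1[, k] - tr$omega2[, k])) > 0), integer(1))
  expect_equal(tr$eta, eta_brute)
})

test_that("simulated studies are reproducible and structurally valid", {
  cfg <- sim_config(p = 12, n = 40, delta1 = 0.1, delta2 = 0.2, seed = 10)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  counts <- s1$study$counts
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_equal(dim(counts), c(40, 12))
  # per-sample totals follow the drawn library sizes
  expect_true(all(rowSums(counts) >= 1))
  expect_lt(abs(log(mean(rowSums(counts))) - log(1e4)), 0.25)
})

test_that("zero fraction tracks the configured zero-inflation level", {
  cfg <- sim_config(p = 20, n = 300, delta1 = 0, delta2 = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  # copula lower-tail zeros plus occasional multinomial zeros
  expect_gt(mean(sim$study$counts == 0), 0.25)
  expect_lt(mean(sim$study$counts == 0), 0.40)
  cfg0 <- sim_config(p = 20, n = 300, delta1 = 0, delta2 = 0,
                     zero_inflation = 0, seed = 11)
  expect_lt(mean(simulate_dataset(cfg0)$study$counts == 0), 0.05)
})

test_that("planted edges separate from non-edges in SparCC estimates", {
  cfg <- sim_config(p = 10, n = 2000, delta1 = 0, delta2 = 0,
                    zero_inflation = 0, seed = 12)
  sim <- simulate_dataset(cfg)
  rho <- sparcc(sim$study$counts, sparcc_config(max_exclusion_iters = 0))
  A <- sim$truth$base
  ut <- upper.tri(A)
  edge_vals <- rho[ut & A == 1]
  non_vals <- rho[ut & A == 0]
  # AUC of edge vs non-edge separation
  auc <- mean(outer(edge_vals, non_vals, ">"))
  expect_gt(auc, 0.9)
})

test_that("multivariable mode shifts the group-2 covariate mean", {
  sim <- simulate_dataset(sim_config(p = 10, n = 2000, seed = 13))
  x <- sim$study$covariates[, "age"]
  g <- sim$study$group
  expect_equal(mean(x[g == 2]) - mean(x[g == 1]), 5, tolerance = 1)
  simu <- simulate_dataset(sim_config(p = 10, n = 2000, multivariable = FALSE,
                                      seed = 13))
  expect_null(simu$study$covariates)
})
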
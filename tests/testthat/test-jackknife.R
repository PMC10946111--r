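test_that("degree centrality is the signed column sum including the diagonal", {
  expect_equal(unname(degree_centrality(diag(4))), rep(1, 4))
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  expect_equal(unname(degree_centrality(m)), c(1.5, 1.5, 1.0))
  set.seed(2)
  r <- matrix(rnorm(36), 6)
  r <- (r + t(r)) / 2
  brute <- vapply(1:6, function(k) sum(r[, k]), numeric(1))
  expect_equal(unname(degree_centrality(r)), brute)
  expect_equal(unname(degree_centrality(r, absolute = TRUE)),
               vapply(1:6, function(k) sum(abs(r[, k])), numeric(1)))
})

test_that("pseudo-value arithmetic follows the jackknife identity", {
  # n_z = 4, full estimate 2.0, one leave-one-out estimate 1.9 -> 2.3
  pv <- pseudonet:::pseudovalues_from_centralities(2.0, matrix(1.9), 4)
  expect_equal(pv[1, 1], 4 * 2.0 - 3 * 1.9)
  # leave-one-out equal to full estimate -> pseudo-values equal the estimate
  th <- c(1.2, -0.4)
  loo <- rbind(th, th, th, th)
  pv2 <- pseudonet:::pseudovalues_from_centralities(th, loo, 4)
  expect_equal(pv2, matrix(th, 4, 2, byrow = TRUE), ignore_attr = TRUE)
})

test_that("jackknife pseudo-values equal a naive rebuild-from-scratch oracle", {
  study <- make_poisson_study(n = 40, p = 10, seed = 21)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  pv <- jackknife_pseudovalues(study, cfg)
  expect_equal(unname(pv), oracle_jackknife(study, cfg), ignore_attr = TRUE)
})

test_that("group means of pseudo-values equal the jackknife bias-corrected estimate", {
  study <- make_poisson_study(n = 24, p = 6, seed = 5)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  pv <- jackknife_pseudovalues(study, cfg)
  for (z in 1:2) {
    idx <- which(study$group == z)
    nz <- length(idx)
    theta <- colSums(sparcc(study$counts[idx, ], cfg))
    loo_mean <- colMeans(t(vapply(seq_along(idx), function(i)
      colSums(sparcc(study$counts[idx[-i], ], cfg)), numeric(6))))
    expect_equal(unname(colMeans(pv[idx, ])),
                 unname(nz * theta - (nz - 1) * loo_mean))
  }
})

test_that("pseudo-values are invariant to sample order within groups", {
  study <- make_poisson_study(n = 20, p = 5, seed = 9)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  pv <- jackknife_pseudovalues(study, cfg)
  perm <- sample(20)
  study_p <- grouped_study(study$counts[perm, ], study$group[perm],
                           covariates = study$covariates[perm, , drop = FALSE])
  pv_p <- jackknife_pseudovalues(study_p, cfg)
  expect_equal(unname(pv_p), unname(pv[perm, ]), ignore_attr = TRUE)
})

test_that("parallel leave-one-out matches serial execution exactly", {
  study <- make_poisson_study(n = 16, p = 5, seed = 13)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  expect_equal(jackknife_pseudovalues(study, cfg, jobs = 1L),
               jackknife_pseudovalues(study, cfg, jobs = 2L))
})

test_that("paired difference pseudo-values are zero for identical timepoints and antisymmetric", {
  s1 <- make_poisson_study(n = 20, p = 8, seed = 31)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  pv_same <- paired_difference_pseudovalues(s1, s1, cfg)
  expect_equal(unname(pv_same), matrix(0, 20, 8), ignore_attr = TRUE)
  set.seed(32)
  s2 <- grouped_study(matrix(rpois(20 * 8, 120), 20, 8), s1$group_levels[s1$group],
                      covariates = s1$covariates)
  pv12 <- paired_difference_pseudovalues(s1, s2, cfg)
  pv21 <- paired_difference_pseudovalues(s2, s1, cfg)
  expect_equal(unname(pv12), -unname(pv21), ignore_attr = TRUE)
})

test_that("paired pseudo-values match the naive two-timepoint oracle", {
  s1 <- make_poisson_study(n = 20, p = 8, seed = 41)
  set.seed(42)
  s2 <- grouped_study(matrix(rpois(20 * 8, 100), 20, 8),
                      s1$group_levels[s1$group], covariates = s1$covariates)
  cfg <- sparcc_config(max_exclusion_iters = 0)
  expect_equal(unname(paired_difference_pseudovalues(s1, s2, cfg)),
               oracle_paired_jackknife(s1, s2, cfg), ignore_attr = TRUE)
})

test_that("paired variant rejects mismatched subject sets", {
  s1 <- make_poisson_study(n = 16, p = 5, seed = 51)
  s2 <- make_poisson_study(n = 16, p = 5, seed = 52)
  s2$sample_ids[1] <- "other"
  expect_error(paired_difference_pseudovalues(s1, s2), "subject sets differ")
})

test_that("grouped_study enforces its invariants", {
  counts <- matrix(rpois(40, 10), 10, 4)
  expect_error(grouped_study(counts, rep(1, 10)), "two distinct")
  expect_error(grouped_study(counts, c(rep(1, 7), rep(2, 3))), "at least 4")
  expect_error(grouped_study(counts[, 1:2], rep(1:2, 5)), "3 taxa")
})
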
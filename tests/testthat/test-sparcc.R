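test_that("count-to-fraction conversion is row-stochastic and handles zeros", {
  expect_equal(to_fractions(matrix(c(1, 1), 1), 1)[1, ], c(0.5, 0.5))
  expect_equal(to_fractions(matrix(0, 1, 3), 1)[1, ], rep(1 / 3, 3))
  expect_equal(to_fractions(matrix(c(3, 1), 1), 1)[1, ], c(4 / 6, 2 / 6))
  set.seed(1)
  f <- to_fractions(matrix(rpois(60, 10), 10, 6))
  expect_equal(rowSums(f), rep(1, 10))
  expect_true(all(f > 0))
  expect_error(to_fractions(matrix(c(-1, 2), 1)), "non-negative")
  expect_error(to_fractions(matrix(c(0, 2, 1), 1), pseudocount = 0),
               "strictly positive")
})

test_that("log-ratio variances match closed forms and a brute-force oracle", {
  # constant ratio across samples -> zero variance
  f <- to_fractions(matrix(c(2, 2, 1, 4, 4, 2, 8, 8, 4), 3, byrow = TRUE), 0)
  expect_equal(logratio_variance(f)$T[1, 2], 0)
  # ratios e, e, 1/e, 1/e -> unbiased variance of (1,1,-1,-1) = 4/3
  u <- exp(c(1, 1, -1, -1))
  f2 <- cbind(u / (1 + u), 1 / (1 + u), 0)
  f2[, 3] <- 1e-9; f2 <- f2 / rowSums(f2)
  expect_equal(logratio_variance(f2)$T[1, 2], 4 / 3, tolerance = 1e-6)
  # random table vs elementwise double loop
  set.seed(7)
  fr <- to_fractions(matrix(rpois(40, 30), 10, 4))
  lrv <- logratio_variance(fr)
  expect_equal(lrv$T, oracle_logratio_variance(fr), ignore_attr = TRUE)
  expect_equal(lrv$t_total, rowSums(lrv$T))
  expect_error(logratio_variance(fr[1:2, ]), "3 samples")
})

test_that("basis-variance solver inverts forward-constructed systems", {
  # symmetric case: all variances s, zero correlation
  s <- 0.7
  Tm <- matrix(2 * s, 3, 3); diag(Tm) <- 0
  lrv <- structure(list(T = Tm, t_total = rowSums(Tm)),
                   class = "logratio_variances")
  expect_equal(solve_basis_variances(lrv), rep(s, 3))
  # p = 4 with distinct variances, rho = 0: T_jk = sigma_j^2 + sigma_k^2
  sig2 <- c(1, 2, 3, 4)
  Tm4 <- outer(sig2, sig2, "+"); diag(Tm4) <- 0
  lrv4 <- structure(list(T = Tm4, t_total = rowSums(Tm4)),
                    class = "logratio_variances")
  expect_equal(solve_basis_variances(lrv4), sig2)
  # excluding one pair keeps the system consistent and the solution exact
  expect_equal(solve_basis_variances(lrv4, cbind(1L, 2L)), sig2)
  # over-exclusion leaving a taxon with no partner is an error
  expect_error(solve_basis_variances(lrv, rbind(c(1L, 2L), c(1L, 3L))),
               "no retained partner")
})

test_that("correlation estimation satisfies the algebraic identities", {
  sig2 <- c(1, 4, 9)
  s <- sqrt(sig2)
  make_lrv <- function(Tm) {
    diag(Tm) <- 0
    structure(list(T = Tm, t_total = rowSums(Tm)),
              class = "logratio_variances")
  }
  # t_jk = sigma_j^2 + sigma_k^2  ->  rho = 0
  r0 <- estimate_correlations(make_lrv(outer(sig2, sig2, "+")), sig2)
  expect_equal(r0[upper.tri(r0)], rep(0, 3))
  # t_jk = (sigma_j - sigma_k)^2  ->  rho = 1
  r1 <- estimate_correlations(make_lrv(outer(s, s, "-")^2), sig2)
  expect_equal(r1[upper.tri(r1)], rep(1, 3))
  # t_jk = (sigma_j + sigma_k)^2  ->  rho = -1
  rm1 <- estimate_correlations(make_lrv(outer(s, s, "+")^2), sig2)
  expect_equal(rm1[upper.tri(rm1)], rep(-1, 3))
  expect_error(estimate_correlations(make_lrv(outer(s, s, "+")), c(0, 1, 1)),
               "strictly positive")
})

test_that("sparcc output is a valid association matrix on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    counts <- matrix(rnbinom(30 * 6, mu = 60, size = 2), 30, 6)
    rho <- sparcc(counts)
    expect_true(isSymmetric(unname(rho)))
    expect_equal(unname(diag(rho)), rep(1, 6))
    expect_true(all(rho >= -1 & rho <= 1))
  }
  expect_error(sparcc(matrix(rpois(20, 10), 10, 2)), "3 taxa")
})

test_that("sparcc is equivariant under taxon permutation", {
  set.seed(3)
  counts <- matrix(rnbinom(25 * 5, mu = 80, size = 3), 25, 5,
                   dimnames = list(NULL, paste0("t", 1:5)))
  perm <- c(4, 2, 5, 1, 3)
  r1 <- sparcc(counts)
  r2 <- sparcc(counts[, perm])
  expect_equal(unname(r2), unname(r1[perm, perm]), ignore_attr = TRUE)
})

test_that("sparcc is compositionally invariant to per-sample scaling", {
  set.seed(4)
  counts <- matrix(rpois(30 * 5, 200) + 1, 30, 5)
  cfg <- sparcc_config(pseudocount = 0)
  scaled <- counts * sample(1:7, 30, replace = TRUE)
  expect_equal(sparcc(counts, cfg), sparcc(scaled, cfg))
})

test_that("disabling exclusion iterations reproduces the single-pass solve", {
  set.seed(5)
  counts <- matrix(rpois(40 * 6, 100), 40, 6)
  cfg0 <- sparcc_config(max_exclusion_iters = 0)
  f <- to_fractions(counts, 1)
  lrv <- logratio_variance(f)
  direct <- estimate_correlations(lrv, solve_basis_variances(lrv))
  expect_equal(unname(sparcc(counts, cfg0)), unname(direct),
               ignore_attr = TRUE)
})

test_that("sparcc recovers basis correlations from log-normal compositions", {
  # independent log-normals: all correlations near zero
  set.seed(11)
  n <- 2000
  loga <- matrix(rnorm(n * 5, mean = rep(c(2, 3, 4, 3, 2), each = n)), n, 5)
  counts <- matrix(rpois(n * 5, exp(loga) * 10), n, 5)
  rho <- sparcc(counts)
  expect_lt(max(abs(rho[upper.tri(rho)])), 0.1)
  # one strongly correlated pair is found and excluded first
  S <- diag(6) * 0.25
  S[1, 2] <- S[2, 1] <- 0.8 * 0.25
  loga2 <- MASS::mvrnorm(n, mu = c(4, 4, 3, 3, 2, 2), Sigma = S)
  counts2 <- matrix(rpois(n * 6, exp(loga2) * 10), n, 6)
  rho2 <- sparcc(counts2)
  excl <- attr(rho2, "excluded_pairs")
  expect_gte(nrow(excl), 1)
  expect_equal(sort(excl[1, ]), c(1L, 2L))
  expect_equal(rho2[1, 2], 0.8, tolerance = 0.1)
})
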
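# Shared fixtures and independent oracle implementations used across tests.
# Oracles deliberately avoid the package's vectorized code paths.

# small random study with Poisson counts (no network structure)
make_poisson_study <- function(n = 40, p = 10, seed = 1, covariates = TRUE) {
  set.seed(seed)
  counts <- matrix(rpois(n * p, lambda = 120), n, p)
  group <- rep(1:2, length.out = n)
  covars <- if (covariates) cbind(age = rnorm(n, 55, 10)) else NULL
  grouped_study(counts, group, covariates = covars)
}

# brute-force log-ratio variances: explicit double loop over taxon pairs
oracle_logratio_variance <- function(fractions) {
  p <- ncol(fractions)
  Tm <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      if (j != k) Tm[j, k] <- var(log(fractions[, j] / fractions[, k]))
    }
  }
  Tm
}

# naive group-specific jackknife: rebuilds every leave-one-out count table
# from scratch and recomputes column sums of the SparCC estimate
oracle_jackknife <- function(study, config) {
  n <- nrow(study$counts)
  p <- ncol(study$counts)
  pv <- matrix(NA_real_, n, p)
  for (z in 1:2) {
    idx <- which(study$group == z)
    nz <- length(idx)
    theta <- colSums(sparcc(study$counts[idx, , drop = FALSE], config))
    for (i in seq_along(idx)) {
      keep <- idx[-i]
      th_i <- colSums(sparcc(study$counts[keep, , drop = FALSE], config))
      pv[idx[i], ] <- nz * theta - (nz - 1) * th_i
    }
  }
  pv
}

# naive paired-difference jackknife oracle
oracle_paired_jackknife <- function(s1, s2, config) {
  n <- nrow(s1$counts)
  p <- ncol(s1$counts)
  pv <- matrix(NA_real_, n, p)
  for (z in 1:2) {
    idx <- which(s1$group == z)
    nz <- length(idx)
    d_full <- sparcc(s2$counts[idx, , drop = FALSE], config) -
      sparcc(s1$counts[idx, , drop = FALSE], config)
    theta <- colSums(d_full)
    for (i in seq_along(idx)) {
      keep <- idx[-i]
      d_i <- sparcc(s2$counts[keep, , drop = FALSE], config) -
        sparcc(s1$counts[keep, , drop = FALSE], config)
      pv[idx[i], ] <- nz * theta - (nz - 1) * colSums(d_i)
    }
  }
  pv
}

# exhaustive LTS oracle: OLS on every h-subset, minimal trimmed objective
oracle_lts_enumerate <- function(y, X, h) {
  n <- length(y)
  subsets <- utils::combn(n, h)
  best <- list(obj = Inf, coef = NULL)
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    f <- lm.fit(X[idx, , drop = FALSE], y[idx])
    if (f$rank < ncol(X)) next
    r2 <- sort((y - X %*% f$coefficients)^2)
    obj <- sum(r2[seq_len(h)])
    if (obj < best$obj) best <- list(obj = obj, coef = f$coefficients)
  }
  best
}

# contingency-table metrics oracle
oracle_metrics <- function(call, eta) {
  tp <- sum(call == 1 & eta == 1); fp <- sum(call == 1 & eta == 0)
  fn <- sum(call == 0 & eta == 1); tn <- sum(call == 0 & eta == 0)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accuracy = (tp + tn) / length(eta))
}
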
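#' SparCC estimator configuration
#'
#' Settings for the compositional correlation estimator. The defaults follow
#' the original SparCC conventions: a pseudocount of 1 to smooth zero counts,
#' and an iterative "strong pair" exclusion loop that removes, one pair per
#' iteration, the not-yet-excluded taxon pair with the largest absolute
#' estimated correlation above `exclusion_threshold`, for at most
#' `max_exclusion_iters` iterations. Estimation is a deterministic single pass
#' on pseudocount-smoothed fractions (no Dirichlet resampling), so that
#' leave-one-out re-estimation downstream is exactly reproducible.
#'
#' @param pseudocount Non-negative value added to every count before
#'   conversion to fractions (default 1). A value of 0 is only valid when all
#'   counts are strictly positive.
#' @param exclusion_threshold Absolute correlation above which a pair may be
#'   excluded from the basis-variance system, in (0, 1) (default 0.1).
#' @param max_exclusion_iters Maximum number of exclusion iterations
#'   (default 10); 0 disables the exclusion loop.
#' @param clip_correlations Clip estimated correlations to \[-1, 1\]
#'   (default TRUE).
#' @return A list of class `sparcc_config`.
#' @export
sparcc_config <- function(pseudocount = 1, exclusion_threshold = 0.1,
                          max_exclusion_iters = 10L, clip_correlations = TRUE) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("`pseudocount` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(exclusion_threshold) || exclusion_threshold <= 0 ||
      exclusion_threshold >= 1)
    stop("`exclusion_threshold` must lie in (0, 1)", call. = FALSE)
  if (max_exclusion_iters < 0)
    stop("`max_exclusion_iters` must be >= 0", call. = FALSE)
  structure(list(pseudocount = pseudocount,
                 exclusion_threshold = exclusion_threshold,
                 max_exclusion_iters = as.integer(max_exclusion_iters),
                 clip_correlations = isTRUE(clip_correlations)),
            class = "sparcc_config")
}

#' Convert counts to relative abundances
#'
#' Adds a pseudocount to every cell and divides each sample (row) by its
#' total, yielding a strictly positive row-stochastic matrix of fractions.
#'
#' @param counts A samples-by-taxa matrix of non-negative counts.
#' @param pseudocount Non-negative smoothing constant (default 1); 0 requires
#'   strictly positive counts.
#' @return A numeric matrix of the same shape whose rows sum to 1.
#' @export
to_fractions <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("`counts` must be numeric", call. = FALSE)
  if (any(counts < 0))
    stop("`counts` must be non-negative", call. = FALSE)
  if (pseudocount < 0)
    stop("`pseudocount` must be non-negative", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0))
    stop("pseudocount 0 requires strictly positive counts", call. = FALSE)
  x <- counts + pseudocount
  x / rowSums(x)
}

#' Log-ratio variance matrix
#'
#' Computes the p-by-p matrix of unbiased sample variances of
#' log(u_j / u_k) over samples, the basic observable of compositional
#' correlation analysis, together with its row totals.
#'
#' @param fractions A strictly positive samples-by-taxa matrix (rows summing
#'   to 1; see [to_fractions()]).
#' @return A list of class `logratio_variances` with elements `T` (p-by-p
#'   symmetric, zero diagonal) and `t_total` (row sums of `T`).
#' @export
logratio_variance <- function(fractions) {
  fractions <- as.matrix(fractions)
  n <- nrow(fractions)
  if (n < 3L)
    stop("at least 3 samples are required to estimate log-ratio variances",
         call. = FALSE)
  if (any(fractions <= 0))
    stop("`fractions` must be strictly positive", call. = FALSE)
  L <- log(fractions)
  S <- stats::cov(L)                      # unbiased, denominator n - 1
  v <- diag(S)
  # Var(log u_j - log u_k) = Var(log u_j) + Var(log u_k) - 2 Cov
  Tm <- outer(v, v, "+") - 2 * S
  Tm <- (Tm + t(Tm)) / 2
  Tm[Tm < 0] <- 0                         # guard tiny negative round-off
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(fractions), colnames(fractions))
  structure(list(T = Tm, t_total = rowSums(Tm)), class = "logratio_variances")
}

#' Solve the basis-variance system
#'
#' Recovers the variances of the (unobserved) log basis abundances from the
#' log-ratio variance totals under the sparsity assumption: with d_j retained
#' partners for taxon j, the retained row total t_j satisfies approximately
#' t_j = d_j * sigma_j^2 + sum over retained partners k of sigma_k^2.
#' Negative solutions are clipped to a small positive floor.
#'
#' @param lrv A `logratio_variances` object.
#' @param excluded_pairs Optional two-column integer matrix of taxon index
#'   pairs excluded from the system (unordered; both orientations removed).
#' @param floor Lower clip for solved variances (default 1e-12).
#' @return Numeric vector of basis variances (length p).
#' @export
solve_basis_variances <- function(lrv, excluded_pairs = NULL, floor = 1e-12) {
  stopifnot(inherits(lrv, "logratio_variances"))
  Tm <- lrv$T
  p <- ncol(Tm)
  M <- matrix(1, p, p)
  diag(M) <- 0
  if (!is.null(excluded_pairs) && NROW(excluded_pairs) > 0L) {
    ep <- matrix(as.integer(excluded_pairs), ncol = 2L)
    M[ep] <- 0
    M[ep[, c(2L, 1L), drop = FALSE]] <- 0
  }
  d <- rowSums(M)
  if (any(d < 1)) {
    bad <- which(d < 1)
    nm <- colnames(Tm)[bad]
    if (is.null(nm)) nm <- bad
    stop("taxa left with no retained partner: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  A <- M
  diag(A) <- d
  t_ret <- rowSums(Tm * M)
  sigma2 <- tryCatch(solve(A, t_ret), error = function(e) {
    stop("basis-variance system is singular (over-exclusion among taxa ",
         paste(utils::head(colnames(Tm), 5L), collapse = ", "), " ...)",
         call. = FALSE)
  })
  pmax(as.numeric(sigma2), floor)
}

#' Correlations from basis variances
#'
#' Inverts the log-ratio variance identity
#' t_jk = sigma_j^2 + sigma_k^2 - 2 rho_jk sigma_j sigma_k
#' to estimate the taxon-taxon correlation matrix.
#'
#' @param lrv A `logratio_variances` object.
#' @param basis Numeric vector of strictly positive basis variances.
#' @param clip Clip estimates to \[-1, 1\] (default TRUE).
#' @return A p-by-p symmetric correlation matrix with unit diagonal.
#' @export
estimate_correlations <- function(lrv, basis, clip = TRUE) {
  stopifnot(inherits(lrv, "logratio_variances"))
  if (any(basis <= 0))
    stop("basis variances must be strictly positive", call. = FALSE)
  s <- sqrt(basis)
  rho <- (outer(basis, basis, "+") - lrv$T) / (2 * outer(s, s))
  rho <- (rho + t(rho)) / 2
  if (clip) rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(lrv$T)
  rho
}

#' SparCC co-abundance network estimate
#'
#' Estimates the compositional (basis) correlation matrix among taxa from a
#' count table: counts are smoothed and converted to fractions, log-ratio
#' variances are computed, and the basis-variance system is solved
#' iteratively while excluding, one per iteration, the strongest remaining
#' correlated pair above the exclusion threshold. The procedure is fully
#' deterministic.
#'
#' @param counts Samples-by-taxa matrix of non-negative counts with at least
#'   3 samples and 3 taxa.
#' @param config A [sparcc_config()] object.
#' @return A p-by-p symmetric association matrix with unit diagonal and
#'   entries in \[-1, 1\]; the excluded pairs are attached as the
#'   `"excluded_pairs"` attribute.
#' @export
#' @examples
#' set.seed(1)
#' counts <- matrix(rpois(20 * 5, 50), 20, 5,
#'                  dimnames = list(NULL, paste0("t", 1:5)))
#' rho <- sparcc(counts)
#' range(rho)
sparcc <- function(counts, config = sparcc_config()) {
  stopifnot(inherits(config, "sparcc_config"))
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L)
    stop("at least 3 taxa are required (basis system is underdetermined)",
         call. = FALSE)
  f <- to_fractions(counts, config$pseudocount)
  lrv <- logratio_variance(f)
  p <- ncol(lrv$T)
  excluded <- matrix(integer(0), 0L, 2L)
  excl_mask <- matrix(FALSE, p, p)
  iters <- config$max_exclusion_iters
  retained_partners <- rep(p - 1L, p)
  if (iters > 0L) {
    for (it in seq_len(iters)) {
      basis <- solve_basis_variances(lrv, excluded)
      rho <- estimate_correlations(lrv, basis, config$clip_correlations)
      a <- abs(rho)
      a[excl_mask] <- -Inf
      a[lower.tri(a, diag = TRUE)] <- -Inf
      # never exclude a pair that would leave a taxon with no partner
      # (the classic SparCC convention)
      blocked <- retained_partners <= 1L
      a[blocked, ] <- -Inf
      a[, blocked] <- -Inf
      best <- which.max(a)
      if (a[best] <= config$exclusion_threshold) break
      jk <- arrayInd(best, dim(a))
      excluded <- rbind(excluded, jk)
      excl_mask[jk] <- TRUE
      excl_mask[jk[, c(2L, 1L), drop = FALSE]] <- TRUE
      retained_partners[jk] <- retained_partners[jk] - 1L
    }
  }
  basis <- solve_basis_variances(lrv, excluded)
  rho <- estimate_correlations(lrv, basis, config$clip_correlations)
  attr(rho, "excluded_pairs") <- excluded
  attr(rho, "basis_variances") <- basis
  rho
}
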
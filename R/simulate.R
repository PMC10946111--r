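#' Simulation configuration
#'
#' Study conditions for the synthetic benchmark: a scale-free
#' (Barabasi-Albert) truth network over p taxa, perturbed per group by
#' removing all edges incident to each group's "spiked" covariate-associated
#' taxa (a fraction delta_z of taxa per group), and compositional counts
#' whose latent Gaussian copula carries the group-specific truth adjacency
#' while the spiked taxa also receive a covariate-driven marginal shift.
#'
#' @param p Number of taxa (default 20).
#' @param n Total number of samples (default 200); group labels are drawn
#'   Bernoulli(0.5).
#' @param delta1,delta2 Spike-in effect sizes in \[0, 1\]: the fraction of
#'   taxa per group whose edges are removed and whose abundance is
#'   covariate-associated (defaults 0.05 and 0.20).
#' @param multivariable If TRUE (default) a continuous covariate
#'   X ~ N(55, 10) (e.g. age) is generated with the group-2 mean shifted by
#'   `covariate_shift`, and spiked taxa load on standardized X per group; if
#'   FALSE only the group indicator acts (group-2 spiked taxa receive a mean
#'   shift) and no covariate enters the downstream regression.
#' @param ba_edges_per_node Edges added per node in the preferential
#'   attachment graph (default 1, a scale-free tree).
#' @param edge_correlation Latent correlation placed on truth-network edges
#'   (default 0.6).
#' @param covariate_shift Group-2 shift of the covariate mean (default 5,
#'   i.e. mean age 60 vs 55).
#' @param zero_inflation Marginal zero probability of each taxon's
#'   abundance (default 0.3); zeros arise from the lower tail of the latent
#'   Gaussian copula.
#' @param library_size_logmean,library_size_logsd Log-normal parameters of
#'   per-sample sequencing depth (defaults log(10000) and 0.3).
#' @param effect_coefficient Magnitude of the spiked covariate association on
#'   the latent log-abundance scale (default 1).
#' @param share_spiked Force both groups to share one spiked set when
#'   delta1 == delta2 (the exact-null configuration; default FALSE).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p = 20L, n = 200L, delta1 = 0.05, delta2 = 0.2,
                       multivariable = TRUE, ba_edges_per_node = 1L,
                       edge_correlation = 0.6, covariate_shift = 5,
                       zero_inflation = 0.3,
                       library_size_logmean = log(1e4),
                       library_size_logsd = 0.3,
                       effect_coefficient = 1, share_spiked = FALSE,
                       seed = 1L) {
  if (p < 3L) stop("`p` must be >= 3", call. = FALSE)
  if (delta1 < 0 || delta1 > 1 || delta2 < 0 || delta2 > 1)
    stop("effect sizes must lie in [0, 1]", call. = FALSE)
  if (ceiling(delta1 * p) >= p || ceiling(delta2 * p) >= p)
    stop("effect size spikes every taxon; reduce delta", call. = FALSE)
  if (edge_correlation <= 0 || edge_correlation >= 1)
    stop("`edge_correlation` must lie in (0, 1)", call. = FALSE)
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("`zero_inflation` must lie in [0, 1)", call. = FALSE)
  if (share_spiked && delta1 != delta2)
    stop("`share_spiked` requires delta1 == delta2", call. = FALSE)
  structure(list(p = as.integer(p), n = as.integer(n), delta1 = delta1,
                 delta2 = delta2, multivariable = isTRUE(multivariable),
                 ba_edges_per_node = as.integer(ba_edges_per_node),
                 edge_correlation = edge_correlation,
                 covariate_shift = covariate_shift,
                 zero_inflation = zero_inflation,
                 library_size_logmean = library_size_logmean,
                 library_size_logsd = library_size_logsd,
                 effect_coefficient = effect_coefficient,
                 share_spiked = isTRUE(share_spiked),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Scale-free random network
#'
#' Draws a Barabasi-Albert preferential-attachment graph and returns its
#' 0/1 adjacency matrix (symmetric, zero diagonal, connected for m >= 1).
#'
#' @param p Number of nodes (>= 2).
#' @param m Edges added per incoming node (default 1).
#' @param seed Optional seed applied locally.
#' @return A p-by-p 0/1 adjacency matrix.
#' @export
generate_ba_network <- function(p, m = 1L, seed = NULL) {
  if (p < 2L) stop("`p` must be >= 2", call. = FALSE)
  if (p < m + 1L) stop("`p` must exceed `m`", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  g <- igraph::sample_pa(p, m = m, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- pmin(A + t(A), 1)          # defensive 0/1 symmetrization
  diag(A) <- 0
  storage.mode(A) <- "integer"
  A
}

#' Group-specific truth-network perturbation
#'
#' Draws the spiked (covariate-associated) taxon sets S_z of size
#' `ceiling(delta_z * p)` uniformly among non-isolated nodes, removes from
#' the base adjacency all edges incident to S_z to form the group-specific
#' truth adjacency, and derives the per-taxon differential-connectivity
#' truth label: eta_k = 1 when taxon k has at least one neighbor differing
#' between the two group networks.
#'
#' @param base p-by-p 0/1 symmetric adjacency with zero diagonal.
#' @param delta1,delta2 Spike fractions in \[0, 1\].
#' @param seed Optional seed applied locally.
#' @param share_spiked Use a single spiked set for both groups (requires
#'   equal spike sizes); yields the exact null (identical networks).
#' @return A list of class `truth_network`: `base`, `omega1`, `omega2`,
#'   `spiked1`, `spiked2`, `eta`.
#' @export
perturb_truth <- function(base, delta1, delta2, seed = NULL,
                          share_spiked = FALSE) {
  base <- as.matrix(base)
  p <- ncol(base)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  k1 <- ceiling(delta1 * p)
  k2 <- ceiling(delta2 * p)
  if (k1 >= p || k2 >= p)
    stop("spiked set must leave at least one taxon untouched", call. = FALSE)
  eligible <- which(rowSums(base) > 0)
  if (length(eligible) < max(k1, k2))
    stop("not enough non-isolated nodes to spike", call. = FALSE)
  draw <- function(k) sort(eligible[sample.int(length(eligible), k)])
  s1 <- draw(k1)
  s2 <- if (share_spiked) {
    if (k1 != k2) stop("`share_spiked` requires equal spike sizes",
                       call. = FALSE)
    s1
  } else draw(k2)
  knock_out <- function(s) {
    om <- base
    om[s, ] <- 0L
    om[, s] <- 0L
    om
  }
  omega1 <- knock_out(s1)
  omega2 <- knock_out(s2)
  structure(list(base = base, omega1 = omega1, omega2 = omega2,
                 spiked1 = s1, spiked2 = s2,
                 eta = true_dc_labels(omega1, omega2)),
            class = "truth_network")
}

# Nearest positive-definite correlation matrix by eigenvalue clipping.
nearest_pd_corr <- function(S, eps = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- stats::cov2cor(R)
  (R + t(R)) / 2
}

#' Simulate a two-group microbiome study
#'
#' Generates a complete synthetic study under a [sim_config()]: binary
#' groups Z ~ Bernoulli(0.5); covariate X ~ N(55, 10) (group-2 mean shifted
#' when multivariable); a fresh scale-free truth network perturbed per group
#' around the spiked taxa; latent Gaussian vectors drawn per group from a
#' correlation matrix carrying `edge_correlation` on the group's truth edges
#' (projected to the nearest positive-definite correlation); zero-inflated
#' truncated log-normal marginals through the copula quantile transform --
#' a taxon's abundance is zero when its latent Gaussian falls below
#' `qnorm(zero_inflation)`, so zeros are coupled across taxa exactly as a
#' Gaussian copula with zero-inflated marginals implies, and the non-zero
#' part is a left-truncated log-normal with taxon-level location and scale
#' (upper tail winsorized at 3 sd); a covariate (or group) shift of the
#' spiked taxa's log-abundance; and multinomial counts at a log-normal
#' per-sample library size.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_study` with elements `study`
#'   (a [grouped_study()]), `truth` (a `truth_network`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$p
  n <- cfg$n
  Z <- stats::rbinom(n, 1L, 0.5) + 1L
  mu_x <- 55 + cfg$covariate_shift * (Z == 2L) * cfg$multivariable
  X <- stats::rnorm(n, mu_x, 10)
  base <- generate_ba_network(p, cfg$ba_edges_per_node)
  truth <- perturb_truth(base, cfg$delta1, cfg$delta2,
                         share_spiked = cfg$share_spiked)
  mu_taxon <- stats::rnorm(p, 0, 1)
  sd_taxon <- stats::runif(p, 0.5, 1.5)
  Xs <- as.numeric(scale(X))
  loga <- matrix(NA_real_, n, p)
  for (z in 1:2) {
    idx <- which(Z == z)
    omega <- if (z == 1L) truth$omega1 else truth$omega2
    spiked <- if (z == 1L) truth$spiked1 else truth$spiked2
    Sigma <- nearest_pd_corr(diag(p) + cfg$edge_correlation * omega)
    G <- MASS::mvrnorm(length(idx), mu = rep(0, p), Sigma = Sigma)
    zero <- G < stats::qnorm(cfg$zero_inflation)   # copula lower tail
    G <- pmin(G, 3)               # winsorize the upper tail
    la <- sweep(sweep(G, 2L, sd_taxon, "*"), 2L, mu_taxon, "+")
    la[zero] <- -Inf
    if (cfg$multivariable) {
      if (length(spiked))
        la[, spiked] <- la[, spiked] + cfg$effect_coefficient * Xs[idx]
    } else if (z == 2L && length(spiked)) {
      la[, spiked] <- la[, spiked] + cfg$effect_coefficient
    }
    loga[idx, ] <- la
  }
  abun <- exp(loga)
  lib <- pmax(1, round(stats::rlnorm(n, cfg$library_size_logmean,
                                     cfg$library_size_logsd)))
  counts <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    pr <- abun[i, ]
    if (sum(pr) <= 0) pr <- rep(1, p)   # degenerate all-zero guard
    counts[i, ] <- stats::rmultinom(1L, lib[i], pr)
  }
  dimnames(counts) <- list(sprintf("sample%03d", seq_len(n)),
                           sprintf("taxon%02d", seq_len(p)))
  covars <- if (cfg$multivariable) cbind(age = X) else NULL
  study <- grouped_study(counts, Z, covariates = covars)
  structure(list(study = study, truth = truth, config = cfg),
            class = "sim_study")
}
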
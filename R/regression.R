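#' q-values for multiple testing
#'
#' Converts p-values to q-values (FDR-scale significance measures). The
#' Storey method estimates the null proportion pi0 on the lambda grid
#' 0, 0.05, ..., 0.95 with a cubic smoothing spline and sets
#' `q_(i) = min over j >= i of pi0 * m * p_(j) / j`. The Benjamini-Hochberg
#' method is the pi0 = 1 special case (`stats::p.adjust` step-up values).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @param pi0 Optional null-proportion override in (0, 1\]; forcing 1 makes
#'   the Storey method coincide with BH.
#' @return Numeric vector of q-values in \[0, 1\], same order as `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  if (is.null(pi0)) {
    lambda <- seq(0, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m >= 4L) {
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    } else max(pi0_l)
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) pi0 <- 1 / m   # stabilizer for fully signal-dominated p
  }
  if (pi0 <= 0 || pi0 > 1) stop("`pi0` must lie in (0, 1]", call. = FALSE)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  run <- Inf
  rank_desc <- m:1
  for (j in seq_len(m)) {
    run <- min(run, pi0 * m * p[o[j]] / rank_desc[j])
    q[o[j]] <- run
  }
  pmin(q, 1)
}

#' Per-taxon pseudo-value regression tests
#'
#' For each taxon, regresses its jackknife pseudo-values on an intercept,
#' the binary group indicator (coded 0/1) and the study covariates by least
#' trimmed squares, and tests the group coefficient with
#' `U = beta / SE(beta)` against a t-distribution with the fit's residual
#' degrees of freedom. q-values over taxa control the FDR; a taxon is
#' flagged differentially connected (DC) when its q-value is below `alpha`.
#' Per-taxon fit failures yield an NA row with a warning rather than
#' aborting the analysis.
#'
#' @param pseudo n-by-p pseudo-value matrix aligned with `study` rows.
#' @param study A [grouped_study()].
#' @param lts An [lts_config()]; a set seed is offset by the taxon index so
#'   fits stay independent yet reproducible.
#' @param alpha DC call threshold on the q-value (default 0.05).
#' @param qvalue_method `"storey"` (default) or `"bh"`.
#' @return A data frame of class `dc_result`, one row per taxon: `taxon`,
#'   `beta`, `se`, `t_stat`, `p_value`, `q_value`, `is_dc`, plus one
#'   `gamma_<name>` column per covariate. Configuration and the centrality
#'   convention are attached as attributes.
#' @export
taxon_tests <- function(pseudo, study, lts = lts_config(), alpha = 0.05,
                        qvalue_method = c("storey", "bh")) {
  stopifnot(inherits(study, "grouped_study"))
  qvalue_method <- match.arg(qvalue_method)
  pseudo <- as.matrix(pseudo)
  n <- nrow(study$counts)
  p <- ncol(study$counts)
  if (nrow(pseudo) != n || ncol(pseudo) != p)
    stop("`pseudo` must be an n-by-p matrix aligned with the study",
         call. = FALSE)
  Z <- as.numeric(study$group == 2L)
  if (stats::var(Z) == 0)
    stop("group indicator is constant; two groups are required", call. = FALSE)
  design <- cbind("(Intercept)" = 1, group = Z, study$covariates)
  q_cov <- ncol(design) - 2L
  cov_names <- if (q_cov > 0) colnames(design)[-(1:2)] else character(0)
  out <- data.frame(taxon = study$taxon_ids,
                    beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                    p_value = NA_real_, q_value = NA_real_, is_dc = NA,
                    stringsAsFactors = FALSE)
  for (nm in cov_names) out[[paste0("gamma_", nm)]] <- NA_real_
  for (k in seq_len(p)) {
    cfg_k <- lts
    if (!is.null(lts$seed)) cfg_k$seed <- lts$seed + k
    fit <- tryCatch(fit_lts(pseudo[, k], design, cfg_k), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("LTS fit failed for taxon '", study$taxon_ids[k], "': ",
              conditionMessage(fit), call. = FALSE)
      next
    }
    beta <- unname(fit$coefficients[2L])
    se <- unname(fit$se[2L])
    tstat <- if (se > 0) beta / se else if (beta == 0) 0 else sign(beta) * Inf
    pval <- if (fit$df > 0) 2 * stats::pt(-abs(tstat), df = fit$df) else NA_real_
    out$beta[k] <- beta
    out$se[k] <- se
    out$t_stat[k] <- tstat
    out$p_value[k] <- pval
    for (nm in cov_names)
      out[[paste0("gamma_", nm)]][k] <- unname(fit$coefficients[nm])
  }
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- qvalues(out$p_value[ok], qvalue_method)
  out$is_dc <- out$q_value < alpha
  attr(out, "alpha") <- alpha
  attr(out, "qvalue_method") <- qvalue_method
  attr(out, "lts_config") <- lts
  attr(out, "centrality") <- attr(pseudo, "centrality")
  class(out) <- c("dc_result", "data.frame")
  out
}

#' Covariate-adjusted differential connectivity test
#'
#' The end-to-end pipeline: group-specific SparCC networks, leave-one-out
#' jackknife pseudo-values of degree centrality, per-taxon least trimmed
#' squares regression of the pseudo-values on group and covariates, and
#' q-value FDR control. The group coefficient estimates the change in a
#' taxon's network centrality between the two groups given the covariates.
#'
#' @param study A [grouped_study()].
#' @param sparcc_cfg A [sparcc_config()]; see [jackknife_pseudovalues()]
#'   for the calibration/sensitivity trade-off of the exclusion iterations.
#' @param lts_cfg An [lts_config()].
#' @param alpha DC call threshold on the q-value (default 0.05).
#' @param qvalue_method `"storey"` (default) or `"bh"`.
#' @param jobs Workers for the leave-one-out loop (default 1).
#' @param absolute Use absolute degree centrality (default FALSE).
#' @return A `dc_result` data frame (see [taxon_tests()]) with full
#'   provenance (configurations, centrality convention) in its attributes.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(p = 10, n = 24, seed = 7))
#' res <- dc_test(sim$study, lts_cfg = lts_config(seed = 1))
#' head(res)
dc_test <- function(study,
                    sparcc_cfg = sparcc_config(),
                    lts_cfg = lts_config(), alpha = 0.05,
                    qvalue_method = c("storey", "bh"), jobs = 1L,
                    absolute = FALSE) {
  qvalue_method <- match.arg(qvalue_method)
  pseudo <- tryCatch(
    jackknife_pseudovalues(study, sparcc_cfg, jobs = jobs,
                           absolute = absolute),
    error = function(e) stop("pseudo-value stage: ", conditionMessage(e),
                             call. = FALSE))
  res <- tryCatch(
    taxon_tests(pseudo, study, lts_cfg, alpha, qvalue_method),
    error = function(e) stop("regression stage: ", conditionMessage(e),
                             call. = FALSE))
  attr(res, "sparcc_config") <- sparcc_cfg
  res
}

#' Paired two-timepoint differential connectivity test
#'
#' Variant of [dc_test()] for paired designs: pseudo-values are computed on
#' the group-specific difference of the two timepoints' association matrices
#' (see [paired_difference_pseudovalues()]), so the group coefficient
#' measures between-group differences in the temporal change of
#' connectivity.
#'
#' @inheritParams dc_test
#' @param study_t1,study_t2 [grouped_study()] objects for the two
#'   timepoints (same subjects, taxa and groups).
#' @return A `dc_result` data frame.
#' @export
dc_test_paired <- function(study_t1, study_t2,
                           sparcc_cfg = sparcc_config(),
                           lts_cfg = lts_config(), alpha = 0.05,
                           qvalue_method = c("storey", "bh"), jobs = 1L,
                           absolute = FALSE) {
  qvalue_method <- match.arg(qvalue_method)
  pseudo <- tryCatch(
    paired_difference_pseudovalues(study_t1, study_t2, sparcc_cfg,
                                   jobs = jobs, absolute = absolute),
    error = function(e) stop("pseudo-value stage: ", conditionMessage(e),
                             call. = FALSE))
  res <- tryCatch(
    taxon_tests(pseudo, study_t1, lts_cfg, alpha, qvalue_method),
    error = function(e) stop("regression stage: ", conditionMessage(e),
                             call. = FALSE))
  attr(res, "sparcc_config") <- sparcc_cfg
  attr(res, "paired") <- TRUE
  res
}
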
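#' Two-group microbiome study container
#'
#' Bundles a count table with a binary group indicator and optional clinical
#' covariates. Group labels are recoded to 1/2 in sorted order of the
#' observed labels. Each group must have at least 4 subjects so that every
#' leave-one-out subsample still supports network estimation.
#'
#' @param counts Samples-by-taxa matrix of non-negative counts (>= 3 taxa).
#' @param group Length-n vector with exactly two distinct values.
#' @param covariates Optional n-by-q numeric matrix (or data frame coerced to
#'   one) of covariates; may be NULL for a group-only analysis.
#' @param sample_ids,taxon_ids Optional identifier vectors; default to the
#'   dimnames of `counts` or generated labels.
#' @return A list of class `grouped_study` with elements `counts`, `group`
#'   (integer 1/2), `covariates`, `sample_ids`, `taxon_ids`.
#' @export
grouped_study <- function(counts, group, covariates = NULL,
                          sample_ids = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  p <- ncol(counts)
  if (p < 3L) stop("at least 3 taxa are required", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  if (length(group) != n)
    stop("`group` length must match the number of samples", call. = FALSE)
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("`group` must take exactly two distinct values, got ",
         length(lev), call. = FALSE)
  g <- as.integer(match(group, lev))
  nz <- tabulate(g, 2L)
  if (any(nz < 4L))
    stop("each group needs at least 4 subjects (smallest has ", min(nz), ")",
         call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- colnames(counts)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids", call. = FALSE)
  dimnames(counts) <- list(sample_ids, taxon_ids)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("`covariates` rows must match samples", call. = FALSE)
    if (!is.numeric(covariates))
      stop("`covariates` must be numeric (expand factors to dummies first)",
           call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("X", seq_len(ncol(covariates)))
    rownames(covariates) <- sample_ids
  }
  structure(list(counts = counts, group = g, covariates = covariates,
                 sample_ids = sample_ids, taxon_ids = taxon_ids,
                 group_levels = lev),
            class = "grouped_study")
}

#' @export
print.grouped_study <- function(x, ...) {
  nz <- tabulate(x$group, 2L)
  cat("grouped_study:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa; groups", paste(x$group_levels, collapse = "/"),
      sprintf("(n1=%d, n2=%d);", nz[1], nz[2]),
      if (is.null(x$covariates)) "no covariates"
      else paste0(ncol(x$covariates), " covariate(s)"), "\n")
  invisible(x)
}

#' Degree centrality of an association matrix
#'
#' The connectivity summary compared between groups: the signed marginal
#' (column) sum of the association matrix, including the unit diagonal. The
#' constant diagonal contribution is absorbed by the regression intercept
#' downstream. An absolute-value variant is available but off by default.
#'
#' @param assoc A p-by-p symmetric association matrix.
#' @param absolute Sum absolute values instead of signed values
#'   (default FALSE).
#' @return Numeric vector of length p, named by taxon.
#' @export
degree_centrality <- function(assoc, absolute = FALSE) {
  assoc <- as.matrix(assoc)
  if (nrow(assoc) != ncol(assoc))
    stop("`assoc` must be square", call. = FALSE)
  if (absolute) colSums(abs(assoc)) else colSums(assoc)
}

# Eq.-style pseudo-value arithmetic: nz * full - (nz - 1) * leave-one-out.
# `theta_loo` is an nz-by-p matrix of leave-one-out centralities.
pseudovalues_from_centralities <- function(theta_full, theta_loo, nz) {
  theta_loo <- matrix(theta_loo, ncol = length(theta_full))
  sweep(-(nz - 1) * theta_loo, 2L, nz * theta_full, "+")
}

#' Group-specific jackknife pseudo-values of degree centrality
#'
#' For each group separately, estimates the SparCC association matrix on the
#' group's full subsample to obtain taxon degree centralities, re-estimates
#' it leaving each subject out in turn, and forms the leave-one-out jackknife
#' pseudo-value for subject i and taxon k:
#' `n_z * theta_k - (n_z - 1) * theta_k(i)`. Rows are returned in the
#' original sample order. Parallel execution over subjects is deterministic
#' and order-independent.
#'
#' The default SparCC configuration is the classic iterative estimator
#' (strong-pair exclusion, threshold 0.1, up to 10 iterations), matching the
#' network estimator the method is defined with. Note that the exclusion
#' loop is a discrete model-selection step: leave-one-out refits can flip
#' exclusion decisions, and the jackknife amplifies each flip by a factor of
#' n_z, which makes pseudo-values heavy-tailed and the downstream test
#' anticonservative. Passing `sparcc_config(max_exclusion_iters = 0)` gives
#' a smooth estimator with near-nominal type-I calibration at the cost of
#' sensitivity to global network perturbations; see the package vignette.
#'
#' @param study A [grouped_study()].
#' @param config A [sparcc_config()] (see Details).
#' @param jobs Number of worker processes for the leave-one-out loop
#'   (default 1).
#' @param absolute Use absolute degree centrality (default FALSE).
#' @return An n-by-p matrix of pseudo-values (rows = samples in input order),
#'   with the centrality convention recorded in the `"centrality"` attribute.
#' @export
jackknife_pseudovalues <- function(study,
                                   config = sparcc_config(),
                                   jobs = 1L, absolute = FALSE) {
  stopifnot(inherits(study, "grouped_study"))
  n <- nrow(study$counts)
  p <- ncol(study$counts)
  pv <- matrix(NA_real_, n, p,
               dimnames = list(study$sample_ids, study$taxon_ids))
  for (z in 1:2) {
    idx <- which(study$group == z)
    nz <- length(idx)
    cz <- study$counts[idx, , drop = FALSE]
    theta <- degree_centrality(sparcc(cz, config), absolute)
    loo <- parallel::mclapply(seq_len(nz), function(i) {
      tryCatch(
        degree_centrality(sparcc(cz[-i, , drop = FALSE], config), absolute),
        error = function(e) {
          stop("leave-one-out re-estimation failed for sample '",
               study$sample_ids[idx[i]], "': ", conditionMessage(e),
               call. = FALSE)
        })
    }, mc.cores = max(1L, as.integer(jobs)))
    bad <- vapply(loo, inherits, logical(1L), what = "try-error")
    if (any(bad)) stop(loo[[which(bad)[1L]]])
    theta_loo <- do.call(rbind, loo)
    pv[idx, ] <- pseudovalues_from_centralities(theta, theta_loo, nz)
  }
  attr(pv, "centrality") <- if (absolute) "absolute" else "signed"
  pv
}

#' Paired two-timepoint difference pseudo-values
#'
#' Temporal variant for paired designs: per group, the element-wise
#' difference of the timepoint-2 and timepoint-1 association matrices is
#' taken, degree centrality is computed on the difference, and jackknife
#' pseudo-values are formed by removing each subject from both timepoints
#' before re-estimating both matrices and their difference.
#'
#' @param study_t1,study_t2 [grouped_study()] objects for the two timepoints:
#'   identical subjects, taxa and group labels.
#' @param config A [sparcc_config()]; the smoothness trade-off discussed in
#'   [jackknife_pseudovalues()] applies here too.
#' @param jobs Workers for the leave-one-out loop (default 1).
#' @param absolute Use absolute degree centrality of the difference matrix
#'   (default FALSE).
#' @return An n-by-p pseudo-value matrix in the sample order of `study_t1`.
#' @export
paired_difference_pseudovalues <- function(study_t1, study_t2,
                                           config = sparcc_config(),
                                           jobs = 1L, absolute = FALSE) {
  stopifnot(inherits(study_t1, "grouped_study"),
            inherits(study_t2, "grouped_study"))
  if (!identical(study_t1$sample_ids, study_t2$sample_ids))
    stop("subject sets differ between timepoints", call. = FALSE)
  if (!identical(study_t1$taxon_ids, study_t2$taxon_ids))
    stop("taxon sets differ between timepoints", call. = FALSE)
  if (!identical(study_t1$group, study_t2$group))
    stop("group labels differ between timepoints", call. = FALSE)
  n <- nrow(study_t1$counts)
  p <- ncol(study_t1$counts)
  pv <- matrix(NA_real_, n, p,
               dimnames = list(study_t1$sample_ids, study_t1$taxon_ids))
  diff_centrality <- function(c1, c2) {
    degree_centrality(sparcc(c2, config) - sparcc(c1, config), absolute)
  }
  for (z in 1:2) {
    idx <- which(study_t1$group == z)
    nz <- length(idx)
    c1 <- study_t1$counts[idx, , drop = FALSE]
    c2 <- study_t2$counts[idx, , drop = FALSE]
    theta <- diff_centrality(c1, c2)
    loo <- parallel::mclapply(seq_len(nz), function(i) {
      diff_centrality(c1[-i, , drop = FALSE], c2[-i, , drop = FALSE])
    }, mc.cores = max(1L, as.integer(jobs)))
    theta_loo <- do.call(rbind, loo)
    pv[idx, ] <- pseudovalues_from_centralities(theta, theta_loo, nz)
  }
  attr(pv, "centrality") <- if (absolute) "absolute" else "signed"
  pv
}
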
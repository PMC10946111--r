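#' Read a two-group study from count and metadata files
#'
#' The count table is tab-separated with sample ids in the first column and
#' taxon ids as header (pass `taxa_are_rows = TRUE` for the transposed
#' dialect). Metadata is comma-separated with sample ids in the first
#' column. Tables are inner-joined on sample id; samples with missing group
#' or covariate values are dropped with a message. Character/factor
#' covariates are expanded to dummy columns.
#'
#' @param counts_path Path to the TSV count table.
#' @param metadata_path Path to the CSV metadata table.
#' @param group_col Name of the binary group column in the metadata.
#' @param covariate_cols Character vector of covariate column names
#'   (default none).
#' @param taxa_are_rows Counts are taxa-by-samples (default FALSE).
#' @return A [grouped_study()].
#' @export
read_study <- function(counts_path, metadata_path, group_col,
                       covariate_cols = character(0),
                       taxa_are_rows = FALSE) {
  if (!file.exists(counts_path))
    stop("count table not found: ", counts_path, call. = FALSE)
  if (!file.exists(metadata_path))
    stop("metadata not found: ", metadata_path, call. = FALSE)
  counts <- utils::read.delim(counts_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (ncol(counts) < 2L)
    stop("count table needs an id column plus taxa", call. = FALSE)
  ids <- as.character(counts[[1L]])
  cm <- as.matrix(counts[, -1L, drop = FALSE])
  if (!is.numeric(cm))
    stop("non-numeric values in count table ", counts_path, call. = FALSE)
  rownames(cm) <- ids
  if (taxa_are_rows) cm <- t(cm)
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mids <- as.character(meta[[1L]])
  if (anyDuplicated(rownames(cm)) || anyDuplicated(mids))
    stop("duplicate sample ids", call. = FALSE)
  if (!group_col %in% names(meta))
    stop("group column '", group_col, "' not in metadata", call. = FALSE)
  missing_cov <- setdiff(covariate_cols, names(meta))
  if (length(missing_cov))
    stop("covariate column(s) not in metadata: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  common <- intersect(rownames(cm), mids)
  if (!length(common))
    stop("no overlapping sample ids between counts and metadata",
         call. = FALSE)
  meta <- meta[match(common, mids), , drop = FALSE]
  cm <- cm[common, , drop = FALSE]
  keep_cols <- c(group_col, covariate_cols)
  complete <- stats::complete.cases(meta[, keep_cols, drop = FALSE])
  if (any(!complete))
    message("dropping ", sum(!complete),
            " sample(s) with missing group/covariate values: ",
            paste(common[!complete], collapse = ", "))
  meta <- meta[complete, , drop = FALSE]
  cm <- cm[complete, , drop = FALSE]
  covars <- NULL
  if (length(covariate_cols)) {
    cdf <- meta[, covariate_cols, drop = FALSE]
    for (j in seq_along(cdf))
      if (is.character(cdf[[j]])) cdf[[j]] <- factor(cdf[[j]])
    covars <- stats::model.matrix(~ ., data = cdf)[, -1L, drop = FALSE]
    rownames(covars) <- rownames(cm)
  }
  grouped_study(cm, meta[[group_col]], covariates = covars)
}

#' Write a study (and optional truth) to disk
#'
#' Writes the counts as TSV (sample id first column), the metadata as CSV
#' (sample id, group, covariates) and, if given, the truth network as JSON
#' (base and group adjacencies, spiked sets, truth labels).
#'
#' @param study A [grouped_study()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth_network` to serialize alongside.
#' @param prefix File name prefix (default "study").
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir, truth = NULL, prefix = "study") {
  stopifnot(inherits(study, "grouped_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, paste0(prefix, "_counts.tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_metadata.csv"))
  cdf <- data.frame(sample_id = study$sample_ids, study$counts,
                    check.names = FALSE)
  utils::write.table(cdf, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mdf <- data.frame(sample_id = study$sample_ids, group = study$group)
  if (!is.null(study$covariates))
    mdf <- cbind(mdf, as.data.frame(study$covariates))
  utils::write.csv(mdf, meta_path, row.names = FALSE, quote = FALSE)
  paths <- c(counts = counts_path, metadata = meta_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(
      list(base = truth$base, omega1 = truth$omega1, omega2 = truth$omega2,
           spiked1 = truth$spiked1, spiked2 = truth$spiked2,
           eta = truth$eta),
      truth_path, matrix = "rowmajor")
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Drop rare taxa by prevalence
#'
#' Removes taxa with non-zero counts in fewer than `min_prevalence` of the
#' samples (e.g. 0.10 drops taxa seen in fewer than 10% of samples), the
#' standard pre-filter before network estimation.
#'
#' @param study A [grouped_study()].
#' @param min_prevalence Fraction in \[0, 1\] (default 0.1).
#' @return A filtered [grouped_study()]; removed taxa are reported in a
#'   message and in the `"removed_taxa"` attribute.
#' @export
prevalence_filter <- function(study, min_prevalence = 0.1) {
  stopifnot(inherits(study, "grouped_study"))
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("`min_prevalence` must lie in [0, 1]", call. = FALSE)
  prev <- colMeans(study$counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop("prevalence filter removed every taxon", call. = FALSE)
  if (any(!keep))
    message("prevalence filter removed ", sum(!keep), " taxa: ",
            paste(study$taxon_ids[!keep], collapse = ", "))
  out <- grouped_study(study$counts[, keep, drop = FALSE],
                       study$group_levels[study$group],
                       covariates = study$covariates)
  attr(out, "removed_taxa") <- study$taxon_ids[!keep]
  out
}

#' Write a DC result table
#'
#' Tab-separated output, one row per taxon, preceded by a `#`-comment
#' header echoing the analysis configuration.
#'
#' @param res A `dc_result` from [dc_test()] or [taxon_tests()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dc_results <- function(res, path) {
  stopifnot(inherits(res, "dc_result"))
  lts <- attr(res, "lts_config")
  sp <- attr(res, "sparcc_config")
  hdr <- c(
    paste0("# alpha: ", attr(res, "alpha")),
    paste0("# qvalue_method: ", attr(res, "qvalue_method")),
    paste0("# centrality: ", attr(res, "centrality")),
    if (!is.null(sp))
      paste0("# sparcc: pseudocount=", sp$pseudocount,
             " exclusion_threshold=", sp$exclusion_threshold,
             " max_exclusion_iters=", sp$max_exclusion_iters),
    if (!is.null(lts))
      paste0("# lts: n_initial_subsets=", lts$n_initial_subsets,
             " reweight_cutoff=", lts$reweight_cutoff,
             " seed=", if (is.null(lts$seed)) "NA" else lts$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association matrix as TSV
#'
#' @param assoc p-by-p association matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_association <- function(assoc, path) {
  df <- data.frame(taxon = colnames(assoc), as.data.frame(assoc),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
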
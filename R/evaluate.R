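#' Per-taxon differential-connectivity truth labels
#'
#' A taxon is truly differentially connected when at least one of its
#' adjacency entries differs between the two group-specific truth networks:
#' `eta_k = I(sum_j |omega1_jk - omega2_jk| > 0)`.
#'
#' @param omega1,omega2 p-by-p 0/1 symmetric adjacency matrices.
#' @return Integer 0/1 vector of length p.
#' @export
true_dc_labels <- function(omega1, omega2) {
  omega1 <- as.matrix(omega1)
  omega2 <- as.matrix(omega2)
  if (!identical(dim(omega1), dim(omega2)))
    stop("adjacency matrices must have the same shape", call. = FALSE)
  as.integer(colSums(abs(omega1 - omega2)) > 0)
}

#' Classification metrics for DC calls
#'
#' Scores q-value calls (`q < alpha`) against the truth labels with the four
#' benchmark metrics: precision, recall, F1 (harmonic mean of the first
#' two) and accuracy. Ratios with a zero denominator are returned as NA
#' ("undefined") so replicate averages can exclude them.
#'
#' @param q_values Length-p q-values (NA allowed; NA is never a call).
#' @param eta Length-p 0/1 truth labels.
#' @param alpha Call threshold (default 0.05).
#' @return A list of class `dc_metrics`: `precision`, `recall`, `f1`,
#'   `accuracy`, `n_true_dc`, `n_called_dc`, `alpha`.
#' @export
compute_metrics <- function(q_values, eta, alpha = 0.05) {
  if (length(q_values) != length(eta))
    stop("`q_values` and `eta` must be aligned", call. = FALSE)
  eta <- as.integer(eta)
  call <- !is.na(q_values) & q_values < alpha
  p <- length(eta)
  tp <- sum(call & eta == 1L)
  fp <- sum(call & eta == 0L)
  fn <- sum(!call & eta == 1L)
  tn <- sum(!call & eta == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / p,
                 n_true_dc = sum(eta), n_called_dc = sum(call),
                 alpha = alpha),
            class = "dc_metrics")
}

#' Replicate simulation benchmark
#'
#' Runs the full pipeline over Monte Carlo replicates: each replicate draws
#' a fresh truth network and dataset (seed = `cfg$seed + s`), runs the
#' differential-connectivity test, and scores it against the truth labels.
#' Reports per-metric replicate means with Monte Carlo standard errors;
#' undefined (NA) metric values are dropped from the averages by default.
#'
#' @param cfg A [sim_config()]; its seed anchors the replicate seeds.
#' @param replicates Number of Monte Carlo replicates (default 50).
#' @param alpha Call threshold (default 0.05).
#' @param sparcc_cfg,lts_cfg Estimator configurations; the LTS seed is set
#'   per replicate from the replicate seed.
#' @param qvalue_method `"storey"` (default) or `"bh"`.
#' @param jobs Workers for the leave-one-out loops (default 1).
#' @param drop_undefined Drop NA metric values from means (default TRUE);
#'   FALSE zero-fills them instead.
#' @param verbose Print a line per replicate (default FALSE).
#' @return A list of class `dc_benchmark`: `summary` (one-row data frame in
#'   the layout p, n, delta1, delta2, precision, recall, f1, accuracy with
#'   `<metric>_se` columns, replicate and failure counts) and
#'   `per_replicate` (one row per completed replicate).
#' @export
run_benchmark <- function(cfg, replicates = 50L, alpha = 0.05,
                          sparcc_cfg = sparcc_config(),
                          lts_cfg = lts_config(),
                          qvalue_method = c("storey", "bh"), jobs = 1L,
                          drop_undefined = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  qvalue_method <- match.arg(qvalue_method)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  rows <- vector("list", replicates)
  n_failed <- 0L
  for (s in seq_len(replicates)) {
    cfg_s <- cfg
    cfg_s$seed <- cfg$seed + s
    lts_s <- lts_cfg
    lts_s$seed <- cfg$seed + s
    m <- tryCatch({
      sim <- simulate_dataset(cfg_s)
      res <- dc_test(sim$study, sparcc_cfg, lts_s, alpha, qvalue_method,
                     jobs = jobs)
      compute_metrics(res$q_value, sim$truth$eta, alpha)
    }, error = function(e) e)
    if (inherits(m, "error")) {
      n_failed <- n_failed + 1L
      warning("replicate ", s, " failed: ", conditionMessage(m),
              call. = FALSE)
      next
    }
    rows[[s]] <- data.frame(replicate = s, precision = m$precision,
                            recall = m$recall, f1 = m$f1,
                            accuracy = m$accuracy,
                            n_true_dc = m$n_true_dc,
                            n_called_dc = m$n_called_dc)
    if (verbose)
      message(sprintf("replicate %d: recall %.3f, F1 %s", s, m$recall,
                      format(m$f1, digits = 3)))
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(per) || nrow(per) == 0L)
    stop("all replicates failed", call. = FALSE)
  avg <- function(x) {
    if (!drop_undefined) x[is.na(x)] <- 0
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  met <- c("precision", "recall", "f1", "accuracy")
  stats_tab <- vapply(met, function(mn) avg(per[[mn]]), numeric(2L))
  summary <- data.frame(p = cfg$p, n = cfg$n, delta1 = cfg$delta1,
                        delta2 = cfg$delta2,
                        multivariable = cfg$multivariable,
                        as.list(stats_tab["mean", ]),
                        stats::setNames(as.list(stats_tab["se", ]),
                                        paste0(met, "_se")),
                        n_replicates = nrow(per), n_failed = n_failed)
  structure(list(summary = summary, per_replicate = per,
                 alpha = alpha, config = cfg),
            class = "dc_benchmark")
}

#' @export
print.dc_benchmark <- function(x, ...) {
  cat("Differential-connectivity benchmark (", x$summary$n_replicates,
      " replicates, alpha = ", x$alpha, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
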
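#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of order statistics. Values are reassigned by
#' rank, with ties broken deterministically by row order, so the sorted
#' value vector of every normalized column is identical and the operation
#' is exactly idempotent.
#'
#' @param m Numeric matrix, probes x samples, positive intensities.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop2("'m' must be a numeric matrix", class = "exprgraph_validation_error")
  if (ncol(m) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(m)
  }
  ref <- rowMeans(apply(m, 2L, sort, method = "radix"))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j], method = "radix"), j] <- ref
  out
}

#' Summarize probes to probe sets by median polish
#'
#' The RMA-style summarization step: each probe set's log2 probe x sample
#' block is fit with Tukey's median polish (rows-first sweeps, at most 10
#' iterations, stopping when the reduction in the sum of absolute residuals
#' falls below 1% of the current total), and the per-sample summary is the
#' overall effect plus the sample (column) effect.
#'
#' @param m Numeric matrix of linear-scale intensities, probes x samples
#'   (typically the output of [quantile_normalize()]).
#' @param probe_map Data frame with columns `probe_id` and `probeset_id`
#'   mapping each probe to exactly one probe set.
#' @return Matrix of log2 expression, probe sets x samples, rows in order of
#'   first appearance in `probe_map`; carries a `method_tag` attribute.
#' @export
median_polish_summarize <- function(m, probe_map) {
  if (!all(c("probe_id", "probeset_id") %in% names(probe_map)))
    stop2("'probe_map' needs columns probe_id and probeset_id",
          class = "exprgraph_validation_error")
  if (anyDuplicated(probe_map$probe_id))
    stop2("each probe must map to exactly one probe set",
          class = "exprgraph_validation_error")
  log2m <- log2(m)
  sets <- unique(probe_map$probeset_id)
  rows_of <- split(probe_map$probe_id, probe_map$probeset_id)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(m),
                dimnames = list(sets, colnames(m)))
  empty <- character()
  for (ps in sets) {
    probes <- intersect(rows_of[[ps]], rownames(log2m))
    if (!length(probes)) {
      empty <- c(empty, ps)
      next
    }
    block <- log2m[probes, , drop = FALSE]
    if (nrow(block) == 1L) {
      out[ps, ] <- block[1L, ]
    } else {
      fit <- medpolish(block, eps = 0.01, maxiter = 10L, trace.iter = FALSE,
                       na.rm = FALSE)
      out[ps, ] <- fit$overall + fit$col
    }
  }
  if (length(empty)) {
    warning(sprintf("%d probe set(s) had no probes in the matrix and were omitted: %s",
                    length(empty), paste(head(empty, 5L), collapse = ", ")))
    out <- out[setdiff(sets, empty), , drop = FALSE]
  }
  attr(out, "method_tag") <-
    "log2+quantile+medianpolish(rows-first,maxiter=10,eps=0.01)"
  out
}

#' Quality-control summary of an expression matrix
#'
#' Computes, per sample, the five-number summary and a Gaussian-kernel
#' density estimate on a 512-point grid spanning the observed range, plus
#' the sample-by-sample Spearman correlation matrix (average ranks for
#' ties). Constant (zero-variance) samples yield `NA` correlations and are
#' reported.
#'
#' @param m Numeric matrix, features x samples.
#' @return A list of class `qc_report` with elements `per_sample_quantiles`,
#'   `spearman_correlation`, `density_estimates`, and `constant_samples`.
#' @export
qc_report <- function(m) {
  if (!is.matrix(m) || ncol(m) < 1L)
    stop2("'m' must be a matrix with >= 1 sample",
          class = "exprgraph_validation_error")
  constant <- colnames(m)[apply(m, 2L, function(x) sd(x) == 0)]
  spearman <- suppressWarnings(cor(m, method = "spearman"))
  diag(spearman) <- ifelse(colnames(m) %in% constant, NA_real_, 1)
  quantiles <- apply(m, 2L, fivenum)
  rownames(quantiles) <- c("min", "q1", "median", "q3", "max")
  dens <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    d <- density(x, n = 512L, from = min(x), to = max(x))
    list(grid = d$x, density = d$y)
  })
  names(dens) <- colnames(m)
  structure(list(per_sample_quantiles = quantiles,
                 spearman_correlation = spearman,
                 density_estimates = dens,
                 constant_samples = constant),
            class = "qc_report")
}
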
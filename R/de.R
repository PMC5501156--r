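#' Differential-expression selection criteria
#'
#' The selection rule applied after testing: a gene is selected when its
#' BH-adjusted p-value is strictly below `fdr_threshold` and its absolute
#' log2 fold-change is strictly above `abs_log2fc_threshold` (the
#' conventional FDR < 0.05, |log2FC| > 1 defaults).
#'
#' @param fdr_threshold FDR cut, in (0, 1].
#' @param abs_log2fc_threshold Non-negative absolute log2 fold-change cut.
#' @return An object of class `de_criteria`.
#' @export
de_criteria <- function(fdr_threshold = 0.05, abs_log2fc_threshold = 1) {
  structure(list(
    fdr_threshold = assert_number(fdr_threshold, "fdr_threshold", 0, 1,
                                  strict_lower = TRUE),
    abs_log2fc_threshold = assert_number(abs_log2fc_threshold,
                                         "abs_log2fc_threshold", 0)
  ), class = "de_criteria")
}

#' Fit per-gene group means on a single-factor design
#'
#' Group-means parameterization: per gene, the mean of each `SETS` group and
#' the pooled residual variance s2 with n - (number of groups) degrees of
#' freedom. All pairwise contrasts (later group minus earlier group, in
#' order of first appearance in the phenodata) are enumerated for testing.
#'
#' @param eset Gene-level `SummarizedExperiment` (see [collapse_to_genes()]).
#' @return A list of class `de_fit`: `means` (genes x groups), `s2`, `df`
#'   (residual df, scalar), `group_sizes`, `contrasts` (data frame with
#'   columns `a`, `b`, `label`).
#' @export
fit_contrasts <- function(eset) {
  g <- groups_of(eset)
  levels <- unique(g)
  if (length(levels) < 2L)
    stop2("differential expression needs >= 2 groups in SETS",
          class = "exprgraph_validation_error")
  sizes <- table(factor(g, levels = levels))
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop2("group(s) with fewer than 2 samples: ",
          paste(small, collapse = ", "), class = "exprgraph_validation_error")
  expr <- exprs_of(eset)
  means <- matrix(
    vapply(levels, function(lv)
      rowMeans(expr[, g == lv, drop = FALSE]), numeric(nrow(expr))),
    nrow = nrow(expr), dimnames = list(rownames(expr), levels))
  resid <- expr - means[, g, drop = FALSE]
  df <- ncol(expr) - length(levels)
  s2 <- rowSums(resid ^ 2) / df
  pairs <- combn(levels, 2L)
  contrasts <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                          label = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
                          stringsAsFactors = FALSE)
  structure(list(means = means, s2 = s2, df = df,
                 group_sizes = setNames(as.integer(sizes), names(sizes)),
                 contrasts = contrasts,
                 genes = rownames(expr),
                 symbols = if ("symbol" %in%
                               names(SummarizedExperiment::rowData(eset)))
                   setNames(SummarizedExperiment::rowData(eset)$symbol,
                            rownames(expr)) else NULL),
            class = "de_fit")
}

trigamma_inverse <- function(y) {
  # Newton iteration on x -> trigamma(x), monotone decreasing on (0, Inf)
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits the standard hierarchical model in which the true per-gene variances
#' follow a scaled inverse chi-square prior with `d0` degrees of freedom and
#' location `s0^2`. Hyperparameters are estimated by matching the first two
#' moments of log s2 to the theoretical scaled-F distribution (digamma /
#' trigamma inversion). The posterior (shrunken) variance is
#' `(d0*s0^2 + df*s2) / (d0 + df)`.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene vector).
#' @param d0 Optional: force the prior degrees of freedom instead of
#'   estimating them. `0` reproduces the ordinary (unmoderated) t exactly;
#'   `Inf` shrinks every variance to `s0^2`.
#' @param s0sq Optional prior location; required when `d0` is forced and
#'   nonzero, estimated otherwise.
#' @return A list of class `variance_moderation`: `d0`, `s0sq`, `s2_post`,
#'   and `flag` (one of "estimated", "forced", "fallback_ordinary_t",
#'   "degenerate_infinite_prior").
#' @export
moderate_variances <- function(s2, df, d0 = NULL, s0sq = NULL) {
  df <- rep_len(df, length(s2))
  flag <- "estimated"
  if (!is.null(d0)) {
    flag <- "forced"
    if (d0 == 0) {
      s0sq <- s0sq %||% NA_real_
    } else if (is.null(s0sq)) {
      stop2("'s0sq' is required when forcing a nonzero 'd0'",
            class = "exprgraph_validation_error")
    }
  } else {
    usable <- which(df > 0 & is.finite(s2) & s2 > 0)
    if (length(usable) < 10L) {
      warning("fewer than 10 genes with positive residual variance; ",
              "falling back to ordinary t (no moderation)")
      flag <- "fallback_ordinary_t"
      d0 <- 0
      s0sq <- NA_real_
    } else {
      z <- log(s2[usable])
      e <- z - digamma(df[usable] / 2) + log(df[usable] / 2)
      emean <- mean(e)
      n <- length(e)
      evar <- mean((e - emean) ^ 2) * n / (n - 1) -
        mean(trigamma(df[usable] / 2))
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        flag <- "degenerate_infinite_prior"
        d0 <- Inf
        s0sq <- exp(emean)
      }
    }
  }
  s2_post <- if (is.infinite(d0)) rep_len(s0sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0sq + df * s2) / (d0 + df)
  structure(list(d0 = d0, s0sq = s0sq, s2_post = setNames(s2_post, names(s2)),
                 flag = flag),
            class = "variance_moderation")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p ascending, take `adj_i = min_{j >= i}
#' (m * p_j / j)` capped at 1, return in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop2("p-values must lie in [0, 1]", class = "exprgraph_validation_error")
  p.adjust(p, method = "BH")
}

#' Moderated t-tests for all pairwise contrasts
#'
#' For each pairwise group contrast: log2FC = mean(b) - mean(a), moderated
#' t = log2FC / sqrt(s2_post * (1/n_a + 1/n_b)), two-sided p from the t
#' distribution with `df + d0` degrees of freedom, BH adjustment within each
#' contrast (or globally with `adjust = "global"`), and selection per the
#' criteria (strict inequalities).
#'
#' @param fit A [fit_contrasts()] result.
#' @param moderation A [moderate_variances()] result.
#' @param criteria A [de_criteria()].
#' @param adjust `"per_contrast"` (default) or `"global"` BH family.
#' @return A data frame of class `de_result` with columns `gene`, `symbol`,
#'   `contrast`, `log2fc`, `t`, `p_value`, `fdr`, `selected`, `direction`;
#'   attributes `criteria` and `moderation`.
#' @export
test_pairwise <- function(fit, moderation, criteria = de_criteria(),
                          adjust = c("per_contrast", "global")) {
  adjust <- match.arg(adjust)
  d0 <- moderation$d0
  df_total <- fit$df + d0
  res <- do.call(rbind, lapply(seq_len(nrow(fit$contrasts)), function(i) {
    a <- fit$contrasts$a[i]; b <- fit$contrasts$b[i]
    lfc <- fit$means[, b] - fit$means[, a]
    se <- sqrt(moderation$s2_post *
                 (1 / fit$group_sizes[[a]] + 1 / fit$group_sizes[[b]]))
    t <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    p <- 2 * pt(-abs(t), df = df_total)
    data.frame(gene = fit$genes,
               symbol = if (!is.null(fit$symbols))
                 unname(fit$symbols[fit$genes]) else fit$genes,
               contrast = fit$contrasts$label[i],
               log2fc = unname(lfc), t = unname(t), p_value = unname(p),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$fdr <- if (adjust == "global") benjamini_hochberg(res$p_value)
             else ave(res$p_value, res$contrast, FUN = benjamini_hochberg)
  res$selected <- res$fdr < criteria$fdr_threshold &
    abs(res$log2fc) > criteria$abs_log2fc_threshold
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  structure(res, class = c("de_result", "data.frame"),
            criteria = criteria,
            moderation = moderation[c("d0", "s0sq", "flag")])
}

#' Union of selected genes across contrasts
#'
#' For multi-group designs the DE gene set of the experiment is the union of
#' the per-contrast selections, with per-gene provenance of which
#' contrast(s) selected it.
#'
#' @param de A `de_result` data frame.
#' @return A list: `genes` (character), `by_gene` (named list of contrast
#'   labels per selected gene).
#' @export
union_across_contrasts <- function(de) {
  sel <- de[de$selected, , drop = FALSE]
  by_gene <- split(sel$contrast, sel$gene)
  list(genes = names(by_gene), by_gene = by_gene)
}

#' One-call differential expression on an expression set
#'
#' Chains [fit_contrasts()], [moderate_variances()] and [test_pairwise()].
#'
#' @inheritParams test_pairwise
#' @param eset Gene- or probe-set-level `SummarizedExperiment`.
#' @param moderate `FALSE` forces the ordinary pooled-variance t (d0 = 0).
#' @return A `de_result` data frame.
#' @export
run_de <- function(eset, criteria = de_criteria(), moderate = TRUE,
                   adjust = "per_contrast") {
  fit <- fit_contrasts(eset)
  mod <- if (moderate) moderate_variances(fit$s2, fit$df)
         else moderate_variances(fit$s2, fit$df, d0 = 0)
  test_pairwise(fit, mod, criteria, adjust = adjust)
}
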
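#' Build the enrichment universe from platform gene sets
#'
#' The universe is the set of genes against which over-representation
#' counts are taken: for a single platform, its deduplicated gene set; for
#' several platforms analyzed together, the intersection of the
#' deduplicated sets.
#'
#' @param ... One or more character vectors of gene ids (one per platform),
#'   or a single list of them.
#' @return A list of class `universe`: `genes` (sorted unique ids) and
#'   `provenance` (`"single_platform"` or `"multi_platform_intersection"`).
#' @export
build_universe <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  if (!length(sets) || any(!lengths(sets)))
    stop2("every platform gene set must be nonempty",
          class = "exprgraph_validation_error")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  genes <- Reduce(intersect, sets)
  if (!length(genes))
    stop2("platform gene sets have an empty intersection; ",
          "check that the platforms are compatible",
          class = "exprgraph_validation_error")
  structure(list(genes = sort(genes),
                 provenance = if (length(sets) == 1L) "single_platform"
                              else "multi_platform_intersection"),
            class = "universe")
}

#' Hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of drawing at least `k`
#' annotated genes when `n` genes are drawn without replacement from a
#' universe of `N` genes of which `K` are annotated,
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param N Universe size.
#' @param K Universe genes annotated to the term.
#' @param n Query-set size.
#' @param k Query genes annotated to the term.
#' @return The upper-tail probability; vectorized over its arguments.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  args <- cbind(N, K, n, k)
  N <- args[, 1]; K <- args[, 2]; n <- args[, 3]; k <- args[, 4]
  if (any(args < 0) || any(args != round(args)))
    stop2("counts must be nonnegative integers",
          class = "exprgraph_validation_error")
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop2("count constraints violated: need k <= min(K, n), K <= N, n <= N",
          class = "exprgraph_validation_error")
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Hypergeometric over-representation of terms in gene clusters
#'
#' For each cluster, the query set is the cluster's genes intersected with
#' the universe; each term (restricted to the universe, tested only when it
#' has at least one universe gene) gets an upper-tail hypergeometric
#' p-value, flagged significant when strictly below `alpha`. No
#' multiple-testing correction is applied by default (the conventional raw
#' p < 0.001 cut); set `adjust = TRUE` for a BH-adjusted flag instead.
#'
#' @param clusters A `cluster_assignment`, or a named list of character
#'   vectors (cluster name -> gene ids).
#' @param term_map Named list of term member-gene vectors (see
#'   [read_gmt()]).
#' @param universe A [build_universe()] result.
#' @param alpha Significance cut on the (raw or adjusted) p-value.
#' @param adjust Apply BH adjustment within each cluster before flagging.
#' @return A data frame of class `enrichment_result`, sorted by p within
#'   cluster: `cluster`, `term_id`, `term_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `significant`.
#' @export
enrich_clusters <- function(clusters, term_map, universe, alpha = 0.001,
                            adjust = FALSE) {
  if (inherits(clusters, "cluster_assignment")) {
    lab <- clusters$labels
    cl_names <- if (!is.null(clusters$clust_info))
      clusters$clust_info[as.character(sort(unique(lab)))]
    else as.character(sort(unique(lab)))
    cl_sets <- split(names(lab), lab)
    names(cl_sets) <- unname(cl_names)
  } else cl_sets <- clusters
  uni <- universe$genes
  N <- length(uni)
  term_names <- attr(term_map, "term_names") %||%
    setNames(names(term_map), names(term_map))
  terms_u <- lapply(term_map, intersect, y = uni)
  terms_u <- terms_u[lengths(terms_u) >= 1L]

  empty <- data.frame(cluster = character(), term_id = character(),
                      term_name = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(terms_u))
    return(structure(empty, class = c("enrichment_result", "data.frame"),
                     alpha = alpha))

  out <- lapply(names(cl_sets), function(cl) {
    query <- intersect(cl_sets[[cl]], uni)
    if (!length(query)) {
      warning(sprintf("cluster '%s' has no genes in the universe; skipped", cl))
      return(NULL)
    }
    K <- lengths(terms_u)
    k <- vapply(terms_u, function(tg) length(intersect(tg, query)), integer(1))
    p <- hypergeom_upper_tail(N, K, length(query), k)
    data.frame(cluster = cl, term_id = names(terms_u),
               term_name = unname(term_names[names(terms_u)]),
               N = N, K = unname(K), n = length(query), k = unname(k),
               p_value = unname(p), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster = character(), term_id = character(),
                      term_name = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  crit <- if (adjust && nrow(res))
    ave(res$p_value, res$cluster, FUN = benjamini_hochberg) else res$p_value
  res$significant <- crit < alpha
  res <- res[order(res$cluster, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"), alpha = alpha)
}
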
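#' Pearson-correlation dissimilarity between genes
#'
#' `d_ij = 1 - pearson(x_i, x_j)` over the sample profiles of each gene
#' pair, so perfectly correlated genes are at distance 0 and perfectly
#' anti-correlated genes at distance 2.
#'
#' @param expr Numeric matrix, genes x samples, with >= 2 genes and
#'   positive variance per gene.
#' @return Square symmetric matrix with zero diagonal and the gene ids as
#'   dimnames.
#' @export
pearson_dissimilarity <- function(expr) {
  if (!is.matrix(expr) || nrow(expr) < 2L)
    stop2("need a matrix with >= 2 genes", class = "exprgraph_validation_error")
  v <- apply(expr, 1L, sd)
  if (any(v == 0))
    stop2("zero-variance gene(s): ",
          paste(head(rownames(expr)[v == 0], 10L), collapse = ", "),
          class = "exprgraph_validation_error")
  d <- 1 - cor(t(expr))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

new_cluster_assignment <- function(labels, method, k, parameters = list()) {
  structure(list(labels = labels, method = method, k = as.integer(k),
                 parameters = parameters,
                 sizes = table(labels),
                 clust_info = NULL, experiment = NULL),
            class = "cluster_assignment")
}

#' Hierarchical clustering on a dissimilarity matrix
#'
#' Agglomerative clustering (default average linkage) with the tree cut to
#' exactly `k` clusters. Deterministic for a given input.
#'
#' @param d Dissimilarity matrix from [pearson_dissimilarity()].
#' @param k Number of clusters, `2 <= k <= n`.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A `cluster_assignment` (named integer labels in `1..k`).
#' @export
hierarchical_cluster <- function(d, k, linkage = "average") {
  n <- nrow(d)
  if (k < 2L || k > n)
    stop2(sprintf("k must be in [2, %d]", n),
          class = "exprgraph_validation_error")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- stats::cutree(hc, k = k)
  new_cluster_assignment(labels, "hierarchical", k,
                         parameters = list(linkage = linkage))
}

pam_objective <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1L, min))
}

pam_assign <- function(d, medoids) {
  idx <- apply(d[, medoids, drop = FALSE], 1L, which.min)
  setNames(as.integer(idx), rownames(d))
}

#' k-medoids clustering (PAM: Partitioning Around Medoids)
#'
#' Native BUILD + SWAP implementation. BUILD seeds medoids greedily (first
#' the point minimizing total dissimilarity, then repeatedly the point with
#' the largest reduction of the objective). SWAP repeatedly applies the
#' best strictly-improving medoid/non-medoid exchange until none exists
#' (a local optimum of the total dissimilarity-to-nearest-medoid
#' objective). Ties are broken by index order, so the result is
#' deterministic.
#'
#' @param d Dissimilarity matrix.
#' @param k Number of clusters, `2 <= k < n`.
#' @return A `cluster_assignment` whose `parameters` carry the `medoids`
#'   (ids) and the final `objective`.
#' @export
pam_cluster <- function(d, k) {
  n <- nrow(d)
  if (k < 2L || k >= n)
    stop2(sprintf("k must be in [2, %d)", n),
          class = "exprgraph_validation_error")
  # BUILD
  medoids <- which.min(colSums(d))
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(j)
      sum(pmax(nearest - d[, j], 0)), numeric(1))
    best <- cand[which.max(gain)]
    medoids <- c(medoids, best)
    nearest <- pmin(nearest, d[, best])
  }
  # SWAP
  obj <- pam_objective(d, medoids)
  repeat {
    best_obj <- obj
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        trial <- medoids
        trial[mi] <- h
        o <- pam_objective(d, trial)
        if (o < best_obj - 1e-12) {
          best_obj <- o
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    obj <- best_obj
  }
  medoids <- sort(medoids)
  labels <- pam_assign(d, medoids)
  new_cluster_assignment(labels, "pam", k,
                         parameters = list(medoids = rownames(d)[medoids],
                                           objective = pam_objective(d, medoids)))
}

#' Average silhouette width of an assignment
#' @param d Dissimilarity matrix.
#' @param labels Integer cluster labels in the row order of `d`.
#' @return Mean silhouette width.
#' @export
average_silhouette <- function(d, labels) {
  sil <- cluster::silhouette(as.integer(labels), dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Choose k by maximizing average silhouette width
#'
#' Evaluates `k` over `k_range` (clamped to `[2, n-1]`) with the requested
#' method and returns the smallest `k` attaining the maximum average
#' silhouette width.
#'
#' @param d Dissimilarity matrix.
#' @param method `"pam"` or `"hierarchical"`.
#' @param k_range Candidate values of k.
#' @return The chosen k (integer).
#' @export
choose_k <- function(d, method = c("pam", "hierarchical"), k_range = 2:10) {
  method <- match.arg(method)
  n <- nrow(d)
  ks <- k_range[k_range >= 2 & k_range <= n - 1L]
  if (!length(ks))
    stop2("no admissible k in range for n = ", n,
          class = "exprgraph_validation_error")
  widths <- vapply(ks, function(k) {
    a <- if (method == "pam") pam_cluster(d, k) else hierarchical_cluster(d, k)
    average_silhouette(d, a$labels)
  }, numeric(1))
  as.integer(ks[which.max(widths)])
}

#' Attach experiment-scoped display names to clusters
#'
#' Each cluster receives a `clustInfo` string of the form
#' `"<method>:<k>:<index>@<experiment>"`, unique within an experiment and
#' parseable with [parse_clust_info()].
#'
#' @param assignment A `cluster_assignment`.
#' @param experiment_name Experiment label.
#' @return The assignment with `clust_info` (per cluster index) and
#'   `experiment` filled in.
#' @export
name_clusters <- function(assignment, experiment_name) {
  if (!length(assignment$labels))
    stop2("empty cluster assignment", class = "exprgraph_validation_error")
  idx <- sort(unique(assignment$labels))
  assignment$clust_info <- setNames(
    sprintf("%s:%d:%d@%s", assignment$method, assignment$k, idx,
            experiment_name),
    as.character(idx))
  assignment$experiment <- experiment_name
  assignment
}

#' @rdname name_clusters
#' @param clust_info A `clustInfo` string.
#' @export
parse_clust_info <- function(clust_info) {
  m <- regmatches(clust_info,
                  regexec("^([^:]+):([0-9]+):([0-9]+)@(.+)$", clust_info))[[1]]
  if (length(m) != 5L)
    stop2("not a valid clustInfo string: ", clust_info,
          class = "exprgraph_validation_error")
  list(method = m[2L], k = as.integer(m[3L]), index = as.integer(m[4L]),
       experiment = m[5L])
}

#' Cluster the DE-gene expression submatrix
#'
#' Convenience wrapper: Pearson dissimilarity on the given genes' profiles,
#' silhouette-based choice of k when `k` is `NULL`, clustering with the
#' requested method, and cluster naming.
#'
#' @param expr Gene x sample log2 matrix (typically the DE-selected
#'   submatrix).
#' @param method `"pam"` or `"hierarchical"`.
#' @param k Number of clusters, or `NULL` to choose by silhouette.
#' @param experiment_name Label used in `clustInfo` strings.
#' @return A named `cluster_assignment`.
#' @export
cluster_genes <- function(expr, method = c("pam", "hierarchical"), k = NULL,
                          experiment_name = "experiment") {
  method <- match.arg(method)
  d <- pearson_dissimilarity(expr)
  if (is.null(k)) k <- choose_k(d, method)
  a <- if (method == "pam") pam_cluster(d, k) else hierarchical_cluster(d, k)
  name_clusters(a, experiment_name)
}

#' Cluster assignment as a data frame
#' @param assignment A named `cluster_assignment`.
#' @return Data frame with columns `gene`, `cluster`, `clustInfo`, `method`,
#'   `k`.
#' @export
cluster_table <- function(assignment) {
  lab <- assignment$labels
  data.frame(gene = names(lab), cluster = as.integer(lab),
             clustInfo = if (!is.null(assignment$clust_info))
               unname(assignment$clust_info[as.character(lab)])
             else NA_character_,
             method = assignment$method, k = assignment$k,
             stringsAsFactors = FALSE, row.names = NULL)
}
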
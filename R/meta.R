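#' Restrict a collection of experiments to their common gene set
#'
#' Meta-analysis harmonization: every experiment's gene-level matrix is
#' subset to the intersection of the collections' gene ids (by entrez id).
#' That intersection is also the enrichment universe for the collection.
#'
#' @param esets List of two or more gene-level `SummarizedExperiment`s with
#'   distinct `experiment_name` metadata.
#' @return A list: `esets` (restricted, same order) and `universe` (a
#'   [build_universe()] result with multi-platform provenance).
#' @export
harmonize_genes <- function(esets) {
  if (length(esets) < 2L)
    stop2("a collection needs >= 2 experiments",
          class = "exprgraph_validation_error")
  names_ <- vapply(esets, function(e)
    S4Vectors::metadata(e)$experiment_name %||% "", character(1))
  if (anyDuplicated(names_))
    stop2("experiment names must be unique: ",
          paste(names_[duplicated(names_)], collapse = ", "),
          class = "exprgraph_validation_error")
  universe <- build_universe(lapply(esets, rownames))
  restricted <- lapply(esets, function(e) e[universe$genes, ])
  list(esets = restricted, universe = universe)
}

#' Integrate independently analyzed experiments into one graph
#'
#' Each experiment keeps its own `EXPERIMENT` and `CLUSTER` nodes (the
#' `clustInfo` strings carry the experiment tag) while `GENE` nodes are
#' shared, enabling cross-experiment queries such as [coexpressed_with()].
#' Per-experiment inference is untouched by the presence of the other
#' experiments; only the enrichment universe is collection-aware.
#'
#' @param g A graph holding background data.
#' @param experiments List of per-experiment result lists, each with
#'   elements `experiment` (metadata list with unique `name`), `de`,
#'   `clusters`, `enrichment`.
#' @return The graph.
#' @export
integrate_experiments <- function(g, experiments) {
  nms <- vapply(experiments, function(x) x$experiment$name %||% "",
                character(1))
  if (anyDuplicated(nms))
    stop2("duplicate experiment name(s): ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "),
          "; use re-load semantics for replacement instead",
          class = "exprgraph_validation_error")
  for (x in experiments)
    g <- load_experiment(g, x$experiment, de = x$de, clusters = x$clusters,
                         enrichment = x$enrichment)
  g
}

#' Meta-analysis of a collection of experiments
#'
#' Harmonizes the gene spaces, runs differential expression, clustering and
#' over-representation per experiment (against the shared intersection
#' universe), and integrates everything into a single property graph over
#' shared background data.
#'
#' @param esets List of gene-level `SummarizedExperiment`s.
#' @param annotation Gene annotation table (for background gene nodes).
#' @param ppi PPI table (or `NULL`).
#' @param term_map Named list of term gene sets.
#' @param criteria A [de_criteria()].
#' @param cluster_method,k Clustering settings (see [cluster_genes()]).
#' @param alpha Enrichment significance cut.
#' @param organism Organism label.
#' @return A list: `graph`, `universe`, and `per_experiment` (named list of
#'   `de`, `clusters`, `enrichment` per experiment).
#' @export
meta_analyze <- function(esets, annotation, ppi = NULL, term_map = list(),
                         criteria = de_criteria(), cluster_method = "pam",
                         k = NULL, alpha = 0.001,
                         organism = "Homo sapiens") {
  h <- harmonize_genes(esets)
  per <- lapply(h$esets, function(e) {
    name <- S4Vectors::metadata(e)$experiment_name
    de <- run_de(e, criteria)
    sel <- union_across_contrasts(de)
    clusters <- if (length(sel$genes) >= 3L)
      cluster_genes(exprs_of(e)[sel$genes, , drop = FALSE],
                    cluster_method, k, name)
    enr <- if (!is.null(clusters))
      enrich_clusters(clusters, term_map, h$universe, alpha = alpha)
    list(experiment = list(name = name,
                           platform = S4Vectors::metadata(e)$platform_id),
         de = de, clusters = clusters, enrichment = enr)
  })
  names(per) <- vapply(per, function(x) x$experiment$name, character(1))
  g <- load_background(annotation, ppi, organism)
  g <- integrate_experiments(g, per)
  list(graph = g, universe = h$universe, per_experiment = per)
}
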
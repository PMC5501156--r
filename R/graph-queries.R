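#' Schema summary: realized relationship triples
#'
#' Lists each distinct `(label_a, edge_type, label_b)` combination actually
#' present in the graph, once (undirected PPI edges are reported with their
#' canonical GENE-GENE orientation).
#'
#' @param g A [property_graph()].
#' @return Data frame with columns `from`, `type`, `to`, sorted.
#' @export
schema_summary <- function(g) {
  edges <- pg_edge_list(g)
  if (!length(edges))
    return(data.frame(from = character(), type = character(),
                      to = character(), stringsAsFactors = FALSE))
  tr <- unique(do.call(rbind, lapply(edges, function(e)
    data.frame(from = g$nodes[[e$from]]$label, type = e$type,
               to = g$nodes[[e$to]]$label, stringsAsFactors = FALSE))))
  tr <- tr[order(tr$from, tr$type, tr$to), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Node degree for one edge type
#'
#' The degree of node `i` is the number of edges of the selected type
#' adjacent to it (for undirected types each edge contributes to both
#' endpoints; for directed types in- and out-edges both count as
#' adjacent). By the handshake lemma the degrees of an undirected type sum
#' to twice the edge count.
#'
#' @param g A [property_graph()].
#' @param edge_type One of the schema edge types.
#' @param nodes Optional node ids to restrict the result to; defaults to
#'   every node whose label can touch the edge type.
#' @return Named integer vector of degrees.
#' @export
degree <- function(g, edge_type = "PPI_INTERACTION", nodes = NULL) {
  schema <- EDGE_SCHEMA[[edge_type]]
  if (is.null(schema))
    stop2("unknown edge type: ", edge_type, class = "exprgraph_schema_error")
  if (is.null(nodes)) {
    labs <- c(schema$from, schema$to)
    nodes <- vapply(Filter(function(nd) nd$label %in% labs, pg_node_list(g)),
                    `[[`, character(1), "id")
  }
  deg <- setNames(integer(length(nodes)), nodes)
  for (e in pg_edge_list(g)) {
    if (e$type != edge_type) next
    if (e$from %in% nodes) deg[[e$from]] <- deg[[e$from]] + 1L
    if (e$to %in% nodes) deg[[e$to]] <- deg[[e$to]] + 1L
  }
  deg
}

ppi_neighbors <- function(g, score_threshold) {
  nb <- list()
  for (e in pg_edge_list(g)) {
    if (e$type != "PPI_INTERACTION") next
    cs <- e$props$combined_score %||% NA_real_
    if (is.na(cs) || cs <= score_threshold) next
    nb[[e$from]] <- c(nb[[e$from]], e$to)
    nb[[e$to]] <- c(nb[[e$to]], e$from)
  }
  nb
}

#' Rank DE genes by qualifying PPI connectivity ("hub candidates")
#'
#' For every differentially expressed gene (a target of any `WAS_SELECTED`
#' edge), counts its distinct PPI partners with `combined_score`
#' strictly above the threshold that were themselves clusterized into a
#' cluster represented by at least one BP term — the full experiment ->
#' gene -> partner -> cluster -> BP traversal, not bare PPI degree. Ranked
#' by score descending, ties by gene symbol ascending, cut to `top_n`.
#'
#' @param g A graph holding background data and >= 1 loaded experiment.
#' @param combined_score_threshold Strict lower bound on the PPI combined
#'   score (default 0.80).
#' @param top_n Number of rows returned (default 10; `Inf` for all).
#' @return Data frame of class `hub_ranking`: `gene` (node id), `symbol`,
#'   `score`, and list columns `partners` (partner symbols) and `bp_terms`
#'   (BP term names attached to the partners' clusters).
#' @export
hub_candidates <- function(g, combined_score_threshold = 0.80, top_n = 10) {
  edges <- pg_edge_list(g)
  de_genes <- unique(vapply(Filter(function(e) e$type == "WAS_SELECTED",
                                   edges), `[[`, character(1), "to"))
  if (!length(de_genes)) {
    message("no DE genes (WAS_SELECTED edges) in the graph")
    return(structure(data.frame(gene = character(), symbol = character(),
                                score = integer(), stringsAsFactors = FALSE),
                     class = c("hub_ranking", "data.frame")))
  }
  cluster_of <- list()   # gene -> cluster ids
  for (e in edges) if (e$type == "WAS_CLUSTERIZED")
    cluster_of[[e$from]] <- c(cluster_of[[e$from]], e$to)
  bp_of_cluster <- list()
  for (e in edges) if (e$type == "WAS_REPRESENTED")
    bp_of_cluster[[e$from]] <- c(bp_of_cluster[[e$from]], e$to)
  nb <- ppi_neighbors(g, combined_score_threshold)

  rows <- lapply(de_genes, function(gid) {
    partners <- unique(nb[[gid]] %||% character())
    qualifying <- Filter(function(h) {
      cls <- cluster_of[[h]] %||% character()
      any(vapply(cls, function(cl) length(bp_of_cluster[[cl]]) > 0,
                 logical(1)))
    }, partners)
    bp_ids <- unique(unlist(lapply(qualifying, function(h)
      unlist(lapply(cluster_of[[h]], function(cl) bp_of_cluster[[cl]])))))
    sym_of <- function(id) g$nodes[[id]]$props$symbol %||% id
    data.frame(gene = gid, symbol = sym_of(gid),
               score = length(qualifying),
               partners = I(list(unname(sort(vapply(qualifying, sym_of,
                                                    character(1)))))),
               bp_terms = I(list(unname(sort(vapply(
                 bp_ids %||% character(),
                 function(b) g$nodes[[b]]$props$Term %||% b,
                 character(1)))))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  structure(head(res, top_n), class = c("hub_ranking", "data.frame"))
}

#' Materialize a HUB node for highly connected DE genes
#'
#' Creates one `HUB` node (name `"HUB"`) and an `AS_HUBS` edge from every
#' DE gene whose [hub_candidates()] score is strictly above
#' `score_threshold` (the conventional cut is 50). Re-running replaces the
#' previous HUB subgraph; when no gene qualifies the graph is left
#' unchanged.
#'
#' @param g A graph with a loaded experiment.
#' @param score_threshold Strict lower bound on the qualifying-partner
#'   count.
#' @param combined_score_threshold Passed to [hub_candidates()].
#' @return The graph, invisibly.
#' @export
create_hub <- function(g, score_threshold = 50,
                       combined_score_threshold = 0.80) {
  ranking <- hub_candidates(g, combined_score_threshold, top_n = Inf)
  hub_id <- "HUB:HUB"
  if (!is.null(g$nodes[[hub_id]])) pg_remove_node(g, hub_id)
  qual <- ranking[ranking$score > score_threshold, , drop = FALSE]
  if (!nrow(qual)) {
    message("no gene exceeds the hub score threshold of ", score_threshold,
            "; no HUB node created")
    return(invisible(g))
  }
  pg_add_node(g, hub_id, "HUB", list(name = "HUB"))
  for (gid in qual$gene)
    pg_add_edge(g, gid, hub_id, "AS_HUBS",
                list(score = qual$score[qual$gene == gid]))
  invisible(g)
}

#' Genes co-expressed with a gene across experiments
#'
#' Partners are genes sharing at least one cluster with the query gene via
#' `WAS_CLUSTERIZED`; the score is the number of distinct shared clusters
#' (across every loaded experiment), with the shared clusters' `clustInfo`
#' strings collected. Ordered by score descending, ties by symbol.
#'
#' @param g A graph with loaded experiments.
#' @param gene_symbol Symbol of the query gene.
#' @return Data frame: `symbol`, `score`, list column `clusters`.
#' @export
coexpressed_with <- function(g, gene_symbol) {
  nodes <- pg_node_list(g)
  genes <- Filter(function(nd) nd$label == "GENE", nodes)
  symbols <- vapply(genes, function(nd) nd$props$symbol %||% nd$id,
                    character(1))
  hit <- which(symbols == gene_symbol)
  if (!length(hit)) {
    near <- unique(symbols[agrepl(gene_symbol, symbols, max.distance = 0.2)])
    stop2("unknown gene symbol '", gene_symbol, "'",
          if (length(near)) paste0("; near matches: ",
                                   paste(head(near, 5L), collapse = ", ")),
          class = "exprgraph_validation_error")
  }
  gid <- genes[[hit[1L]]]$id
  members <- list()   # cluster -> genes
  for (e in pg_edge_list(g)) if (e$type == "WAS_CLUSTERIZED")
    members[[e$to]] <- c(members[[e$to]], e$from)
  shared_clusters <- names(members)[vapply(members, function(m) gid %in% m,
                                           logical(1))]
  partner_clusters <- list()
  for (cl in shared_clusters)
    for (h in setdiff(members[[cl]], gid))
      partner_clusters[[h]] <- c(partner_clusters[[h]], cl)
  if (!length(partner_clusters))
    return(data.frame(symbol = character(), score = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(names(partner_clusters), function(h) {
    cls <- unique(partner_clusters[[h]])
    data.frame(symbol = g$nodes[[h]]$props$symbol %||% h,
               score = length(cls),
               clusters = I(list(sort(vapply(cls, function(cl)
                 g$nodes[[cl]]$props$clustInfo %||% cl, character(1))))),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$score, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  res
}
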
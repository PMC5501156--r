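#' @name graph_schema
#' @title Property-graph schema
#'
#' @description
#' The knowledge store is a typed property graph. Node labels: `GENE`,
#' `BP` (biological process), `CLUSTER`, `EXPERIMENT`, `ORGANISM`, `HUB`.
#' Edge types and their endpoint constraints:
#' `PPI_INTERACTION` GENE-GENE (undirected, stored once with the smaller
#' node id first), `WAS_SELECTED` EXPERIMENT->GENE, `WAS_CLUSTERIZED`
#' GENE->CLUSTER, `WAS_REPRESENTED` CLUSTER->BP, `AS_HUBS` GENE->HUB,
#' `BELONGS_TO` GENE->ORGANISM. Inserting an edge that violates these
#' constraints raises an error of class `exprgraph_schema_error`.
NULL

NODE_LABELS <- c("GENE", "BP", "CLUSTER", "EXPERIMENT", "ORGANISM", "HUB")

EDGE_SCHEMA <- list(
  PPI_INTERACTION = list(from = "GENE", to = "GENE", directed = FALSE),
  WAS_SELECTED    = list(from = "EXPERIMENT", to = "GENE", directed = TRUE),
  WAS_CLUSTERIZED = list(from = "GENE", to = "CLUSTER", directed = TRUE),
  WAS_REPRESENTED = list(from = "CLUSTER", to = "BP", directed = TRUE),
  AS_HUBS         = list(from = "GENE", to = "HUB", directed = TRUE),
  BELONGS_TO      = list(from = "GENE", to = "ORGANISM", directed = TRUE)
)

PPI_CHANNELS <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
                  "experiments", "databases", "textmining", "combined_score")

#' Create an empty property graph
#'
#' Nodes carry exactly one label and a key-value property map; edges carry
#' a type and a property map. The store enforces the endpoint-label
#' constraints of the [graph_schema] on every insertion and never holds
#' duplicate `(source, target, type)` edges or dangling endpoints.
#'
#' @return An object of class `property_graph`.
#' @export
property_graph <- function() {
  structure(list(nodes = new.env(parent = emptyenv()),
                 edges = new.env(parent = emptyenv())),
            class = "property_graph")
}

edge_key <- function(from, to, type) paste(from, type, to, sep = "\r")

#' Low-level graph mutation and access
#'
#' `pg_add_node()` inserts (or upserts) a node; `pg_add_edge()` inserts an
#' edge after schema validation (undirected `PPI_INTERACTION` edges are
#' canonicalized to the smaller endpoint first; re-inserting an existing
#' edge replaces its properties, never duplicates it); `pg_remove_node()`
#' removes a node and every incident edge.
#'
#' @param g A [property_graph()].
#' @param id,from,to Node identifiers (character).
#' @param label One of the schema node labels.
#' @param type One of the schema edge types.
#' @param props Named list of atomic properties.
#' @return `g`, invisibly (the graph is modified in place).
#' @export
pg_add_node <- function(g, id, label, props = list()) {
  if (!label %in% NODE_LABELS)
    stop2("unknown node label: ", label, class = "exprgraph_schema_error")
  existing <- g$nodes[[id]]
  if (!is.null(existing) && existing$label != label)
    stop2(sprintf("node '%s' already exists with label %s", id,
                  existing$label), class = "exprgraph_schema_error")
  g$nodes[[id]] <- list(id = id, label = label, props = props)
  invisible(g)
}

#' @rdname pg_add_node
#' @export
pg_add_edge <- function(g, from, to, type, props = list()) {
  schema <- EDGE_SCHEMA[[type]]
  if (is.null(schema))
    stop2("unknown edge type: ", type, class = "exprgraph_schema_error")
  nf <- g$nodes[[from]]; nt <- g$nodes[[to]]
  if (is.null(nf) || is.null(nt))
    stop2(sprintf("edge %s: endpoint node(s) missing (%s, %s)", type,
                  from, to), class = "exprgraph_schema_error")
  if (!schema$directed && from > to) { tmp <- from; from <- to; to <- tmp
                                       tmp <- nf; nf <- nt; nt <- tmp }
  if (nf$label != schema$from || nt$label != schema$to)
    stop2(sprintf("edge %s requires %s->%s endpoints, got %s->%s", type,
                  schema$from, schema$to, nf$label, nt$label),
          class = "exprgraph_schema_error")
  if (!schema$directed && from == to)
    stop2("self-loops are not allowed for ", type,
          class = "exprgraph_schema_error")
  g$edges[[edge_key(from, to, type)]] <-
    list(from = from, to = to, type = type, props = props)
  invisible(g)
}

#' @rdname pg_add_node
#' @export
pg_remove_node <- function(g, id) {
  if (is.null(g$nodes[[id]])) return(invisible(g))
  for (e in pg_edge_list(g))
    if (e$from == id || e$to == id)
      rm(list = edge_key(e$from, e$to, e$type), envir = g$edges)
  rm(list = id, envir = g$nodes)
  invisible(g)
}

#' @rdname pg_add_node
#' @export
pg_node_list <- function(g) {
  ids <- sort(ls(g$nodes))
  lapply(ids, function(i) g$nodes[[i]])
}

#' @rdname pg_add_node
#' @export
pg_edge_list <- function(g) {
  keys <- sort(ls(g$edges))
  lapply(keys, function(k) g$edges[[k]])
}

#' @rdname pg_add_node
#' @export
pg_get_node <- function(g, id) g$nodes[[id]]

#' Graph metrics: node and edge counts by label and type
#'
#' @param g A [property_graph()].
#' @return A list with `n_nodes`, `n_edges`, `nodes_by_label` (named
#'   integer vector) and `edges_by_type`.
#' @export
graph_summary <- function(g) {
  nodes <- pg_node_list(g)
  edges <- pg_edge_list(g)
  labels <- vapply(nodes, `[[`, character(1), "label")
  types <- vapply(edges, `[[`, character(1), "type")
  list(n_nodes = length(nodes), n_edges = length(edges),
       nodes_by_label = c(table(factor(labels, levels = NODE_LABELS))),
       edges_by_type = c(table(factor(types, levels = names(EDGE_SCHEMA)))))
}

gene_node_id <- function(entrez) paste0("GENE:", entrez)

#' Load background data: genes, organism, and the PPI network
#'
#' Every distinct annotated gene becomes a `GENE` node (properties
#' `entrez_id`, `symbol`, `description`) linked `BELONGS_TO` its `ORGANISM`
#' node; PPI rows become undirected `PPI_INTERACTION` edges carrying the
#' seven evidence channels plus `combined_score`. PPI rows referencing
#' unknown genes are skipped and counted.
#'
#' @param annotation Data frame with columns `entrez_id`, `symbol`,
#'   `description` (and optionally `probeset_id`).
#' @param ppi Data frame with columns `gene_a`, `gene_b` and the STRING
#'   channel scores; may be `NULL` or empty.
#' @param organism Organism label.
#' @param g An existing graph to extend, or `NULL` for a fresh one.
#' @return The graph, with attribute `skipped_ppi_edges` (count).
#' @export
load_background <- function(annotation, ppi = NULL,
                            organism = "Homo sapiens", g = NULL) {
  g <- g %||% property_graph()
  org_id <- paste0("ORGANISM:", organism)
  pg_add_node(g, org_id, "ORGANISM", list(name = organism))
  ann <- annotation[!duplicated(annotation$entrez_id), , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    gid <- gene_node_id(ann$entrez_id[i])
    pg_add_node(g, gid, "GENE",
                list(entrez_id = as.character(ann$entrez_id[i]),
                     symbol = ann$symbol[i],
                     description = ann$description[i],
                     organism = organism))
    pg_add_edge(g, gid, org_id, "BELONGS_TO")
  }
  skipped <- 0L
  if (!is.null(ppi) && nrow(ppi)) {
    channels <- intersect(PPI_CHANNELS, names(ppi))
    for (i in seq_len(nrow(ppi))) {
      a <- gene_node_id(ppi$gene_a[i]); b <- gene_node_id(ppi$gene_b[i])
      if (is.null(g$nodes[[a]]) || is.null(g$nodes[[b]])) {
        skipped <- skipped + 1L
        next
      }
      pg_add_edge(g, a, b, "PPI_INTERACTION",
                  as.list(ppi[i, channels, drop = FALSE]))
    }
  }
  attr(g, "skipped_ppi_edges") <- skipped
  if (skipped > 0L)
    warning(sprintf("%d PPI edge(s) referenced unknown genes and were skipped",
                    skipped))
  g
}

#' Load an analyzed experiment into the graph
#'
#' Creates one `EXPERIMENT` node, `WAS_SELECTED` edges to every selected
#' gene (properties `log2fc`, `fdr`, `direction`, `contrast`; for a gene
#' selected in several contrasts, the contrast with the smallest FDR is
#' recorded on the edge), `CLUSTER` nodes keyed by their `clustInfo`,
#' `WAS_CLUSTERIZED` edges, and `WAS_REPRESENTED` edges from each cluster
#' to its significantly enriched `BP` terms. Re-loading an experiment of
#' the same name replaces its prior subgraph, so the operation is
#' idempotent. Selected genes absent from the background are auto-created
#' with minimal properties and listed in the `reconciliation` attribute.
#'
#' @param g A graph holding background data.
#' @param experiment Named list with at least `name`; optional `design`,
#'   `platform`, `parameters`.
#' @param de A `de_result` data frame (or `NULL`).
#' @param clusters A named `cluster_assignment` (or `NULL`).
#' @param enrichment An `enrichment_result` (or `NULL`).
#' @return The graph, with attribute `reconciliation` (character vector of
#'   auto-created gene ids).
#' @export
load_experiment <- function(g, experiment, de = NULL, clusters = NULL,
                            enrichment = NULL) {
  name <- experiment$name
  if (is.null(name) || !nzchar(name))
    stop2("experiment needs a nonempty 'name'",
          class = "exprgraph_validation_error")
  exp_id <- paste0("EXPERIMENT:", name)

  # replace semantics: drop the prior experiment node and its clusters
  if (!is.null(g$nodes[[exp_id]])) {
    for (nd in pg_node_list(g)) {
      if (nd$label == "CLUSTER" &&
          identical(parse_clust_info(nd$props$clustInfo)$experiment, name))
        pg_remove_node(g, nd$id)
    }
    pg_remove_node(g, exp_id)
  }

  pg_add_node(g, exp_id, "EXPERIMENT",
              list(name = name,
                   design = experiment$design %||% "single-factor",
                   platform = experiment$platform %||% "unspecified",
                   parameters = paste(
                     names(experiment$parameters %||% list()),
                     unlist(experiment$parameters %||% list()),
                     sep = "=", collapse = ";")))
  missing_genes <- character()
  ensure_gene <- function(gene) {
    gid <- gene_node_id(gene)
    if (is.null(g$nodes[[gid]])) {
      missing_genes <<- c(missing_genes, gene)
      pg_add_node(g, gid, "GENE", list(entrez_id = as.character(gene),
                                       symbol = as.character(gene),
                                       description = ""))
    }
    gid
  }

  if (!is.null(de)) {
    sel <- de[de$selected, , drop = FALSE]
    if (nrow(sel)) {
      sel <- sel[order(sel$gene, sel$fdr, sel$contrast), , drop = FALSE]
      sel <- sel[!duplicated(sel$gene), , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        gid <- ensure_gene(sel$gene[i])
        pg_add_edge(g, exp_id, gid, "WAS_SELECTED",
                    list(log2fc = sel$log2fc[i], fdr = sel$fdr[i],
                         direction = sel$direction[i],
                         contrast = sel$contrast[i]))
      }
    }
  }

  if (!is.null(clusters)) {
    if (is.null(clusters$clust_info))
      clusters <- name_clusters(clusters, name)
    for (idx in names(clusters$clust_info)) {
      cid <- paste0("CLUSTER:", clusters$clust_info[[idx]])
      pg_add_node(g, cid, "CLUSTER",
                  list(clustInfo = clusters$clust_info[[idx]],
                       method = clusters$method, k = clusters$k))
    }
    for (gene in names(clusters$labels)) {
      gid <- ensure_gene(gene)
      info <- clusters$clust_info[[as.character(clusters$labels[[gene]])]]
      pg_add_edge(g, gid, paste0("CLUSTER:", info), "WAS_CLUSTERIZED")
    }
  }

  if (!is.null(enrichment) && nrow(enrichment)) {
    sig <- enrichment[enrichment$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      cid <- paste0("CLUSTER:", sig$cluster[i])
      if (is.null(g$nodes[[cid]])) next
      bid <- paste0("BP:", sig$term_id[i])
      pg_add_node(g, bid, "BP", list(term_id = sig$term_id[i],
                                     Term = sig$term_name[i]))
      pg_add_edge(g, cid, bid, "WAS_REPRESENTED",
                  list(p_value = sig$p_value[i], k = sig$k[i], K = sig$K[i]))
    }
  }

  attr(g, "reconciliation") <- unique(missing_genes)
  g
}
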
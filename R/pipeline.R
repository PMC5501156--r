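#' Assemble and validate a pipeline run configuration
#'
#' @param experiment_name Experiment label (used in graph node ids and
#'   `clustInfo` strings).
#' @param inputs Named list of input paths: `expression`, `phenodata`,
#'   `probe_map`, `annotation`, `ppi`, `term_map`.
#' @param output_dir Directory for all artifacts.
#' @param design Free-text overall-design note.
#' @param normalization Currently only `"rma-style"` (log2, quantile
#'   normalization, median-polish summarization). MAS5 is not supported.
#' @param fdr_threshold,abs_log2fc_threshold DE selection cuts.
#' @param platform_id,organism Metadata labels.
#' @param clustering_method `"pam"` or `"hierarchical"`.
#' @param clustering_k Number of clusters, or `NULL` for silhouette-based
#'   choice.
#' @param enrichment_alpha Raw-p significance cut for over-representation.
#' @param combined_score_threshold,hub_score_threshold Hub-query cuts.
#' @param moderate Use empirical-Bayes variance moderation.
#' @param seed Integer seed recorded in provenance.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(experiment_name, inputs, output_dir,
                       design = "single-factor",
                       normalization = "rma-style",
                       fdr_threshold = 0.05, abs_log2fc_threshold = 1,
                       platform_id = "synthetic",
                       organism = "Homo sapiens",
                       clustering_method = "pam", clustering_k = NULL,
                       enrichment_alpha = 0.001,
                       combined_score_threshold = 0.80,
                       hub_score_threshold = 50,
                       moderate = TRUE, seed = 1L) {
  if (!identical(normalization, "rma-style"))
    stop2("only 'rma-style' normalization is supported (MAS5 is not)",
          class = "exprgraph_validation_error")
  need <- c("expression", "phenodata", "probe_map", "annotation", "ppi",
            "term_map")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop2("config inputs missing: ", paste(miss, collapse = ", "),
          class = "exprgraph_validation_error")
  absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
  if (length(absent))
    stop2("input file(s) not found: ", paste(absent, collapse = ", "),
          class = "exprgraph_validation_error")
  structure(list(
    experiment_name = experiment_name, design = design,
    normalization = normalization,
    criteria = de_criteria(fdr_threshold, abs_log2fc_threshold),
    platform_id = platform_id, organism = organism,
    clustering_method = match.arg(clustering_method,
                                  c("pam", "hierarchical")),
    clustering_k = if (!is.null(clustering_k))
      assert_count(clustering_k, "clustering_k", min = 2L),
    enrichment_alpha = assert_number(enrichment_alpha, "enrichment_alpha",
                                     0, 1, strict_lower = TRUE),
    combined_score_threshold = assert_number(combined_score_threshold,
                                             "combined_score_threshold", 0, 1),
    hub_score_threshold = assert_number(hub_score_threshold,
                                        "hub_score_threshold", 0),
    moderate = isTRUE(moderate),
    inputs = inputs[need], output_dir = output_dir,
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()]; the `inputs`
#' block holds the six input paths (relative paths are resolved against
#' the YAML file's directory).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  y$inputs <- lapply(y$inputs, resolve)
  if (!is.null(y$output_dir)) y$output_dir <- resolve(y$output_dir)
  do.call(run_config, y)
}

#' Carry probe-set-level DE statistics to gene level
#'
#' After probe-set-level testing, the annotation step maps each gene to its
#' retained probe set (see [collapse_to_genes()]); the gene inherits that
#' probe set's statistics and selection flag.
#'
#' @param de A `de_result` keyed by probe-set ids.
#' @param collapsed The gene-level `SummarizedExperiment` from
#'   [collapse_to_genes()].
#' @return A `de_result` keyed by entrez gene ids, with symbols attached.
#' @export
annotate_de_result <- function(de, collapsed) {
  rd <- SummarizedExperiment::rowData(collapsed)
  map <- setNames(rownames(collapsed), rd$probeset_id)
  sym <- setNames(rd$symbol, rownames(collapsed))
  out <- de[de$gene %in% names(map), , drop = FALSE]
  out$gene <- unname(map[out$gene])
  out$symbol <- unname(sym[out$gene])
  rownames(out) <- NULL
  structure(out, class = class(de), criteria = attr(de, "criteria"),
            moderation = attr(de, "moderation"))
}

pipeline_stages <- c("normalization", "eset", "differential_expression",
                     "annotation", "clusterization", "functional_analysis")

#' Run the full analysis workflow
#'
#' Executes, in order: normalization (log2 + quantile + median polish with
#' probe-level QC), expression-set assembly, differential expression
#' (moderated t, BH-FDR, fold-change selection), probe-to-gene annotation,
#' clusterization of the selected genes, functional (over-representation)
#' analysis, and materialization of all results into the property graph.
#' Every artifact is written under `config$output_dir`, a provenance
#' derivation graph is exported alongside, and the graph summary is
#' printed.
#'
#' @param config A [run_config()].
#' @param dry_run Print the resolved stage plan and parameters without
#'   reading or writing anything.
#' @return Invisibly, a list with the in-memory results (`normalized`,
#'   `eset`, `de`, `clusters`, `enrichment`, `graph`, `provenance`,
#'   `paths`).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dry_run) {
    cat("pipeline plan (dry run):\n")
    for (s in c(pipeline_stages, "graph_load"))
      cat("  -", s, "\n")
    cat("parameters:\n")
    cat(sprintf("  fdr < %g, |log2FC| > %g, alpha = %g, combined score > %g, hub score > %g\n",
                config$criteria$fdr_threshold,
                config$criteria$abs_log2fc_threshold,
                config$enrichment_alpha, config$combined_score_threshold,
                config$hub_score_threshold))
    cat(sprintf("  clustering: %s, k = %s; moderation: %s; seed = %d\n",
                config$clustering_method,
                if (is.null(config$clustering_k)) "auto (silhouette)"
                else config$clustering_k,
                config$moderate, config$seed))
    return(invisible(NULL))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  rec <- provenance_recorder()
  set.seed(config$seed)

  # -- normalization --------------------------------------------------------
  raw <- read_expression_tsv(config$inputs$expression)
  probe_map <- read_tsv(config$inputs$probe_map)
  qn <- quantile_normalize(raw)
  normalized <- median_polish_summarize(qn, probe_map)
  qc <- qc_report(log2(raw))
  write_expression_tsv(normalized, p("normalized_matrix.tsv"),
                       id_col = "probeset_id")
  jsonlite::write_json(
    list(per_sample_quantiles = qc$per_sample_quantiles,
         spearman_correlation = qc$spearman_correlation,
         constant_samples = qc$constant_samples),
    p("qc_report.json"), digits = NA, matrix = "rowmajor")
  prov_record(rec, "normalization",
              params = list(method = config$normalization,
                            seed = config$seed),
              inputs = list(expression = config$inputs$expression,
                            probe_map = config$inputs$probe_map),
              outputs = list(normalized_matrix = p("normalized_matrix.tsv"),
                             qc_report = p("qc_report.json")))

  # -- e-set ----------------------------------------------------------------
  pheno <- read_tsv(config$inputs$phenodata)
  eset <- build_eset(normalized, pheno, config$platform_id, config$organism,
                     config$experiment_name)
  prov_record(rec, "eset",
              params = list(platform_id = config$platform_id,
                            organism = config$organism,
                            experiment_name = config$experiment_name),
              inputs = list(normalized_matrix = p("normalized_matrix.tsv"),
                            phenodata = config$inputs$phenodata),
              outputs = list(eset = list(dim(eset),
                                         S4Vectors::metadata(eset))))

  # -- differential expression (probe-set level) ----------------------------
  de_ps <- run_de(eset, config$criteria, moderate = config$moderate)
  prov_record(rec, "differential_expression",
              params = list(fdr_threshold = config$criteria$fdr_threshold,
                            abs_log2fc_threshold =
                              config$criteria$abs_log2fc_threshold,
                            moderate = config$moderate),
              inputs = list(eset = list(dim(eset))),
              outputs = list(de_probeset = de_ps))

  # -- annotation -----------------------------------------------------------
  annotation <- read_tsv(config$inputs$annotation)
  collapsed <- collapse_to_genes(eset, annotation)
  de <- annotate_de_result(de_ps, collapsed)
  write_expression_tsv(exprs_of(collapsed), p("collapsed_matrix.tsv"),
                       id_col = "entrez_id")
  write_tsv(de, p("de_table.tsv"))
  volcano <- data.frame(gene = de$gene, symbol = de$symbol,
                        contrast = de$contrast, log2fc = de$log2fc,
                        neg_log10_p = -log10(pmax(de$p_value, 1e-300)),
                        stringsAsFactors = FALSE)
  write_tsv(volcano, p("volcano.tsv"))
  prov_record(rec, "annotation",
              params = list(collapse_rule = "highest_mean_expression"),
              inputs = list(annotation = config$inputs$annotation,
                            de_probeset = de_ps),
              outputs = list(collapsed_matrix = p("collapsed_matrix.tsv"),
                             de_table = p("de_table.tsv"),
                             volcano = p("volcano.tsv")))

  # -- clusterization (DE-selected gene submatrix) --------------------------
  selection <- union_across_contrasts(de)
  clusters <- NULL
  if (length(selection$genes) >= 3L) {
    sub <- exprs_of(collapsed)[selection$genes, , drop = FALSE]
    clusters <- cluster_genes(sub, config$clustering_method,
                              config$clustering_k, config$experiment_name)
    write_tsv(cluster_table(clusters), p("clusters.tsv"))
    heat <- sub[order(clusters$labels[rownames(sub)]), , drop = FALSE]
    write_expression_tsv(heat, p("heatmap_data.tsv"), id_col = "entrez_id")
  } else {
    warning("fewer than 3 selected genes; clusterization skipped")
    write_tsv(data.frame(gene = character(), cluster = integer(),
                         clustInfo = character(), method = character(),
                         k = integer()), p("clusters.tsv"))
  }
  prov_record(rec, "clusterization",
              params = list(method = config$clustering_method,
                            k = clusters$k %||% NA,
                            dissimilarity = "1-pearson"),
              inputs = list(de_table = p("de_table.tsv"),
                            collapsed_matrix = p("collapsed_matrix.tsv")),
              outputs = list(clusters = p("clusters.tsv")))

  # -- functional analysis --------------------------------------------------
  term_map <- read_gmt(config$inputs$term_map)
  universe <- build_universe(rownames(collapsed))
  enrichment <- if (!is.null(clusters))
    enrich_clusters(clusters, term_map, universe,
                    alpha = config$enrichment_alpha)
  else NULL
  if (!is.null(enrichment)) write_tsv(enrichment, p("enrichment.tsv"))
  prov_record(rec, "functional_analysis",
              params = list(alpha = config$enrichment_alpha,
                            universe = universe$provenance,
                            universe_size = length(universe$genes)),
              inputs = list(term_map = config$inputs$term_map,
                            clusters = p("clusters.tsv")),
              outputs = list(enrichment = if (!is.null(enrichment))
                p("enrichment.tsv") else "skipped"))

  # -- graph materialization ------------------------------------------------
  ppi <- read_tsv(config$inputs$ppi)
  g <- load_background(annotation, ppi, config$organism)
  g <- load_experiment(
    g,
    list(name = config$experiment_name, design = config$design,
         platform = config$platform_id,
         parameters = list(fdr = config$criteria$fdr_threshold,
                           abs_log2fc = config$criteria$abs_log2fc_threshold,
                           alpha = config$enrichment_alpha,
                           seed = config$seed)),
    de = de, clusters = clusters, enrichment = enrichment)
  save_graph(g, p("graph.graphml"))
  save_graph(g, p("graph.json"))
  save_graph(g, p("graph.cql"))
  prov_record(rec, "graph_load",
              params = list(organism = config$organism),
              inputs = list(ppi = config$inputs$ppi,
                            de_table = p("de_table.tsv"),
                            clusters = p("clusters.tsv")),
              outputs = list(graphml = p("graph.graphml"),
                             json = p("graph.json"),
                             cypher = p("graph.cql")))
  export_provenance(rec, p("provenance.json"))

  s <- graph_summary(g)
  message(sprintf("graph: %d nodes, %d edges", s$n_nodes, s$n_edges))
  message("nodes by label: ",
          paste(names(s$nodes_by_label), s$nodes_by_label, sep = "=",
                collapse = ", "))
  message("edges by type: ",
          paste(names(s$edges_by_type), s$edges_by_type, sep = "=",
                collapse = ", "))

  invisible(list(normalized = normalized, qc = qc, eset = eset,
                 collapsed = collapsed, de = de, selection = selection,
                 clusters = clusters, enrichment = enrichment, graph = g,
                 provenance = rec,
                 paths = list(
                   normalized = p("normalized_matrix.tsv"),
                   qc = p("qc_report.json"),
                   collapsed = p("collapsed_matrix.tsv"),
                   de_table = p("de_table.tsv"),
                   volcano = p("volcano.tsv"),
                   clusters = p("clusters.tsv"),
                   enrichment = p("enrichment.tsv"),
                   graphml = p("graph.graphml"),
                   json = p("graph.json"),
                   cypher = p("graph.cql"),
                   provenance = p("provenance.json"))))
}
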
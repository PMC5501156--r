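mini_background <- function() {
  ann <- data.frame(probeset_id = paste0("PS", 1:3),
                    entrez_id = as.character(1:3),
                    symbol = c("GA", "GB", "GC"), description = "d")
  ppi <- data.frame(gene_a = c("1", "1", "2"), gene_b = c("2", "3", "3"),
                    neighborhood = 0.1, fusion = 0.1, cooccurrence = 0.1,
                    coexpression = 0.1, experiments = 0.1, databases = 0.1,
                    textmining = 0.1, combined_score = c(0.9, 0.7, 0.85))
  list(ann = ann, ppi = ppi)
}

test_that("schema violations raise typed errors and leave the graph intact", {
  g <- property_graph()
  pg_add_node(g, "GENE:1", "GENE", list(symbol = "GA"))
  pg_add_node(g, "ORGANISM:Hs", "ORGANISM")
  pg_add_node(g, "EXPERIMENT:E1", "EXPERIMENT")
  expect_error(pg_add_node(g, "X", "NOT_A_LABEL"),
               class = "exprgraph_schema_error")
  expect_error(pg_add_edge(g, "GENE:1", "EXPERIMENT:E1", "WAS_SELECTED"),
               class = "exprgraph_schema_error")   # wrong direction
  expect_error(pg_add_edge(g, "GENE:1", "GENE:1", "PPI_INTERACTION"),
               class = "exprgraph_schema_error")   # self loop
  expect_error(pg_add_edge(g, "GENE:1", "GENE:2", "PPI_INTERACTION"),
               class = "exprgraph_schema_error")   # missing endpoint
  expect_error(pg_add_edge(g, "GENE:1", "ORGANISM:Hs", "FRIENDS_WITH"),
               class = "exprgraph_schema_error")   # unknown type
  expect_error(pg_add_node(g, "GENE:1", "BP"),
               class = "exprgraph_schema_error")   # label change
  expect_equal(graph_summary(g)$n_edges, 0)
})

test_that("undirected PPI edges are stored once in canonical order", {
  g <- property_graph()
  pg_add_node(g, "GENE:b", "GENE"); pg_add_node(g, "GENE:a", "GENE")
  pg_add_edge(g, "GENE:b", "GENE:a", "PPI_INTERACTION",
              list(combined_score = 0.9))
  pg_add_edge(g, "GENE:a", "GENE:b", "PPI_INTERACTION",
              list(combined_score = 0.9))
  expect_equal(graph_summary(g)$n_edges, 1)
  e <- pg_edge_list(g)[[1]]
  expect_identical(c(e$from, e$to), c("GENE:a", "GENE:b"))
})

test_that("background loading creates gene/organism nodes and PPI edges", {
  bg <- mini_background()
  g <- load_background(bg$ann, bg$ppi, organism = "Hs")
  s <- graph_summary(g)
  expect_equal(unname(s$nodes_by_label["GENE"]), 3)
  expect_equal(unname(s$nodes_by_label["ORGANISM"]), 1)
  expect_equal(unname(s$edges_by_type["PPI_INTERACTION"]), 3)
  expect_equal(unname(s$edges_by_type["BELONGS_TO"]), 3)
  nd <- pg_get_node(g, "GENE:1")
  expect_identical(nd$props$symbol, "GA")
  # empty PPI -> gene nodes only
  g0 <- load_background(bg$ann, NULL, organism = "Hs")
  expect_equal(unname(graph_summary(g0)$edges_by_type["PPI_INTERACTION"]), 0)
  # duplicate (a,b)+(b,a) rows collapse to one undirected edge
  dup <- bg$ppi[c(1, 1), ]; dup[2, c("gene_a", "gene_b")] <- c("2", "1")
  g2 <- load_background(bg$ann, dup, organism = "Hs")
  expect_equal(unname(graph_summary(g2)$edges_by_type["PPI_INTERACTION"]), 1)
  # unknown genes are skipped and counted
  bad <- bg$ppi; bad$gene_a[1] <- "99"
  expect_warning(g3 <- load_background(bg$ann, bad, organism = "Hs"),
                 "skipped")
  expect_equal(attr(g3, "skipped_ppi_edges"), 1)
})

mini_results <- function() {
  de <- data.frame(gene = c("1", "2"), symbol = c("GA", "GB"),
                   contrast = "b-a", log2fc = c(2, -2), t = 5,
                   p_value = 1e-4, fdr = 1e-3, selected = TRUE,
                   direction = c("up", "down"))
  labels <- setNames(c(1L, 2L, 1L), c("1", "2", "3"))
  cl <- name_clusters(
    structure(list(labels = labels, method = "pam", k = 2L,
                   parameters = list(), sizes = table(labels),
                   clust_info = NULL, experiment = NULL),
              class = "cluster_assignment"), "E1")
  enr <- data.frame(cluster = c("pam:2:1@E1", "pam:2:2@E1"),
                    term_id = c("T1", "T2"),
                    term_name = c("term one", "term two"),
                    N = 3, K = 2, n = 2, k = 2, p_value = c(1e-5, 2e-5),
                    significant = TRUE)
  list(de = de, cl = cl, enr = enr)
}

mini_experiment_graph <- function() {
  bg <- mini_background()
  g <- load_background(bg$ann, bg$ppi, organism = "Hs")
  r <- mini_results()
  load_experiment(g, list(name = "E1", platform = "GPLX"),
                  r$de, r$cl, r$enr)
}

test_that("experiment loading builds the full result subgraph idempotently", {
  g <- mini_experiment_graph()
  s1 <- graph_summary(g)
  expect_equal(unname(s1$nodes_by_label[c("EXPERIMENT", "CLUSTER", "BP")]),
               c(1, 2, 2))
  expect_equal(unname(s1$edges_by_type["WAS_SELECTED"]), 2)
  expect_equal(unname(s1$edges_by_type["WAS_CLUSTERIZED"]), 3)
  expect_equal(unname(s1$edges_by_type["WAS_REPRESENTED"]), 2)
  sel <- Filter(function(e) e$type == "WAS_SELECTED", pg_edge_list(g))
  expect_setequal(vapply(sel, function(e) e$props$direction, character(1)),
                  c("up", "down"))
  # loading the identical experiment again leaves every count unchanged
  r <- mini_results()
  g <- load_experiment(g, list(name = "E1", platform = "GPLX"),
                       r$de, r$cl, r$enr)
  expect_equal(graph_summary(g), s1)
  # re-loading with different results replaces the prior subgraph
  de1 <- r$de[1, , drop = FALSE]
  g <- load_experiment(g, list(name = "E1"), de1, NULL, NULL)
  expect_equal(unname(graph_summary(g)$edges_by_type["WAS_SELECTED"]), 1)
  expect_equal(unname(graph_summary(g)$nodes_by_label["CLUSTER"]), 0)
})

test_that("selected genes missing from the background are reconciled", {
  bg <- mini_background()
  g <- load_background(bg$ann, NULL, organism = "Hs")
  de <- data.frame(gene = "42", symbol = "GX", contrast = "b-a",
                   log2fc = 3, t = 9, p_value = 1e-6, fdr = 1e-5,
                   selected = TRUE, direction = "up")
  g <- load_experiment(g, list(name = "E1"), de, NULL, NULL)
  expect_identical(attr(g, "reconciliation"), "42")
  expect_false(is.null(pg_get_node(g, "GENE:42")))
})

test_that("zero selected genes still yields an EXPERIMENT node", {
  bg <- mini_background()
  g <- load_background(bg$ann, NULL, organism = "Hs")
  de <- data.frame(gene = character(), symbol = character(),
                   contrast = character(), log2fc = numeric(),
                   t = numeric(), p_value = numeric(), fdr = numeric(),
                   selected = logical(), direction = character())
  g <- load_experiment(g, list(name = "E1"), de, NULL, NULL)
  s <- graph_summary(g)
  expect_equal(unname(s$nodes_by_label["EXPERIMENT"]), 1)
  expect_equal(unname(s$edges_by_type["WAS_SELECTED"]), 0)
})

test_that("referential integrity holds after node removal", {
  g <- mini_experiment_graph()
  pg_remove_node(g, "GENE:1")
  ids <- vapply(pg_node_list(g), `[[`, character(1), "id")
  for (e in pg_edge_list(g)) {
    expect_true(e$from %in% ids)
    expect_true(e$to %in% ids)
  }
})

test_that("GraphML and JSON round-trips are lossless; cypher counts CREATEs", {
  g <- mini_experiment_graph()
  for (ext in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_graph(g, path)
    expect_true(graph_equal(g, load_graph(path)), info = ext)
  }
  # empty graph round-trips too
  for (ext in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_graph(property_graph(), path)
    expect_equal(graph_summary(load_graph(path))$n_nodes, 0, info = ext)
  }
  # cypher: one CREATE per node and per relationship
  g2 <- property_graph()
  pg_add_node(g2, "GENE:1", "GENE", list(symbol = "GA"))
  pg_add_node(g2, "EXPERIMENT:E1", "EXPERIMENT", list(name = "E1"))
  pg_add_edge(g2, "EXPERIMENT:E1", "GENE:1", "WAS_SELECTED",
              list(log2fc = 2.5))
  cql <- tempfile(fileext = ".cql")
  save_graph(g2, cql)
  lines <- readLines(cql)
  expect_equal(sum(grepl("CREATE", lines)), 3)
  expect_equal(sum(grepl("^CREATE \\(:", lines)), 2)
  expect_error(load_graph(cql), "write-only",
               class = "exprgraph_validation_error")
  expect_error(save_graph(g2, "x.foo"), class = "exprgraph_validation_error")
  # numeric precision survives the graphml round-trip
  path <- tempfile(fileext = ".graphml")
  pg_add_node(g2, "GENE:2", "GENE", list(weight = 1 / 3))
  save_graph(g2, path)
  back <- load_graph(path)
  expect_equal(pg_get_node(back, "GENE:2")$props$weight, 1 / 3,
               tolerance = 1e-15)
})

test_that("malformed files produce informative errors", {
  bad <- tempfile(fileext = ".graphml")
  writeLines("<graphml><graph><node id='x'/></graph></graphml>", bad)
  expect_error(load_graph(bad), class = "exprgraph_io_error")
  badj <- tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "a"}], "edges": []}', badj)
  expect_error(load_graph(badj), class = "exprgraph_io_error")
})
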
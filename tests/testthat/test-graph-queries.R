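test_that("schema summary reports each realized triple once", {
  expect_equal(nrow(schema_summary(property_graph())), 0)
  bg <- data.frame(probeset_id = paste0("PS", 1:3),
                   entrez_id = as.character(1:3),
                   symbol = paste0("G", 1:3), description = "d")
  ppi <- data.frame(gene_a = "1", gene_b = "2", combined_score = 0.9)
  g <- load_background(bg, ppi, organism = "Hs")
  tr <- schema_summary(g)
  expect_equal(paste(tr$from, tr$type, tr$to),
               c("GENE BELONGS_TO ORGANISM", "GENE PPI_INTERACTION GENE"))
})

test_that("degree counts adjacent edges and satisfies the handshake lemma", {
  g <- property_graph()
  for (i in 1:4) pg_add_node(g, paste0("GENE:", i), "GENE")
  pg_add_edge(g, "GENE:1", "GENE:2", "PPI_INTERACTION")
  pg_add_edge(g, "GENE:2", "GENE:3", "PPI_INTERACTION")
  pg_add_edge(g, "GENE:3", "GENE:1", "PPI_INTERACTION")
  deg <- degree(g, "PPI_INTERACTION")
  expect_equal(unname(deg[paste0("GENE:", 1:3)]), c(2L, 2L, 2L))
  expect_equal(unname(deg[["GENE:4"]]), 0L)   # isolated node
  expect_equal(sum(deg), 2 * 3)
  expect_error(degree(g, "NOPE"), class = "exprgraph_schema_error")
})

test_that("hub ranking follows the full path pattern on a hand-built graph", {
  g <- property_graph()
  syms <- c("CDK1", "SRC", "AAA", "BBB", "CCC")
  for (i in 1:5)
    pg_add_node(g, paste0("GENE:", i), "GENE",
                list(entrez_id = as.character(i), symbol = syms[i]))
  pg_add_node(g, "EXPERIMENT:E1", "EXPERIMENT", list(name = "E1"))
  pg_add_node(g, "CLUSTER:pam:2:1@E1", "CLUSTER",
              list(clustInfo = "pam:2:1@E1"))
  pg_add_node(g, "BP:T1", "BP", list(term_id = "T1", Term = "mitosis"))
  pg_add_edge(g, "CLUSTER:pam:2:1@E1", "BP:T1", "WAS_REPRESENTED")
  # DE genes: 1 (CDK1) and 2 (SRC)
  pg_add_edge(g, "EXPERIMENT:E1", "GENE:1", "WAS_SELECTED")
  pg_add_edge(g, "EXPERIMENT:E1", "GENE:2", "WAS_SELECTED")
  # partners 3,4,5 clusterized; 5's edge scores below threshold
  for (i in 3:5)
    pg_add_edge(g, paste0("GENE:", i), "CLUSTER:pam:2:1@E1",
                "WAS_CLUSTERIZED")
  pg_add_edge(g, "GENE:1", "GENE:3", "PPI_INTERACTION",
              list(combined_score = 0.95))
  pg_add_edge(g, "GENE:1", "GENE:4", "PPI_INTERACTION",
              list(combined_score = 0.85))
  pg_add_edge(g, "GENE:1", "GENE:5", "PPI_INTERACTION",
              list(combined_score = 0.5))
  pg_add_edge(g, "GENE:2", "GENE:4", "PPI_INTERACTION",
              list(combined_score = 0.99))
  # a qualifying partner of nobody: 2-5 edge exactly at threshold (strict >)
  pg_add_edge(g, "GENE:2", "GENE:5", "PPI_INTERACTION",
              list(combined_score = 0.80))
  r <- hub_candidates(g, 0.80, top_n = 10)
  expect_equal(r$symbol, c("CDK1", "SRC"))
  expect_equal(r$score, c(2L, 1L))
  expect_setequal(r$partners[[1]], c("AAA", "BBB"))
  expect_identical(r$bp_terms[[1]], "mitosis")
  # no PPI edges above a high threshold -> all scores 0
  r0 <- hub_candidates(g, 0.999, top_n = 10)
  expect_true(all(r0$score == 0))
})

test_that("queries equal brute-force pattern matchers on random graphs", {
  for (seed in 1:6) {
    g <- random_pgraph(seed, n_genes = 35,
                       n_experiments = 1 + seed %% 2)
    tr <- schema_summary(g)
    expect_identical(paste(tr$from, tr$type, tr$to),
                     oracle_schema_triples(g))
    deg <- degree(g, "PPI_INTERACTION")
    odeg <- oracle_degree(g, "PPI_INTERACTION")
    for (nm in names(odeg)) expect_equal(deg[[nm]], odeg[[nm]])
    expect_equal(sum(deg),
                 2 * sum(vapply(pg_edge_list(g), function(e)
                   e$type == "PPI_INTERACTION", logical(1))))
    r <- hub_candidates(g, 0.80, top_n = Inf)
    oh <- oracle_hub_scores(g, 0.80)
    expect_setequal(r$gene, names(oh))
    for (gid in names(oh)) expect_equal(r$score[r$gene == gid],
                                        unname(oh[gid]), info = gid)
    expect_true(all(diff(r$score) <= 0))
    gid <- names(oh)[[1]]
    oc <- oracle_coexpr(g, gid)
    co <- coexpressed_with(g, pg_get_node(g, gid)$props$symbol)
    expect_equal(nrow(co), length(oc))
    for (h in names(oc))
      expect_equal(co$score[co$symbol == pg_get_node(g, h)$props$symbol],
                   unname(oc[h]))
  }
})

test_that("hub materialization is strict, idempotent, and can be a no-op", {
  g <- random_pgraph(3, n_genes = 30)
  r <- hub_candidates(g, 0.80, top_n = Inf)
  thr <- if (nrow(r)) max(r$score) else 0
  # threshold above the max score -> graph unchanged
  before <- graph_summary(g)
  expect_message(create_hub(g, score_threshold = thr + 1), "no gene")
  expect_equal(graph_summary(g), before)
  # threshold 0 -> every gene with score > 0 linked to one HUB node
  create_hub(g, score_threshold = 0)
  s <- graph_summary(g)
  n_qual <- sum(r$score > 0)
  if (n_qual > 0) {
    expect_equal(unname(s$nodes_by_label["HUB"]), 1)
    expect_equal(unname(s$edges_by_type["AS_HUBS"]), n_qual)
    # idempotent
    create_hub(g, score_threshold = 0)
    expect_equal(graph_summary(g), s)
  }
})

test_that("co-expression lookup errors on unknown symbols with near matches", {
  g <- random_pgraph(5, n_genes = 10)
  expect_error(coexpressed_with(g, "S00"), "near matches",
               class = "exprgraph_validation_error")
  # a gene alone in its cluster has no co-expressed partners
  g2 <- property_graph()
  pg_add_node(g2, "GENE:1", "GENE", list(symbol = "LONER"))
  pg_add_node(g2, "CLUSTER:pam:2:1@E1", "CLUSTER",
              list(clustInfo = "pam:2:1@E1"))
  pg_add_edge(g2, "GENE:1", "CLUSTER:pam:2:1@E1", "WAS_CLUSTERIZED")
  expect_equal(nrow(coexpressed_with(g2, "LONER")), 0)
})

test_that("sharing clusters in two experiments gives a co-expression score of 2", {
  g <- property_graph()
  pg_add_node(g, "GENE:1", "GENE", list(symbol = "GA"))
  pg_add_node(g, "GENE:2", "GENE", list(symbol = "GB"))
  for (e in c("E1", "E2")) {
    cid <- sprintf("CLUSTER:pam:2:1@%s", e)
    pg_add_node(g, cid, "CLUSTER", list(clustInfo = sub("CLUSTER:", "", cid)))
    pg_add_edge(g, "GENE:1", cid, "WAS_CLUSTERIZED")
    pg_add_edge(g, "GENE:2", cid, "WAS_CLUSTERIZED")
  }
  co <- coexpressed_with(g, "GA")
  expect_equal(co$score, 2L)
  expect_setequal(co$clusters[[1]], c("pam:2:1@E1", "pam:2:1@E2"))
})
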
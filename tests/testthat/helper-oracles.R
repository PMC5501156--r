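# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (loops, enumeration, log-combinatorics) and
# share no code with the implementation paths they verify.

oracle_hyper_upper <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(exp(lchoose(K, k:hi) + lchoose(N - K, n - (k:hi)) - lchoose(N, n)))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook Tukey median polish, rows-first sweeps
oracle_medpolish <- function(x, maxiter = 10L, eps = 0.01) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  r <- x
  oldsum <- 0
  for (iter in seq_len(maxiter)) {
    rmed <- apply(r, 1, median)
    r <- sweep(r, 1, rmed)
    row_eff <- row_eff + rmed
    delta <- median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cmed <- apply(r, 2, median)
    r <- sweep(r, 2, cmed)
    col_eff <- col_eff + cmed
    delta <- median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(r))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_pam_best <- function(d, k) {
  n <- nrow(d)
  min(apply(combn(n, k), 2, function(med)
    sum(apply(d[, med, drop = FALSE], 1, min))))
}

rand_dissim_profiles <- function(n, seed) {
  set.seed(seed)
  prof <- matrix(rnorm(n * 20), n,
                 dimnames = list(paste0("g", seq_len(n)), NULL))
  pearson_dissimilarity(prof)
}

tiny_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 60, n_probes_per_gene = 3,
               groups = c(control = 4, tumor = 4), n_de_genes = 12,
               de_log2fc = 2, noise_sd = 0.4, n_terms = 12,
               genes_per_term = 10, ppi_edge_prob = 0.15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

# the bundled end-to-end fixture: small enough for fast runs, dense enough
# that hub/enrichment structure exists
fixture_spec <- function(seed = 11) {
  simulation_spec(n_genes = 300, n_probes_per_gene = 3,
                  groups = c(control = 5, tumor = 5), n_de_genes = 40,
                  de_log2fc = 2, noise_sd = 0.5, n_terms = 30,
                  genes_per_term = 15, ppi_edge_prob = 0.15, seed = seed)
}

# random schema-valid property graph + naive pattern-matching oracles -------

random_pgraph <- function(seed, n_genes = 40, n_experiments = 1) {
  set.seed(seed)
  g <- property_graph()
  org <- "ORGANISM:Test"
  pg_add_node(g, org, "ORGANISM", list(name = "Test"))
  genes <- paste0("GENE:", seq_len(n_genes))
  for (i in seq_len(n_genes)) {
    pg_add_node(g, genes[i], "GENE",
                list(entrez_id = as.character(i),
                     symbol = sprintf("S%03d", i), description = "x"))
    pg_add_edge(g, genes[i], org, "BELONGS_TO")
  }
  pairs <- combn(genes, 2)
  keep <- which(runif(ncol(pairs)) < 0.12)
  for (j in keep)
    pg_add_edge(g, pairs[1, j], pairs[2, j], "PPI_INTERACTION",
                list(combined_score = runif(1, 0.4, 1)))
  for (e in seq_len(n_experiments)) {
    exp_id <- paste0("EXPERIMENT:E", e)
    pg_add_node(g, exp_id, "EXPERIMENT", list(name = paste0("E", e)))
    de <- sample(genes, max(3, rbinom(1, n_genes, 0.35)))
    for (gid in de)
      pg_add_edge(g, exp_id, gid, "WAS_SELECTED",
                  list(log2fc = rnorm(1), fdr = runif(1, 0, 0.05),
                       direction = sample(c("up", "down"), 1)))
    n_cl <- sample(2:4, 1)
    cl_ids <- sprintf("CLUSTER:pam:%d:%d@E%d", n_cl, seq_len(n_cl), e)
    for (ci in seq_len(n_cl))
      pg_add_node(g, cl_ids[ci], "CLUSTER",
                  list(clustInfo = sub("^CLUSTER:", "", cl_ids[ci]),
                       method = "pam", k = n_cl))
    clustered <- sample(genes, max(4, rbinom(1, n_genes, 0.5)))
    for (gid in clustered)
      pg_add_edge(g, gid, sample(cl_ids, 1), "WAS_CLUSTERIZED")
    for (ci in seq_len(n_cl)) {
      if (runif(1) < 0.7) {
        bid <- sprintf("BP:T%d_%d", e, ci)
        pg_add_node(g, bid, "BP",
                    list(term_id = sub("^BP:", "", bid),
                         Term = paste("process", e, ci)))
        pg_add_edge(g, cl_ids[ci], bid, "WAS_REPRESENTED",
                    list(p_value = runif(1, 0, 0.001)))
      }
    }
  }
  g
}

oracle_schema_triples <- function(g) {
  e <- pg_edge_list(g)
  if (!length(e)) return(character())
  sort(unique(vapply(e, function(x)
    paste(pg_get_node(g, x$from)$label, x$type,
          pg_get_node(g, x$to)$label), character(1))))
}

oracle_degree <- function(g, type) {
  deg <- integer()
  for (e in pg_edge_list(g)) {
    if (e$type != type) next
    deg[e$from] <- (if (is.na(deg[e$from])) 0L else deg[e$from]) + 1L
    deg[e$to] <- (if (is.na(deg[e$to])) 0L else deg[e$to]) + 1L
  }
  deg
}

oracle_hub_scores <- function(g, threshold = 0.80) {
  edges <- pg_edge_list(g)
  de <- unique(unlist(lapply(edges, function(e)
    if (e$type == "WAS_SELECTED") e$to)))
  scores <- integer()
  for (gid in de) {
    partners <- character()
    for (e in edges) {
      if (e$type != "PPI_INTERACTION") next
      cs <- e$props$combined_score
      if (is.null(cs) || cs <= threshold) next
      h <- if (e$from == gid) e$to else if (e$to == gid) e$from else next
      # partner must be in a BP-represented cluster
      ok <- FALSE
      for (e2 in edges) {
        if (e2$type != "WAS_CLUSTERIZED" || e2$from != h) next
        for (e3 in edges)
          if (e3$type == "WAS_REPRESENTED" && e3$from == e2$to) ok <- TRUE
      }
      if (ok) partners <- c(partners, h)
    }
    scores[gid] <- length(unique(partners))
  }
  scores
}

oracle_coexpr <- function(g, gid) {
  edges <- pg_edge_list(g)
  my_clusters <- unlist(lapply(edges, function(e)
    if (e$type == "WAS_CLUSTERIZED" && e$from == gid) e$to))
  counts <- list()
  for (cl in my_clusters)
    for (e in edges)
      if (e$type == "WAS_CLUSTERIZED" && e$to == cl && e$from != gid)
        counts[[e$from]] <- unique(c(counts[[e$from]], cl))
  vapply(counts, length, integer(1))
}
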
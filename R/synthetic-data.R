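#' Specify a synthetic microarray experiment
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. The generator emulates a single-factor Affymetrix-style study:
#' per-gene log2 baselines, an additive group effect for a designated set of
#' differentially expressed (DE) genes in the second group, additive probe
#' affinities, and i.i.d. Gaussian noise in log2 space; intensities are
#' exponentiated so the probe-level matrix is strictly positive, matching
#' the log-normal convention of microarray raw data.
#'
#' @param n_genes Number of genes (one probe set per gene).
#' @param n_probes_per_gene Probes per probe set.
#' @param groups Named integer vector of samples per group, e.g.
#'   `c(control = 10, tumor = 10)`. DE genes receive their effect in the
#'   second group.
#' @param n_de_genes Number of genes carrying a true effect.
#' @param de_log2fc Absolute true log2 fold-change of DE genes (sign is
#'   randomized per gene).
#' @param noise_sd Standard deviation of log2-scale noise per probe/sample.
#' @param n_terms Number of gene-set terms to simulate.
#' @param genes_per_term Members per term.
#' @param ppi_edge_prob Bernoulli probability of a PPI edge per gene pair.
#' @param seed Integer seed; all outputs are deterministic given the spec.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000, n_probes_per_gene = 4,
                            groups = c(control = 10, tumor = 10),
                            n_de_genes = 100, de_log2fc = 2,
                            noise_sd = 0.5, n_terms = 50,
                            genes_per_term = 20, ppi_edge_prob = 0.01,
                            seed = 1L) {
  spec <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    n_probes_per_gene = assert_count(n_probes_per_gene, "n_probes_per_gene"),
    groups = groups,
    n_de_genes = assert_count(n_de_genes, "n_de_genes", min = 0L),
    de_log2fc = assert_number(de_log2fc, "de_log2fc", lower = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", lower = 0,
                             strict_lower = TRUE),
    n_terms = assert_count(n_terms, "n_terms", min = 0L),
    genes_per_term = assert_count(genes_per_term, "genes_per_term"),
    ppi_edge_prob = assert_number(ppi_edge_prob, "ppi_edge_prob", 0, 1),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (is.null(names(groups)) || any(!nzchar(names(groups))) ||
      anyDuplicated(names(groups)))
    stop2("'groups' must be a named vector with unique non-empty labels",
          class = "exprgraph_validation_error")
  if (length(groups) < 1L || any(groups < 1) || any(groups != round(groups)))
    stop2("'groups' must contain positive integer sample counts",
          class = "exprgraph_validation_error")
  if (spec$n_de_genes > spec$n_genes)
    stop2("'n_de_genes' must not exceed 'n_genes'",
          class = "exprgraph_validation_error")
  if (spec$genes_per_term > spec$n_genes)
    stop2("'genes_per_term' must not exceed 'n_genes'",
          class = "exprgraph_validation_error")
  spec$groups <- setNames(as.integer(groups), names(groups))
  structure(spec, class = "simulation_spec")
}

sim_gene_ids <- function(n) as.character(1000L + seq_len(n))
sim_symbols <- function(n) sprintf("G%04d", seq_len(n))
sim_probeset_ids <- function(n) sprintf("PS%04d_at", seq_len(n))

#' Simulate a probe-level expression experiment with known ground truth
#'
#' Generates the probe intensity matrix, phenodata (columns `SETS` and
#' `SAMPLE_NAME`), probe-to-probe-set map, probe-set-to-gene annotation, and
#' the ground truth (which genes are DE and their true log2 fold-changes).
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `probe_matrix` (linear-scale intensities,
#'   probes x samples), `phenodata`, `probe_map` (probe_id, probeset_id),
#'   `annotation` (probeset_id, entrez_id, symbol, description) and
#'   `ground_truth` (list: `de_gene_ids`, `true_log2fc`).
#' @export
simulate_experiment <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop2("'spec' must be a simulation_spec", class = "exprgraph_validation_error")
  withr::with_seed(spec$seed, {
    n_g <- spec$n_genes
    n_p <- spec$n_probes_per_gene
    genes <- sim_gene_ids(n_g)
    probesets <- sim_probeset_ids(n_g)
    probes <- as.vector(t(outer(probesets, seq_len(n_p),
                                function(ps, i) sprintf("%s_p%d", ps, i))))
    group_of <- rep(names(spec$groups), spec$groups)
    samples <- sprintf("%s_%02d", group_of,
                       unlist(lapply(spec$groups, seq_len), use.names = FALSE))
    n_s <- length(samples)

    de_idx <- if (spec$n_de_genes > 0) sort(sample.int(n_g, spec$n_de_genes))
              else integer()
    sign <- rep(0, n_g)
    if (length(de_idx))
      sign[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    true_lfc <- sign * spec$de_log2fc

    baseline <- rnorm(n_g, mean = 8, sd = 1.5)
    probe_eff <- rnorm(n_g * n_p, mean = 0, sd = 0.4)
    second_group <- names(spec$groups)[min(2L, length(spec$groups))]
    effect_s <- as.numeric(group_of == second_group)

    # log2 signal[probe, sample] = baseline(gene) + probe affinity +
    #   true_lfc(gene) * 1[sample in second group] + noise
    gene_of_probe <- rep(seq_len(n_g), each = n_p)
    log2sig <- outer(baseline[gene_of_probe] + probe_eff, rep(0, n_s), `+`) +
      outer(true_lfc[gene_of_probe], effect_s) +
      matrix(rnorm(n_g * n_p * n_s, sd = spec$noise_sd),
             nrow = n_g * n_p, ncol = n_s)
    probe_matrix <- 2 ^ log2sig
    dimnames(probe_matrix) <- list(probes, samples)

    phenodata <- data.frame(SETS = group_of, SAMPLE_NAME = samples,
                            stringsAsFactors = FALSE)
    probe_map <- data.frame(probe_id = probes,
                            probeset_id = probesets[gene_of_probe],
                            stringsAsFactors = FALSE)
    annotation <- data.frame(
      probeset_id = probesets, entrez_id = genes, symbol = sim_symbols(n_g),
      description = sprintf("synthetic gene %s", sim_symbols(n_g)),
      stringsAsFactors = FALSE)

    list(
      probe_matrix = probe_matrix,
      phenodata = phenodata,
      probe_map = probe_map,
      annotation = annotation,
      ground_truth = list(
        de_gene_ids = genes[de_idx],
        true_log2fc = setNames(true_lfc, genes)
      )
    )
  })
}

#' Simulate a STRING-style protein-protein interaction table
#'
#' Draws an Erdos-Renyi edge set over the given genes. Each edge carries the
#' seven STRING evidence channels (uniform on `[0,1]`) and a combined score
#' drawn uniform on `[0.5, 1]`, so the conventional 0.80 confidence
#' threshold splits edges non-trivially.
#'
#' @param gene_ids Character vector of at least two gene identifiers.
#' @param edge_prob Per-pair edge probability.
#' @param seed Integer seed.
#' @return A data frame with columns `gene_a`, `gene_b`, the seven channel
#'   scores and `combined_score`; undirected simple edges with
#'   `gene_a < gene_b`.
#' @export
simulate_ppi <- function(gene_ids, edge_prob, seed = 1L) {
  gene_ids <- as.character(gene_ids)
  if (length(unique(gene_ids)) < 2L)
    stop2("need at least 2 distinct genes to simulate a PPI network",
          class = "exprgraph_validation_error")
  assert_number(edge_prob, "edge_prob", 0, 1)
  channels <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
                "experiments", "databases", "textmining")
  withr::with_seed(seed, {
    pairs <- combn(sort(unique(gene_ids)), 2L)
    keep <- runif(ncol(pairs)) < edge_prob
    a <- pairs[1L, keep]
    b <- pairs[2L, keep]
    tab <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    for (ch in channels) tab[[ch]] <- runif(length(a))
    tab$combined_score <- runif(length(a), min = 0.5, max = 1)
    tab
  })
}

#' Simulate a term-to-gene mapping with designated enriched terms
#'
#' Terms are sampled uniformly from the gene universe, except a designated
#' set of "enriched" terms that draw 80% of their members from the DE genes
#' of a ground truth, so downstream hypergeometric tests have known
#' positives.
#'
#' @param gene_ids Character vector of gene identifiers (the universe).
#' @param n_terms Number of terms.
#' @param genes_per_term Members per term (at most `length(gene_ids)`).
#' @param ground_truth Ground-truth list from [simulate_experiment()] (uses
#'   `de_gene_ids`), or `NULL` for no enriched terms.
#' @param n_enriched Number of enriched terms; defaults to 10% of
#'   `n_terms` (at least 1) when DE genes are available, 0 otherwise.
#' @param seed Integer seed.
#' @return Named list of member-gene character vectors, with attributes
#'   `term_names` (descriptions) and `enriched` (ids of designed-enriched
#'   terms). Writable with [write_gmt()].
#' @export
simulate_term_map <- function(gene_ids, n_terms, genes_per_term,
                              ground_truth = NULL, n_enriched = NULL,
                              seed = 1L) {
  gene_ids <- unique(as.character(gene_ids))
  n_terms <- assert_count(n_terms, "n_terms", min = 0L)
  genes_per_term <- assert_count(genes_per_term, "genes_per_term")
  if (genes_per_term > length(gene_ids))
    stop2("'genes_per_term' exceeds the number of genes",
          class = "exprgraph_validation_error")
  de <- intersect(as.character(ground_truth$de_gene_ids %||% character()),
                  gene_ids)
  if (is.null(n_enriched))
    n_enriched <- if (length(de)) max(1L, round(0.1 * n_terms)) else 0L
  n_enriched <- min(assert_count(n_enriched, "n_enriched", min = 0L), n_terms)
  if (!length(de)) n_enriched <- 0L

  withr::with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    enriched <- ids[seq_len(n_enriched)]
    sets <- lapply(seq_len(n_terms), function(i) {
      if (i <= n_enriched) {
        n_from_de <- min(length(de), ceiling(0.8 * genes_per_term))
        from_de <- sample(de, n_from_de)
        rest <- sample(setdiff(gene_ids, from_de),
                       genes_per_term - n_from_de)
        sort(c(from_de, rest))
      } else {
        sort(sample(gene_ids, genes_per_term))
      }
    })
    names(sets) <- ids
    attr(sets, "term_names") <- setNames(
      sprintf("synthetic biological process %s", ids), ids)
    attr(sets, "enriched") <- enriched
    sets
  })
}

#' Generate and optionally write every input of the analysis workflow
#'
#' Convenience wrapper chaining [simulate_experiment()], [simulate_ppi()]
#' and [simulate_term_map()] under sub-seeds derived from `spec$seed`, and
#' writing all tables in their on-disk formats when `dir` is given.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return A list with all of [simulate_experiment()]'s elements plus
#'   `ppi`, `term_map`, and (when written) `paths`.
#' @export
simulate_inputs <- function(spec, dir = NULL) {
  exper <- simulate_experiment(spec)
  genes <- exper$annotation$entrez_id
  ppi <- simulate_ppi(genes, spec$ppi_edge_prob, seed = spec$seed + 1L)
  term_map <- simulate_term_map(genes, spec$n_terms, spec$genes_per_term,
                                exper$ground_truth, seed = spec$seed + 2L)
  exper$ground_truth$term_memberships <- term_map
  exper$ground_truth$ppi_edges <- ppi
  out <- c(exper, list(ppi = ppi, term_map = term_map))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      expression = file.path(dir, "expression.tsv"),
      phenodata = file.path(dir, "phenodata.tsv"),
      probe_map = file.path(dir, "probe_map.tsv"),
      annotation = file.path(dir, "annotation.tsv"),
      ppi = file.path(dir, "ppi.tsv"),
      term_map = file.path(dir, "terms.gmt")
    )
    write_expression_tsv(out$probe_matrix, paths$expression,
                         id_col = "probe_id")
    write_tsv(out$phenodata, paths$phenodata)
    write_tsv(out$probe_map, paths$probe_map)
    write_tsv(out$annotation, paths$annotation)
    write_tsv(out$ppi, paths$ppi)
    write_gmt(out$term_map, paths$term_map)
    out$paths <- paths
  }
  out
}
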
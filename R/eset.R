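#' Validate a phenodata table
#'
#' Phenodata must carry a `SETS` column (experimental group labels) and a
#' `SAMPLE_NAME` column naming the matrix columns; any extra columns are
#' preserved as sample metadata.
#'
#' @param pheno Data frame.
#' @param sample_ids Optional matrix column names to cross-check against.
#' @return `pheno`, invisibly, after validation.
#' @export
validate_phenodata <- function(pheno, sample_ids = NULL) {
  miss <- setdiff(c("SETS", "SAMPLE_NAME"), names(pheno))
  if (length(miss))
    stop2("phenodata is missing required column(s): ",
          paste(miss, collapse = ", "), class = "exprgraph_validation_error")
  if (anyDuplicated(pheno$SAMPLE_NAME))
    stop2("duplicate SAMPLE_NAME in phenodata: ",
          paste(unique(pheno$SAMPLE_NAME[duplicated(pheno$SAMPLE_NAME)]),
                collapse = ", "),
          class = "exprgraph_validation_error")
  if (!is.null(sample_ids)) {
    absent <- setdiff(pheno$SAMPLE_NAME, sample_ids)
    if (length(absent))
      stop2("SAMPLE_NAME(s) not found among matrix columns: ",
            paste(absent, collapse = ", "),
            class = "exprgraph_validation_error")
  }
  invisible(pheno)
}

#' Assemble an expression set
#'
#' Binds a log2 expression matrix to its sample-design table and experiment
#' metadata in a [SummarizedExperiment::SummarizedExperiment] (the field's
#' standard container). Matrix columns are reordered to phenodata row
#' order.
#'
#' @param normalized Log2 expression matrix (features x samples) such as the
#'   output of [median_polish_summarize()].
#' @param pheno Phenodata table; see [validate_phenodata()].
#' @param platform_id,organism,experiment_name Experiment metadata labels.
#' @return A `SummarizedExperiment` with assay `exprs` and metadata entries
#'   `platform_id`, `organism`, `experiment_name`, and `method_tag`.
#' @export
build_eset <- function(normalized, pheno, platform_id = "synthetic",
                       organism = "Homo sapiens",
                       experiment_name = "experiment") {
  validate_phenodata(pheno, colnames(normalized))
  expr <- normalized[, pheno$SAMPLE_NAME, drop = FALSE]
  cd <- S4Vectors::DataFrame(pheno, row.names = pheno$SAMPLE_NAME)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr), colData = cd)
  S4Vectors::metadata(se) <- list(
    platform_id = platform_id, organism = organism,
    experiment_name = experiment_name,
    method_tag = attr(normalized, "method_tag") %||% "unspecified")
  se
}

#' Expression matrix of an expression set
#' @param eset A `SummarizedExperiment` built by [build_eset()].
#' @return The log2 expression matrix.
#' @export
exprs_of <- function(eset) SummarizedExperiment::assay(eset, "exprs")

#' Collapse probe sets to genes
#'
#' Maps probe-set rows to genes using an annotation table. When several
#' probe sets map to the same gene, the probe set with the highest mean
#' expression across samples is retained (ties broken by lexicographic
#' probe-set id); unannotated probe sets are dropped and counted. Expression
#' values are never altered, only selected.
#'
#' @param eset `SummarizedExperiment` with probe-set rows.
#' @param annotation Data frame with columns `probeset_id`, `entrez_id`,
#'   `symbol`, `description`.
#' @return A `SummarizedExperiment` with one row per gene (rownames =
#'   entrez ids), row metadata `probeset_id`, `symbol`, `description`, and a
#'   `collapse_report` metadata entry (counts of unannotated and
#'   duplicate-dropped probe sets).
#' @export
collapse_to_genes <- function(eset, annotation) {
  need <- c("probeset_id", "entrez_id", "symbol", "description")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop2("annotation is missing column(s): ", paste(miss, collapse = ", "),
          class = "exprgraph_validation_error")
  expr <- exprs_of(eset)
  ann <- annotation[annotation$probeset_id %in% rownames(expr), , drop = FALSE]
  ann$entrez_id <- as.character(ann$entrez_id)
  if (!nrow(ann))
    stop2("no probe set in the matrix is annotated",
          class = "exprgraph_validation_error")
  n_unannotated <- sum(!rownames(expr) %in% ann$probeset_id)

  means <- rowMeans(expr)[ann$probeset_id]
  # highest mean expression wins; ties -> lexicographically smallest id
  ord <- order(ann$entrez_id, -means, ann$probeset_id, method = "radix")
  ann <- ann[ord, , drop = FALSE]
  keep <- ann[!duplicated(ann$entrez_id), , drop = FALSE]
  n_duplicate_dropped <- nrow(ann) - nrow(keep)

  out <- expr[keep$probeset_id, , drop = FALSE]
  rownames(out) <- keep$entrez_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = out),
    colData = SummarizedExperiment::colData(eset),
    rowData = S4Vectors::DataFrame(probeset_id = keep$probeset_id,
                                   symbol = keep$symbol,
                                   description = keep$description,
                                   row.names = keep$entrez_id))
  S4Vectors::metadata(se) <- c(
    S4Vectors::metadata(eset),
    list(collapse_report = list(n_unannotated = n_unannotated,
                                n_duplicate_dropped = n_duplicate_dropped)))
  se
}

#' Group labels of an expression set
#' @param eset A `SummarizedExperiment` built by [build_eset()].
#' @return Character vector of `SETS` labels, one per sample.
#' @export
groups_of <- function(eset) {
  as.character(SummarizedExperiment::colData(eset)$SETS)
}
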
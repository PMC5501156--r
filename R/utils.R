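#' @keywords internal
"_PACKAGE"

#' @importFrom stats ave cor density fivenum median medpolish p.adjust
#'   phyper pt quantile rnorm runif sd setNames var
#' @importFrom utils agrepl combn head packageVersion read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(..., class = character()) {
  stop(structure(
    class = c(class, "exprgraph_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop2(sprintf("'%s' must be a single integer >= %d (got %s)",
                  name, min, deparse(x)), class = "exprgraph_validation_error")
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok)
    stop2(sprintf("'%s' must be a single number in %s%g, %g] (got %s)",
                  name, if (strict_lower) "(" else "[", lower, upper,
                  deparse(x)), class = "exprgraph_validation_error")
  as.numeric(x)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout the package: tab
#' separator, header row, no quoting, no row names.
#'
#' @param path File path.
#' @param x A data frame.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' The on-disk layout is one row per probe/gene with the identifier in the
#' first column and one column per sample.
#'
#' @param path File path.
#' @param m Numeric matrix with row and column names.
#' @param id_col Name written for the identifier column.
#' @return `read_expression_tsv()` returns a numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path, id_col = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  write_tsv(d, path)
}

#' Read and write gene-set files in GMT format
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line with
#' set name, description, then member gene identifiers.
#'
#' @param path File path.
#' @param term_map Named list of character vectors (term id -> member gene
#'   ids), optionally with a `term_names` attribute (named character vector
#'   of descriptions).
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `term_names` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  descr <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "",
                  character(1))
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character())
  names(sets) <- ids
  attr(sets, "term_names") <- setNames(descr, ids)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(term_map, path) {
  nms <- attr(term_map, "term_names") %||%
    setNames(names(term_map), names(term_map))
  lines <- vapply(names(term_map), function(id) {
    paste(c(id, unname(nms[[id]]) %||% id, term_map[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
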
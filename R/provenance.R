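#' A data-derivation graph (DDG) recorder
#'
#' Records every pipeline stage as an operation node (name, parameters,
#' timestamps, software version) connected by `used` edges to the data
#' nodes it consumed and `generated` edges to the data nodes it produced.
#' Data nodes are keyed by SHA-256 content hashes, so identical re-runs
#' yield identical hashes and the derivation graph is bipartite and
#' acyclic by construction.
#'
#' @return An object of class `provenance_recorder`.
#' @export
provenance_recorder <- function() {
  structure(new.env(parent = emptyenv()), class = "provenance_recorder") -> rec
  rec$operations <- list()
  rec$data <- list()
  rec$edges <- list()
  rec
}

content_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    digest::digest(file = x, algo = "sha256")
  else
    digest::digest(x, algo = "sha256")
}

#' Record one operation in the derivation graph
#'
#' @param rec A [provenance_recorder()].
#' @param op_name Stage name.
#' @param params Named list of parameter values, recorded verbatim
#'   (including defaults).
#' @param inputs,outputs Named lists of consumed/produced artifacts; file
#'   paths are hashed by content, in-memory objects by canonical
#'   serialization.
#' @param started,finished POSIXct timestamps (default: now).
#' @return The recorder, invisibly.
#' @export
prov_record <- function(rec, op_name, params = list(), inputs = list(),
                        outputs = list(), started = Sys.time(),
                        finished = Sys.time()) {
  op_id <- sprintf("op%03d", length(rec$operations) + 1L)
  rec$operations[[op_id]] <- list(
    id = op_id, name = op_name, parameters = params,
    started = format(started, "%Y-%m-%dT%H:%M:%OS3%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%OS3%z"),
    software = paste0("exprgraph ",
                      as.character(utils::packageVersion("exprgraph"))))
  add_data <- function(role, value, direction) {
    h <- content_hash(value)
    d_id <- paste0("data:", h)
    if (is.null(rec$data[[d_id]]))
      rec$data[[d_id]] <- list(
        id = d_id, role = role, hash = h,
        path = if (is.character(value) && length(value) == 1L &&
                   file.exists(value)) value else NULL)
    rec$edges[[length(rec$edges) + 1L]] <-
      if (direction == "used") list(type = "used", from = d_id, to = op_id)
      else list(type = "generated", from = op_id, to = d_id)
  }
  for (nm in names(inputs)) add_data(nm, inputs[[nm]], "used")
  for (nm in names(outputs)) add_data(nm, outputs[[nm]], "generated")
  invisible(rec)
}

prov_validate <- function(rec) {
  gen_by <- list()
  op_order <- setNames(seq_along(rec$operations), names(rec$operations))
  for (e in rec$edges) {
    if (e$type == "generated") {
      d <- e$to
      if (!is.null(gen_by[[d]]) && gen_by[[d]] != e$from)
        stop2("data node ", d, " generated by more than one operation",
              class = "exprgraph_provenance_error")
      gen_by[[d]] <- e$from
    }
  }
  # acyclicity: a data node must be generated before (or never) it is used
  for (e in rec$edges) {
    if (e$type == "used" && !is.null(gen_by[[e$from]])) {
      if (op_order[[gen_by[[e$from]]]] > op_order[[e$to]])
        stop2("cycle detected: ", e$from, " used before it was generated",
              class = "exprgraph_provenance_error")
    }
  }
  invisible(TRUE)
}

#' Export / import the derivation graph as JSON
#'
#' Acyclicity and single-generator invariants are verified on export.
#'
#' @param rec A [provenance_recorder()].
#' @param path JSON file path.
#' @return `export_provenance()` returns `path` invisibly;
#'   `load_provenance()` returns the parsed record (a list with
#'   `operations`, `data`, `edges`).
#' @export
export_provenance <- function(rec, path) {
  prov_validate(rec)
  obj <- list(operations = unname(rec$operations),
              data = unname(rec$data),
              edges = rec$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname export_provenance
#' @export
load_provenance <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Graphviz DOT rendering of a derivation graph
#' @param rec A [provenance_recorder()].
#' @param path Output `.dot` path.
#' @return `path`, invisibly.
#' @export
prov_to_dot <- function(rec, path) {
  q <- function(s) gsub('"', '\\\\"', s)
  lines <- c("digraph ddg {", "  rankdir=TB;")
  for (op in rec$operations)
    lines <- c(lines, sprintf('  "%s" [shape=box, label="%s"];',
                              q(op$id), q(op$name)))
  for (d in rec$data)
    lines <- c(lines, sprintf('  "%s" [shape=ellipse, label="%s"];',
                              q(d$id), q(d$role)))
  for (e in rec$edges)
    lines <- c(lines, sprintf('  "%s" -> "%s";', q(e$from), q(e$to)))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
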
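prop_type_of <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.numeric(v)) "double"
  else "string"
}

prop_to_chr <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v)
  else if (is.logical(v)) tolower(as.character(v))
  else as.character(v)
}

prop_from_chr <- function(s, type) {
  switch(type,
         double = as.numeric(s),
         boolean = identical(s, "true"),
         s)
}

#' Persist and restore a property graph
#'
#' Supported formats: `graphml` (typed keys; lossless round-trip),
#' `json` (`{"nodes": [...], "edges": [...]}`; lossless round-trip), and
#' `cypher` (a `.cql` script of `CREATE` statements executable in a
#' Cypher-compatible store; write-only). The format is inferred from the
#' file extension when not given.
#'
#' @param g A [property_graph()].
#' @param path Output/input file path.
#' @param format `"graphml"`, `"json"`, or `"cypher"`.
#' @return `save_graph()` returns `path` invisibly; `load_graph()` returns
#'   a `property_graph`.
#' @export
save_graph <- function(g, path, format = NULL) {
  format <- format %||% guess_graph_format(path)
  switch(format,
         graphml = save_graphml(g, path),
         json = save_graph_json(g, path),
         cypher = save_cypher(g, path),
         stop2("unknown graph format: ", format,
               class = "exprgraph_validation_error"))
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path, format = NULL) {
  format <- format %||% guess_graph_format(path)
  switch(format,
         graphml = load_graphml(path),
         json = load_graph_json(path),
         cypher = stop2("the cypher format is write-only",
                        class = "exprgraph_validation_error"),
         stop2("unknown graph format: ", format,
               class = "exprgraph_validation_error"))
}

guess_graph_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, graphml = "graphml", json = "json", cql = "cypher",
         cypher = "cypher",
         stop2("cannot infer graph format from extension: ", path,
               class = "exprgraph_validation_error"))
}

collect_keys <- function(items) {
  keys <- list()
  for (it in items)
    for (nm in names(it$props)) {
      v <- it$props[[nm]]
      ty <- prop_type_of(v)
      if (!is.null(keys[[nm]]) && keys[[nm]] != ty)
        keys[[nm]] <- "string"
      else keys[[nm]] <- ty
    }
  keys
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub('"', "&quot;", s, fixed = TRUE)
  s
}

# string-building writer: xml2's node-by-node construction is too slow for
# graphs with thousands of attributed edges; reading still goes through xml2
save_graphml <- function(g, path) {
  nodes <- pg_node_list(g)
  edges <- pg_edge_list(g)
  nkeys <- collect_keys(nodes)
  ekeys <- collect_keys(edges)
  key_lines <- c(
    vapply(names(nkeys), function(nm) sprintf(
      '  <key id="n_%s" for="node" attr.name="%s" attr.type="%s"/>',
      xml_escape(nm), xml_escape(nm), nkeys[[nm]]), character(1)),
    vapply(names(ekeys), function(nm) sprintf(
      '  <key id="e_%s" for="edge" attr.name="%s" attr.type="%s"/>',
      xml_escape(nm), xml_escape(nm), ekeys[[nm]]), character(1)),
    '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="type" for="edge" attr.name="type" attr.type="string"/>')
  data_line <- function(key, value)
    sprintf('      <data key="%s">%s</data>', key, xml_escape(value))
  node_lines <- vapply(nodes, function(nd) {
    paste(c(sprintf('    <node id="%s">', xml_escape(nd$id)),
            data_line("label", nd$label),
            vapply(names(nd$props), function(nm)
              data_line(paste0("n_", xml_escape(nm)),
                        prop_to_chr(nd$props[[nm]])), character(1)),
            "    </node>"), collapse = "\n")
  }, character(1))
  edge_lines <- vapply(edges, function(e) {
    paste(c(sprintf('    <edge source="%s" target="%s">',
                    xml_escape(e$from), xml_escape(e$to)),
            data_line("type", e$type),
            vapply(names(e$props), function(nm)
              data_line(paste0("e_", xml_escape(nm)),
                        prop_to_chr(e$props[[nm]])), character(1)),
            "    </edge>"), collapse = "\n")
  }, character(1))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               key_lines,
               '  <graph id="G" edgedefault="directed">',
               node_lines, edge_lines,
               "  </graph>", "</graphml>"), path)
}

load_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop2("malformed GraphML file '", path, "': ", conditionMessage(e),
          class = "exprgraph_io_error"))
  # namespace-prefixed XPath; xml_ns_strip() is prohibitively slow on large
  # documents
  ns <- xml2::xml_ns(doc)
  prefix <- if ("d1" %in% names(ns)) "d1:" else ""
  xp <- function(p) gsub("q:", prefix, p, fixed = TRUE)
  keytypes <- list()
  for (k in xml2::xml_find_all(doc, xp("/q:graphml/q:key"), ns))
    keytypes[[xml2::xml_attr(k, "id")]] <-
      list(name = xml2::xml_attr(k, "attr.name"),
           type = xml2::xml_attr(k, "attr.type"))
  g <- property_graph()
  # bulk-extract <data> children grouped by their parent element; per-node
  # xml2 calls are too slow for graphs with thousands of attributed edges
  grouped_data <- function(elems, xpath_data) {
    datas <- xml2::xml_find_all(doc, xp(xpath_data), ns)
    grp <- rep(seq_along(elems), xml2::xml_length(elems))
    list(keys = split(xml2::xml_attr(datas, "key"), factor(grp,
             levels = seq_along(elems))),
         vals = split(xml2::xml_text(datas), factor(grp,
             levels = seq_along(elems))))
  }
  build_props <- function(keys, vals, what, context) {
    props <- list()
    special <- NULL
    for (i in seq_along(keys)) {
      if (identical(keys[i], what)) special <- vals[i]
      else {
        kt <- keytypes[[keys[i]]]
        if (is.null(kt))
          stop2("GraphML ", context, " uses undeclared key '", keys[i], "'",
                class = "exprgraph_io_error")
        props[[kt$name]] <- prop_from_chr(vals[i], kt$type)
      }
    }
    if (is.null(special))
      stop2("GraphML ", context, " has no ", what,
            class = "exprgraph_io_error")
    list(special = special, props = props)
  }
  xn <- xml2::xml_find_all(doc, xp("/q:graphml/q:graph/q:node"), ns)
  ids <- xml2::xml_attr(xn, "id")
  nd <- grouped_data(xn, "/q:graphml/q:graph/q:node/q:data")
  for (i in seq_along(xn)) {
    d <- build_props(nd$keys[[i]], nd$vals[[i]], "label",
                     paste0("node '", ids[i], "'"))
    pg_add_node(g, ids[i], d$special, d$props)
  }
  xe <- xml2::xml_find_all(doc, xp("/q:graphml/q:graph/q:edge"), ns)
  froms <- xml2::xml_attr(xe, "source")
  tos <- xml2::xml_attr(xe, "target")
  ed <- grouped_data(xe, "/q:graphml/q:graph/q:edge/q:data")
  for (i in seq_along(xe)) {
    d <- build_props(ed$keys[[i]], ed$vals[[i]], "type",
                     paste0("edge ", froms[i], "->", tos[i]))
    pg_add_edge(g, froms[i], tos[i], d$special, d$props)
  }
  g
}

save_graph_json <- function(g, path) {
  obj <- list(
    nodes = lapply(pg_node_list(g), function(nd)
      list(id = nd$id, label = nd$label,
           properties = if (length(nd$props)) nd$props else NULL)),
    edges = lapply(pg_edge_list(g), function(e)
      list(source = e$from, target = e$to, type = e$type,
           properties = if (length(e$props)) e$props else NULL))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

load_graph_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop2("malformed JSON graph file '", path, "': ",
                              conditionMessage(e),
                              class = "exprgraph_io_error"))
  g <- property_graph()
  for (nd in obj$nodes) {
    if (is.null(nd$id) || is.null(nd$label))
      stop2("JSON graph node without id/label in '", path, "'",
            class = "exprgraph_io_error")
    pg_add_node(g, nd$id, nd$label, lapply(nd$properties %||% list(),
                                           identity))
  }
  for (e in obj$edges) {
    if (is.null(e$source) || is.null(e$target) || is.null(e$type))
      stop2("JSON graph edge without source/target/type in '", path, "'",
            class = "exprgraph_io_error")
    pg_add_edge(g, e$source, e$target, e$type,
                lapply(e$properties %||% list(), identity))
  }
  g
}

cypher_escape <- function(s) gsub("'", "\\\\'", s)

cypher_props <- function(props) {
  if (!length(props)) return("")
  parts <- vapply(names(props), function(nm) {
    v <- props[[nm]]
    val <- if (is.numeric(v)) sprintf("%.17g", v)
           else if (is.logical(v)) tolower(as.character(v))
           else sprintf("'%s'", cypher_escape(as.character(v)))
    sprintf("`%s`: %s", nm, val)
  }, character(1))
  paste0(" {", paste(parts, collapse = ", "), "}")
}

save_cypher <- function(g, path) {
  node_lines <- vapply(pg_node_list(g), function(nd)
    sprintf("CREATE (:%s%s);", nd$label,
            cypher_props(c(list(`_id` = nd$id), nd$props))), character(1))
  edge_lines <- vapply(pg_edge_list(g), function(e)
    sprintf("MATCH (a {`_id`: '%s'}), (b {`_id`: '%s'}) CREATE (a)-[:%s%s]->(b);",
            cypher_escape(e$from), cypher_escape(e$to), e$type,
            cypher_props(e$props)), character(1))
  writeLines(c(node_lines, edge_lines), path)
}

#' Compare two property graphs for equality
#'
#' Node sets, labels, edge sets, types, and all properties (numeric values
#' within `tol`).
#'
#' @param a,b Property graphs.
#' @param tol Numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(a, b, tol = 1e-12) {
  an <- pg_node_list(a); bn <- pg_node_list(b)
  ae <- pg_edge_list(a); be <- pg_edge_list(b)
  if (length(an) != length(bn) || length(ae) != length(be)) return(FALSE)
  props_equal <- function(p, q) {
    if (!setequal(names(p), names(q))) return(FALSE)
    for (nm in names(p)) {
      x <- p[[nm]]; y <- q[[nm]]
      if (is.numeric(x) && is.numeric(y)) {
        if (abs(x - y) > tol) return(FALSE)
      } else if (!identical(as.character(x), as.character(y))) return(FALSE)
    }
    TRUE
  }
  for (i in seq_along(an)) {
    if (an[[i]]$id != bn[[i]]$id || an[[i]]$label != bn[[i]]$label ||
        !props_equal(an[[i]]$props, bn[[i]]$props)) return(FALSE)
  }
  for (i in seq_along(ae)) {
    if (ae[[i]]$from != be[[i]]$from || ae[[i]]$to != be[[i]]$to ||
        ae[[i]]$type != be[[i]]$type ||
        !props_equal(ae[[i]]$props, be[[i]]$props)) return(FALSE)
  }
  TRUE
}
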
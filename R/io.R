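#' Read / write plane graphs as plain text
#'
#' Two-file plain-text format: a node file with columns `id x y` and an edge
#' file with columns `u v w` (whitespace separated, with header). Weights
#' must be positive; parsing validates the full graph.
#'
#' @param graph a `plane_graph` (or `dual_graph`, written via its centroid
#'   coordinates)
#' @param edge_file,node_file file paths
#' @return `write_edgelist` invisibly returns the paths; `read_edgelist`
#'   returns a `plane_graph`.
#' @export
write_edgelist <- function(graph, edge_file, node_file) {
  if (inherits(graph, "dual_graph")) graph <- dual_as_plane(graph)
  utils::write.table(
    data.frame(u = graph$edges$from, v = graph$edges$to, w = graph$edges$weight),
    edge_file, row.names = FALSE, quote = FALSE)
  utils::write.table(graph$nodes, node_file, row.names = FALSE, quote = FALSE)
  invisible(c(edge_file, node_file))
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(edge_file, node_file) {
  e <- utils::read.table(edge_file, header = TRUE)
  v <- utils::read.table(node_file, header = TRUE)
  plane_graph(v, data.frame(from = e[[1]], to = e[[2]], weight = e[[3]]))
}

# a dual graph as a drawable plane_graph (centroid coordinates; geometry is
# for serialization/visualization only, crossings are possible)
dual_as_plane <- function(dual) {
  co <- dual$coords
  if (anyNA(co$x)) co <- data.frame(x = seq_len(dual$n), y = 0)
  plane_graph(co, dual$edges, validate = FALSE)
}

#' JSON round trip of a plane graph
#'
#' Canonical JSON form with `nodes` (`id`, `x`, `y`) and `edges`
#' (`from`, `to`, `weight`).
#'
#' @param graph a `plane_graph`
#' @param file optional path; when `NULL`, the JSON string is returned
#' @export
plane_graph_to_json <- function(graph, file = NULL) {
  obj <- list(nodes = graph$nodes, edges = graph$edges)
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' @rdname plane_graph_to_json
#' @param x JSON string or file path
#' @export
plane_graph_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  plane_graph(as.data.frame(obj$nodes), as.data.frame(obj$edges))
}

#' GraphML input/output
#'
#' Writes/reads a GraphML-style XML document with node attributes `x`, `y`
#' and the edge attribute `weight`.
#'
#' @param graph a `plane_graph`
#' @param file path to the `.graphml` file
#' @export
write_graphml <- function(graph, file) {
  doc <- xml2::xml_new_root("graphml")
  for (k in list(c("d_x", "node", "x"), c("d_y", "node", "y"),
                 c("d_w", "edge", "weight"))) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = "double")
  }
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(n_nodes(graph))) {
    nd <- xml2::xml_add_child(gr, "node", id = paste0("n", i))
    xml2::xml_add_child(nd, "data", key = "d_x",
                        format(graph$nodes$x[i], digits = 17))
    xml2::xml_add_child(nd, "data", key = "d_y",
                        format(graph$nodes$y[i], digits = 17))
  }
  for (k in seq_len(n_edges(graph))) {
    ed <- xml2::xml_add_child(gr, "edge",
                              source = paste0("n", graph$edges$from[k]),
                              target = paste0("n", graph$edges$to[k]))
    xml2::xml_add_child(ed, "data", key = "d_w",
                        format(graph$edges$weight[k], digits = 17))
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//graph/node")
  ids <- as.integer(sub("^n", "", xml2::xml_attr(nodes, "id")))
  getdata <- function(el, key) {
    as.numeric(xml2::xml_text(
      xml2::xml_find_first(el, sprintf(".//data[@key='%s']", key))))
  }
  xs <- vapply(nodes, getdata, numeric(1), key = "d_x")
  ys <- vapply(nodes, getdata, numeric(1), key = "d_y")
  eds <- xml2::xml_find_all(doc, ".//graph/edge")
  fr <- as.integer(sub("^n", "", xml2::xml_attr(eds, "source")))
  to <- as.integer(sub("^n", "", xml2::xml_attr(eds, "target")))
  w <- vapply(eds, getdata, numeric(1), key = "d_w")
  ord <- order(ids)
  plane_graph(data.frame(id = ids[ord], x = xs[ord], y = ys[ord]),
              data.frame(from = fr, to = to, weight = w))
}
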
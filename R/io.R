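#' Read a vein network from disk
#'
#' Supported formats: GraphML (node attributes `x`, `y` in cm; edge
#' attribute `width` in mm, optional `length` in mm) and a TSV pair — an
#' edge list with columns `node_a`, `node_b`, `width` and optional
#' `length`, plus a companion node table with columns `node_id`, `x`, `y`.
#'
#' @param path file to read (for TSV, the edge-list file).
#' @param format `"graphml"` or `"tsv"`; guessed from the extension when
#'   missing.
#' @param nodes_path companion node table for TSV input; defaults to the
#'   edge path with `_nodes.tsv` substituted for `.tsv`.
#' @param check_crossings verify the planar embedding on input.
#' @return a validated [vein_network()].
#' @export
read_network <- function(path, format = c("guess", "graphml", "tsv"),
                         nodes_path = NULL, check_crossings = TRUE) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    read_network_graphml(path, check_crossings)
  } else {
    nodes_path <- nodes_path %||% default_nodes_path(path)
    read_network_tsv(path, nodes_path, check_crossings)
  }
}

default_nodes_path <- function(path) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", "_nodes.tsv", path)
  else paste0(path, "_nodes.tsv")
}

read_network_graphml <- function(path, check_crossings) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_map <- stats::setNames(
    xml2::xml_attr(keys, "attr.name"),
    xml2::xml_attr(keys, "id"))
  get_data <- function(node_set, attr_name) {
    vapply(node_set, function(nd) {
      data <- xml2::xml_find_all(nd, "./data")
      ids <- xml2::xml_attr(data, "key")
      names <- ifelse(ids %in% names(key_map), key_map[ids], ids)
      hit <- which(names == attr_name)
      if (length(hit) == 0) NA_character_ else xml2::xml_text(data[[hit[1]]])
    }, character(1))
  }
  node_xml <- xml2::xml_find_all(doc, ".//graph/node")
  edge_xml <- xml2::xml_find_all(doc, ".//graph/edge")
  if (length(node_xml) == 0) stop("format error: GraphML contains no nodes")
  node_label <- xml2::xml_attr(node_xml, "id")
  x <- suppressWarnings(as.numeric(get_data(node_xml, "x")))
  y <- suppressWarnings(as.numeric(get_data(node_xml, "y")))
  if (anyNA(x) || anyNA(y))
    stop("format error: every GraphML node needs numeric 'x' and 'y' attributes")
  src <- match(xml2::xml_attr(edge_xml, "source"), node_label)
  dst <- match(xml2::xml_attr(edge_xml, "target"), node_label)
  if (anyNA(src) || anyNA(dst))
    stop("format error: edge endpoint not among declared nodes")
  width <- suppressWarnings(as.numeric(get_data(edge_xml, "width")))
  if (length(edge_xml) > 0 && anyNA(width))
    stop("format error: every GraphML edge needs a numeric 'width' attribute")
  len <- suppressWarnings(as.numeric(get_data(edge_xml, "length")))
  edges <- data.frame(from = src, to = dst, width = width)
  if (!all(is.na(len))) edges$length <- len
  nodes <- data.frame(id = seq_along(node_label), x = x, y = y)
  vein_network(nodes, edges, validate = TRUE, check_crossings = check_crossings)
}

read_network_tsv <- function(path, nodes_path, check_crossings) {
  if (!file.exists(nodes_path))
    stop("format error: companion node table not found: ", nodes_path)
  ed <- utils::read.table(path, header = TRUE, sep = "\t")
  nd <- utils::read.table(nodes_path, header = TRUE, sep = "\t")
  need_e <- c("node_a", "node_b", "width")
  need_n <- c("node_id", "x", "y")
  if (!all(need_e %in% names(ed)))
    stop("format error: edge table needs columns ", paste(need_e, collapse = ", "))
  if (!all(need_n %in% names(nd)))
    stop("format error: node table needs columns ", paste(need_n, collapse = ", "))
  nodes <- data.frame(id = as.integer(nd$node_id), x = nd$x, y = nd$y)
  edges <- data.frame(from = as.integer(ed$node_a), to = as.integer(ed$node_b),
                      width = ed$width)
  if ("length" %in% names(ed)) edges$length <- ed$length
  vein_network(nodes, edges, validate = TRUE, check_crossings = check_crossings)
}

#' Write a vein network to disk
#'
#' Inverse of [read_network()]; output is bit-stable for identical input
#' and round-trips through `read_network()`.
#'
#' @param net a `vein_network`.
#' @param path output file (for TSV, the edge-list file).
#' @param format `"graphml"` or `"tsv"`; guessed from the extension.
#' @param nodes_path companion node file for TSV output.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("guess", "graphml", "tsv"),
                          nodes_path = NULL) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  validate_network(net)
  if (format == "graphml") {
    write_network_graphml(net, path)
  } else {
    nodes_path <- nodes_path %||% default_nodes_path(path)
    write_network_tsv(net, path, nodes_path)
  }
  invisible(path)
}

write_network_graphml <- function(net, path) {
  num <- function(v) formatC(v, format = "g", digits = 17)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="x" for="node" attr.name="x" attr.type="double"/>',
    '  <key id="y" for="node" attr.name="y" attr.type="double"/>',
    '  <key id="width" for="edge" attr.name="width" attr.type="double"/>',
    '  <key id="length" for="edge" attr.name="length" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">')
  lines <- c(lines, sprintf(
    '    <node id="n%d"><data key="x">%s</data><data key="y">%s</data></node>',
    net$nodes$id, num(net$nodes$x), num(net$nodes$y)))
  if (nrow(net$edges)) {
    lines <- c(lines, sprintf(
      paste0('    <edge id="e%d" source="n%d" target="n%d">',
             '<data key="width">%s</data><data key="length">%s</data></edge>'),
      net$edges$id, net$edges$from, net$edges$to,
      num(net$edges$width), num(net$edges$length)))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
}

write_network_tsv <- function(net, path, nodes_path) {
  ed <- data.frame(node_a = net$edges$from, node_b = net$edges$to,
                   width = net$edges$width, length = net$edges$length)
  nd <- data.frame(node_id = net$nodes$id, x = net$nodes$x, y = net$nodes$y)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
}
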
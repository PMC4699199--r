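#' Prune a network to its cycle-supported subgraph
#'
#' Removes every subgraph that is not part of any loop: an edge lies on a
#' cycle if and only if it is not a bridge, so all bridge edges (which
#' includes every tree-like appendage and free-ending veinlet) are deleted
#' and isolated nodes dropped. If several connected components remain, the
#' component with the most internal faces (by Euler's formula,
#' E - V + 1 per connected planar component) is kept with a warning.
#'
#' @param net a `vein_network`.
#' @return the pruned `vein_network`; it has 0 edges if the input contained
#'   no cycle (a forest). Node and edge ids are preserved.
#' @export
prune_to_cycles <- function(net) {
  if (nrow(net$edges) == 0) return(subset_edges(net, logical(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$from),
               to = as.character(net$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id)))
  br <- igraph::bridges(g)
  keep <- rep(TRUE, nrow(net$edges))
  keep[as.integer(br)] <- FALSE
  out <- subset_edges(net, keep)
  if (nrow(out$edges) == 0) return(out)
  # keep the component supporting the most faces
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = as.character(out$edges$from),
               to = as.character(out$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(out$nodes$id)))
  comp <- igraph::components(g2)
  if (comp$no > 1) {
    memb <- comp$membership[as.character(out$edges$from)]
    e_per <- tabulate(memb, comp$no)
    v_per <- comp$csize
    faces <- e_per - v_per + 1
    best <- which.max(faces)
    warning(sprintf(
      "pruned network has %d components; keeping the one with %d faces",
      comp$no, faces[best]))
    out <- subset_edges(out, memb == best)
  }
  out
}

#' Test whether a pruned network is empty
#'
#' @param net a `vein_network`.
#' @return TRUE if the network has no edges.
#' @export
is_empty_network <- function(net) nrow(net$edges) == 0
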
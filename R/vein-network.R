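#' Construct a planar weighted vein network
#'
#' A `vein_network` is the basic container for a vectorized venation graph:
#' a planar embedded graph whose nodes carry coordinates (in cm) and whose
#' edges carry a vein width (in mm). Edges are straight segments between
#' their endpoints; curved veins must be discretized upstream by the
#' vectorizer.
#'
#' @param nodes data.frame with columns `id` (unique integers), `x`, `y`
#'   (coordinates in cm). If `id` is missing, rows are numbered 1..n.
#' @param edges data.frame with columns `from`, `to` (node ids), `width`
#'   (mm) and optionally `length` (mm; defaults to the Euclidean distance
#'   between the endpoints converted to mm) and `id` (unique integers,
#'   defaults to row numbers). Edge ids are stable under pruning and are
#'   used for deterministic tie-breaking throughout the package.
#' @param validate check invariants (positive widths and lengths, no
#'   self-loops, no duplicated node pairs).
#' @param check_crossings additionally verify that no two edge segments
#'   cross anywhere except at shared nodes, i.e. that the coordinates
#'   define a planar embedding. Quadratic with a spatial prefilter; skip
#'   for networks that are planar by construction.
#' @return an object of class `vein_network`.
#' @export
vein_network <- function(nodes, edges, validate = TRUE, check_crossings = FALSE) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (is.null(nodes$id)) nodes$id <- seq_len(nrow(nodes))
  nodes$id <- as.integer(nodes$id)
  stopifnot(!is.null(nodes$x), !is.null(nodes$y))
  if (is.null(edges$id)) edges$id <- seq_len(nrow(edges))
  edges$id <- as.integer(edges$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (anyDuplicated(nodes$id)) stop("duplicated node ids")
  if (anyDuplicated(edges$id)) stop("duplicated edge ids")
  if (nrow(edges) > 0 && is.null(edges$width)) stop("edges need a 'width' column")
  if (is.null(edges$length)) {
    ii <- match(edges$from, nodes$id)
    jj <- match(edges$to, nodes$id)
    edges$length <- 10 * sqrt((nodes$x[ii] - nodes$x[jj])^2 +
                              (nodes$y[ii] - nodes$y[jj])^2)
  }
  net <- structure(
    list(nodes = nodes[, c("id", "x", "y")],
         edges = edges[, c("id", "from", "to", "width", "length")]),
    class = "vein_network",
    units = c(coord = "cm", width = "mm", length = "mm"))
  if (validate) validate_network(net, check_crossings = check_crossings)
  net
}

#' Validate a vein network
#'
#' Checks the container invariants: endpoints refer to existing nodes, all
#' widths and lengths are strictly positive, no self-loops, no duplicated
#' node pairs (parallel straight edges would coincide geometrically), and
#' optionally that the straight-segment embedding is planar.
#'
#' @param net a `vein_network`.
#' @param check_crossings test all segment pairs for crossings.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net, check_crossings = FALSE) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyNA(nodes$x) || anyNA(nodes$y)) stop("missing node coordinates")
  if (nrow(edges) > 0) {
    if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
      stop("edge endpoint refers to unknown node id")
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    if (any(!is.finite(edges$width)) || any(edges$width <= 0))
      stop("all edge widths must be strictly positive")
    if (any(!is.finite(edges$length)) || any(edges$length <= 0))
      stop("all edge lengths must be strictly positive")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key))
      stop("parallel edges between the same node pair are not allowed ",
           "(straight segments would coincide)")
    if (check_crossings) check_embedding(net)
  }
  invisible(net)
}

# Error if any two straight-segment edges intersect other than at a common
# node. Candidate pairs are found by hashing edge bounding boxes on a grid.
check_embedding <- function(net) {
  e <- net$edges
  m <- nrow(e)
  if (m < 2) return(invisible(net))
  ii <- match(e$from, net$nodes$id)
  jj <- match(e$to, net$nodes$id)
  x1 <- net$nodes$x[ii]; y1 <- net$nodes$y[ii]
  x2 <- net$nodes$x[jj]; y2 <- net$nodes$y[jj]
  cell <- stats::median(pmax(abs(x2 - x1), abs(y2 - y1)))
  if (!is.finite(cell) || cell <= 0) cell <- 1
  lox <- floor(pmin(x1, x2) / cell); hix <- floor(pmax(x1, x2) / cell)
  loy <- floor(pmin(y1, y2) / cell); hiy <- floor(pmax(y1, y2) / cell)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(m)) {
    for (cx in lox[k]:hix[k]) for (cy in loy[k]:hiy[k]) {
      key <- paste(cx, cy)
      buckets[[key]] <- c(buckets[[key]], k)
    }
  }
  pairs <- unique(do.call(rbind, lapply(ls(buckets), function(key) {
    ks <- buckets[[key]]
    if (length(ks) < 2) return(NULL)
    t(utils::combn(sort(ks), 2))
  })))
  if (is.null(pairs) || nrow(pairs) == 0) return(invisible(net))
  a <- pairs[, 1]; b <- pairs[, 2]
  share <- e$from[a] == e$from[b] | e$from[a] == e$to[b] |
    e$to[a] == e$from[b] | e$to[a] == e$to[b]
  a <- a[!share]; b <- b[!share]
  if (length(a)) {
    bad <- segments_cross(x1[a], y1[a], x2[a], y2[a],
                          x1[b], y1[b], x2[b], y2[b])
    if (any(bad)) {
      k <- which(bad)[1]
      stop(sprintf("edges %d and %d cross: coordinates are not a planar embedding",
                   e$id[a[k]], e$id[b[k]]))
    }
  }
  invisible(net)
}

n_nodes <- function(net) nrow(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' @export
print.vein_network <- function(x, ...) {
  bb <- if (nrow(x$nodes)) {
    sprintf("%.2f x %.2f cm", diff(range(x$nodes$x)), diff(range(x$nodes$y)))
  } else "empty"
  cat(sprintf("vein_network: %d nodes, %d edges, bounding box %s\n",
              nrow(x$nodes), nrow(x$edges), bb))
  if (nrow(x$edges)) {
    cat(sprintf("  widths [mm]: %.4g - %.4g, total length %.4g mm\n",
                min(x$edges$width), max(x$edges$width), sum(x$edges$length)))
  }
  invisible(x)
}

#' @export
summary.vein_network <- function(object, ...) {
  print(object)
  if (nrow(object$edges)) {
    cat("  width quartiles [mm]:",
        paste(signif(stats::quantile(object$edges$width), 4), collapse = " "),
        "\n")
  }
  invisible(object)
}

#' Plot a vein network
#'
#' Draws the straight-segment embedding with line widths proportional to
#' vein widths.
#'
#' @param x a `vein_network`.
#' @param lwd_scale multiplier from vein width (mm) to line width.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.vein_network <- function(x, lwd_scale = 10, ...) {
  if (nrow(x$edges) == 0) stop("empty network")
  ii <- match(x$edges$from, x$nodes$id)
  jj <- match(x$edges$to, x$nodes$id)
  graphics::plot(x$nodes$x, x$nodes$y, type = "n", asp = 1,
                 xlab = "x [cm]", ylab = "y [cm]", ...)
  graphics::segments(x$nodes$x[ii], x$nodes$y[ii],
                     x$nodes$x[jj], x$nodes$y[jj],
                     lwd = pmax(0.3, x$edges$width * lwd_scale))
  invisible(x)
}

#' Transform node coordinates
#'
#' Applies a coordinate map to all nodes, e.g. a rigid motion or scaling.
#' Edge lengths are recomputed from the new coordinates.
#'
#' @param net a `vein_network`.
#' @param f function taking (x, y) vectors and returning a list or
#'   data.frame with components `x` and `y`.
#' @return the transformed `vein_network`.
#' @export
transform_coords <- function(net, f) {
  xy <- f(net$nodes$x, net$nodes$y)
  nodes <- data.frame(id = net$nodes$id, x = xy$x, y = xy$y)
  edges <- net$edges
  edges$length <- NULL
  vein_network(nodes, edges, validate = FALSE)
}

#' Transform edge widths
#'
#' Applies a map to all edge widths, e.g. a monotone rescaling when testing
#' rank invariance of the topological metrics.
#'
#' @param net a `vein_network`.
#' @param f function from width vector to width vector.
#' @return the modified `vein_network`.
#' @export
map_widths <- function(net, f) {
  net$edges$width <- f(net$edges$width)
  if (any(net$edges$width <= 0)) stop("width map produced non-positive widths")
  net
}

# Subset a network to an edge index set, dropping isolated nodes but keeping
# node/edge ids stable.
subset_edges <- function(net, keep) {
  edges <- net$edges[keep, , drop = FALSE]
  used <- unique(c(edges$from, edges$to))
  nodes <- net$nodes[net$nodes$id %in% used, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "vein_network", units = attr(net, "units"))
}
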
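#' Nesting ratios of a tree, filtered by subtree degree
#'
#' Returns the multiset of nesting ratios `q_j = s_j/r_j` over all
#' internal nodes whose subtree degree `d_j` does not exceed
#' `max_degree`. The degree threshold removes leaf-size effects when
#' comparing specimens: the conventional thresholds are 256 for full
#' leaves and 128 for fragments.
#'
#' @param tree a `nesting_tree`.
#' @param max_degree keep internal nodes with `d_j <= max_degree`.
#' @return numeric vector of nesting ratios (possibly empty).
#' @export
nesting_ratios <- function(tree, max_degree = 256) {
  stopifnot(inherits(tree, "nesting_tree"), max_degree >= 2)
  if (n_internal(tree) == 0) {
    warning("tree has no internal nodes; empty nesting-ratio set")
    return(numeric(0))
  }
  tree$q[tree$d <= max_degree]
}

#' Nesting number of a tree
#'
#' The nesting number is the weighted mean `i = sum_j w_j q_j` of the
#' nesting ratios over the degree-filtered internal nodes, with
#' `sum_j w_j = 1`. The unweighted variant uses equal weights; the
#' degree-weighted variant uses `w_j` proportional to `d_j - 1`, giving
#' large subtrees more influence. Values near 1 indicate strongly nested
#' (balanced) loop hierarchies; small values indicate chain-like nesting.
#'
#' @param tree a `nesting_tree`.
#' @param mode `"unweighted"` (`i_u`) or `"degree_weighted"` (`i_w`).
#' @param max_degree subtree-degree threshold, as in [nesting_ratios()].
#' @return a number in (0, 1], or NA with a warning if no internal node
#'   passes the filter.
#' @export
nesting_number <- function(tree, mode = c("unweighted", "degree_weighted"),
                           max_degree = 256) {
  mode <- match.arg(mode)
  keep <- which(tree$d <= max_degree)
  if (length(keep) == 0) {
    warning("no internal node passes the degree filter; nesting number undefined")
    return(NA_real_)
  }
  qv <- tree$q[keep]
  if (mode == "unweighted") mean(qv)
  else stats::weighted.mean(qv, tree$d[keep] - 1)
}

#' Topological tapering lengths of all edges
#'
#' From each edge a deterministic greedy walk is taken: move to the
#' adjacent edge (sharing an endpoint) with the largest width among those
#' strictly thinner than the current edge, breaking width ties by the
#' smaller edge id; stop when no adjacent edge is thinner. The number of
#' steps is the topological length `L_e` of the start edge. Because
#' widths strictly decrease along the walk it always terminates.
#'
#' @param net a `vein_network` (pruning not required).
#' @return integer vector of `L_e`, named by edge id.
#' @export
topological_lengths <- function(net) {
  E <- nrow(net$edges)
  if (E == 0) return(stats::setNames(integer(0), character(0)))
  w <- net$edges$width
  ids <- net$edges$id
  # adjacency via endpoints
  V <- nrow(net$nodes)
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  inc <- vector("list", V)
  for (k in seq_len(E)) {
    inc[[ii[k]]] <- c(inc[[ii[k]]], k)
    inc[[jj[k]]] <- c(inc[[jj[k]]], k)
  }
  nxt <- integer(E)   # successor edge index, 0 = none
  for (k in seq_len(E)) {
    nb <- setdiff(c(inc[[ii[k]]], inc[[jj[k]]]), k)
    nb <- nb[w[nb] < w[k]]
    if (length(nb) == 0) {
      nxt[k] <- 0L
    } else {
      nxt[k] <- nb[order(-w[nb], ids[nb])[1]]
    }
  }
  L <- rep(NA_integer_, E)
  for (k in order(w)) {           # process thinnest first: successors resolved
    L[k] <- if (nxt[k] == 0L) 0L else 1L + L[nxt[k]]
  }
  stats::setNames(L, ids)
}

#' Mean topological length of a network
#'
#' The arithmetic mean of the topological tapering lengths `L_e` over all
#' `N_E` edges; it quantifies how far tapered vein sequences extend.
#'
#' @param net a `vein_network` with at least one edge.
#' @return a non-negative number.
#' @export
mean_topological_length <- function(net) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  mean(topological_lengths(net))
}

#' Geometric venation metrics
#'
#' Computes the five classical local geometric quantities of a pruned
#' venation network:
#' \describe{
#'   \item{sigma}{vein density: total vein length / leaf area (mm/mm^2);}
#'   \item{a}{mean distance to the nearest vein (mm), estimated as the
#'     mean nearest-centerline distance over a uniform grid of sample
#'     points inside the leaf outline;}
#'   \item{A}{mean areole area (mm^2);}
#'   \item{rho_A}{areole density: areole count / leaf area (1/mm^2);}
#'   \item{d}{length-weighted mean vein diameter (mm).}
#' }
#' The leaf area is the area enclosed by the outer-face boundary polygon.
#'
#' @param net a pruned, connected `vein_network` with at least one facet.
#' @param facets optional precomputed [extract_facets()] result.
#' @param grid_spacing sample-point spacing for `a`, in mm; default
#'   `min(0.1, leaf diameter / 500)`.
#' @param max_points cap on the number of grid sample points; the spacing
#'   is coarsened if the default grid would exceed it.
#' @return named list with elements `sigma`, `a`, `A`, `rho_A`, `d`.
#' @export
geometric_metrics <- function(net, facets = NULL, grid_spacing = NULL,
                              max_points = 40000) {
  fc <- facets %||% extract_facets(net)
  if (length(fc$facets) == 0) stop("network has no facets")
  leaf_area_mm2 <- fc$outer$area * 100     # cm^2 -> mm^2
  total_len <- sum(net$edges$length)
  sigma <- total_len / leaf_area_mm2
  ar <- areole_areas(fc) * 100
  A <- mean(ar)
  rho_A <- length(ar) / leaf_area_mm2
  d <- sum(net$edges$width * net$edges$length) / total_len
  a <- mean_intervein_distance(net, fc, grid_spacing, max_points)
  list(sigma = sigma, a = a, A = A, rho_A = rho_A, d = d)
}

# Mean nearest-centerline distance (mm) over a uniform grid of points
# inside the leaf outline polygon.
mean_intervein_distance <- function(net, fc, grid_spacing = NULL,
                                    max_points = 40000) {
  ox <- net$nodes$x[match(fc$outer$nodes, net$nodes$id)]
  oy <- net$nodes$y[match(fc$outer$nodes, net$nodes$id)]
  diam_mm <- 10 * sqrt(diff(range(ox))^2 + diff(range(oy))^2)
  h_mm <- grid_spacing %||% min(0.1, diam_mm / 500)
  h <- h_mm / 10                            # cm
  repeat {
    gx <- seq(min(ox) + h / 2, max(ox), by = h)
    gy <- seq(min(oy) + h / 2, max(oy), by = h)
    if (length(gx) * length(gy) <= max_points * 4) break
    h <- h * 2
  }
  pts <- expand.grid(x = gx, y = gy)
  keep <- vapply(seq_len(nrow(pts)),
                 function(i) point_in_polygon(pts$x[i], pts$y[i], ox, oy),
                 logical(1))
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > max_points) pts <- pts[seq(1, nrow(pts), length.out = max_points), ]
  if (nrow(pts) == 0) stop("no interior sample points; grid too coarse")
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(net$edges))) {
    dmin <- pmin(dmin, point_segment_distance(
      pts$x, pts$y,
      net$nodes$x[ii[k]], net$nodes$y[ii[k]],
      net$nodes$x[jj[k]], net$nodes$y[jj[k]]))
  }
  10 * mean(dmin)                           # cm -> mm
}

#' The 8-metric venation fingerprint
#'
#' Assembles the five geometric metrics, the mean topological length and
#' the two nesting numbers into a single "venation fingerprint" vector.
#' All entries are local features of the network that can also be
#' estimated from a fragment alone.
#'
#' @param net a pruned, connected `vein_network` with at least 2 facets.
#' @param max_degree subtree-degree threshold for the nesting numbers:
#'   256 for full leaves (default), 128 for fragments.
#' @param pair_weight passed to [build_nesting_tree()].
#' @param grid_spacing,max_points passed to [geometric_metrics()].
#' @return object of class `vein_fingerprint`: a named numeric vector
#'   with entries `sigma`, `a`, `A`, `rho_A`, `d`, `L_top`, `i_u`, `i_w`.
#' @export
fingerprint <- function(net, max_degree = 256, pair_weight = "min",
                        grid_spacing = NULL, max_points = 40000) {
  fc <- extract_facets(net)
  if (length(fc$facets) < 2)
    stop("fingerprint requires at least 2 facets")
  tree <- build_nesting_tree(fc, pair_weight = pair_weight,
                             edge_widths = stats::setNames(
                               net$edges$width, net$edges$id))
  geo <- geometric_metrics(net, facets = fc, grid_spacing = grid_spacing,
                           max_points = max_points)
  out <- c(sigma = geo$sigma, a = geo$a, A = geo$A, rho_A = geo$rho_A,
           d = geo$d,
           L_top = mean_topological_length(net),
           i_u = nesting_number(tree, "unweighted", max_degree),
           i_w = nesting_number(tree, "degree_weighted", max_degree))
  structure(out, class = c("vein_fingerprint", "numeric"))
}

#' @export
print.vein_fingerprint <- function(x, ...) {
  cat("vein_fingerprint:\n")
  v <- unclass(x)
  cat(sprintf("  sigma = %.4g mm/mm^2   a = %.4g mm   A = %.4g mm^2\n",
              v["sigma"], v["a"], v["A"]))
  cat(sprintf("  rho_A = %.4g /mm^2   d = %.4g mm\n", v["rho_A"], v["d"]))
  cat(sprintf("  L_top = %.4g   i_u = %.4g   i_w = %.4g\n",
              v["L_top"], v["i_u"], v["i_w"]))
  invisible(x)
}

fingerprint_metric_names <- function() {
  c("sigma", "a", "A", "rho_A", "d", "L_top", "i_u", "i_w")
}
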
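#' Fragment a network into equally sized square tiles
#'
#' Cuts a venation network in silico into an axis-aligned grid of
#' `tile_cm` x `tile_cm` tiles anchored at the lower-left corner of the
#' node bounding box (optionally shifted by a seeded random offset).
#' Every edge is clipped geometrically at the tile borders, clip points
#' becoming new boundary nodes; each tile's subnetwork is then re-pruned
#' with [prune_to_cycles()], so loops cut open at a border do not count
#' as areoles. Tiles retaining fewer than `min_areoles` facets are
#' discarded — nesting statistics are meaningless on a handful of
#' areoles.
#'
#' @param net a `vein_network`.
#' @param tile_cm tile side length in cm.
#' @param min_areoles minimum facet count for a tile to be kept.
#' @param random_offset if TRUE, shift the grid anchor by a uniform
#'   random offset in `[0, tile_cm)^2` (seeded).
#' @param seed seed for the random offset.
#' @return object of class `fragment_set`: list with `tiles` (each a list
#'   with `tile_id`, `xlim`, `ylim`, `network`, `n_areoles`) and the
#'   fragmentation settings. Empty (with a warning) if no tile survives.
#' @export
fragment_network <- function(net, tile_cm = 1.2, min_areoles = 10,
                             random_offset = FALSE, seed = 0) {
  stopifnot(tile_cm > 0)
  bx <- range(net$nodes$x); by <- range(net$nodes$y)
  off <- if (random_offset) {
    with_seed(seed, stats::runif(2, 0, tile_cm))
  } else c(0, 0)
  x_anchor <- bx[1] - off[1]
  y_anchor <- by[1] - off[2]
  nx_tiles <- ceiling((bx[2] - x_anchor) / tile_cm)
  ny_tiles <- ceiling((by[2] - y_anchor) / tile_cm)
  if (nx_tiles < 1 || ny_tiles < 1) stop("network bounding box is degenerate")
  tiles <- list()
  tid <- 0L
  for (iy in seq_len(ny_tiles) - 1L) for (ix in seq_len(nx_tiles) - 1L) {
    xlim <- x_anchor + c(ix, ix + 1) * tile_cm
    ylim <- y_anchor + c(iy, iy + 1) * tile_cm
    sub <- clip_network(net, xlim, ylim)
    if (is.null(sub)) next
    sub <- suppressWarnings(prune_to_cycles(sub))
    if (is_empty_network(sub)) next
    n_areoles <- length(extract_facets(sub)$facets)
    if (n_areoles < min_areoles) next
    tid <- tid + 1L
    tiles[[tid]] <- list(tile_id = tid, ix = ix, iy = iy,
                         xlim = xlim, ylim = ylim,
                         network = sub, n_areoles = n_areoles)
  }
  if (length(tiles) == 0)
    warning("no tile retained at least ", min_areoles, " areoles")
  structure(list(tiles = tiles, tile_cm = tile_cm,
                 min_areoles = min_areoles),
            class = "fragment_set")
}

# Clip all edges of a network to an axis-aligned box (Liang-Barsky);
# returns NULL when nothing remains.
clip_network <- function(net, xlim, ylim) {
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  x1 <- net$nodes$x[ii]; y1 <- net$nodes$y[ii]
  x2 <- net$nodes$x[jj]; y2 <- net$nodes$y[jj]
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- rep(0, length(x1)); t1 <- rep(1, length(x1))
  for (side in 1:4) {
    p <- switch(side, -dx, dx, -dy, dy)
    q <- switch(side, x1 - xlim[1], xlim[2] - x1, y1 - ylim[1], ylim[2] - y1)
    par <- p == 0
    out <- par & q < 0
    t0[out] <- 2  # mark fully outside
    r <- ifelse(par, 0, q / ifelse(p == 0, 1, p))
    ent <- !par & p < 0
    ext <- !par & p > 0
    t0[ent] <- pmax(t0[ent], r[ent])
    t1[ext] <- pmin(t1[ext], r[ext])
  }
  keep <- which(t0 < t1 - 1e-12)
  if (length(keep) == 0) return(NULL)
  cx1 <- x1[keep] + t0[keep] * dx[keep]; cy1 <- y1[keep] + t0[keep] * dy[keep]
  cx2 <- x1[keep] + t1[keep] * dx[keep]; cy2 <- y1[keep] + t1[keep] * dy[keep]
  key <- function(x, y) paste(format(x, digits = 13), format(y, digits = 13))
  kk <- c(key(cx1, cy1), key(cx2, cy2))
  ux <- c(cx1, cx2)[!duplicated(kk)]
  uy <- c(cy1, cy2)[!duplicated(kk)]
  node_id <- stats::setNames(seq_along(ux), kk[!duplicated(kk)])
  frac <- t1[keep] - t0[keep]
  edges <- data.frame(from = node_id[key(cx1, cy1)],
                      to = node_id[key(cx2, cy2)],
                      width = net$edges$width[keep],
                      length = net$edges$length[keep] * frac)
  zero <- edges$from == edges$to | edges$length <= 0
  edges <- edges[!zero, , drop = FALSE]
  if (nrow(edges) == 0) return(NULL)
  # edges sliced down to a point on the border can duplicate a pair: drop
  dup <- duplicated(paste(pmin(edges$from, edges$to),
                          pmax(edges$from, edges$to)))
  edges <- edges[!dup, , drop = FALSE]
  vein_network(data.frame(id = seq_along(ux), x = ux, y = uy), edges,
               validate = TRUE, check_crossings = FALSE)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d tiles of %.2g x %.2g cm (>= %d areoles each)\n",
              length(x$tiles), x$tile_cm, x$tile_cm, x$min_areoles))
  for (t in x$tiles)
    cat(sprintf("  tile %d [%0.2f,%0.2f]x[%0.2f,%0.2f]: %d areoles, %d edges\n",
                t$tile_id, t$xlim[1], t$xlim[2], t$ylim[1], t$ylim[2],
                t$n_areoles, nrow(t$network$edges)))
  invisible(x)
}

#' Fingerprint every fragment of a fragment set
#'
#' Computes the 8-metric fingerprint of each tile's subnetwork with the
#' fragment-mode subtree-degree threshold (`d <= 128` by default).
#'
#' @param fragments a `fragment_set`.
#' @param specimen_id,species labels copied into every row.
#' @param max_degree subtree-degree threshold for the nesting numbers.
#' @param ... passed to [fingerprint()].
#' @return data.frame with one row per tile: `specimen_id`, `species`,
#'   `tile_id`, and the 8 metric columns.
#' @export
fragment_fingerprints <- function(fragments, specimen_id = "specimen",
                                  species = "unknown", max_degree = 128, ...) {
  rows <- lapply(fragments$tiles, function(t) {
    fp <- fingerprint(t$network, max_degree = max_degree, ...)
    cbind(data.frame(specimen_id = specimen_id, species = species,
                     tile_id = t$tile_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fp))))
  })
  do.call(rbind, rows)
}
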
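#' Deterministic test networks with known ground truth
#'
#' Generators for small synthetic networks whose metrics are known in
#' closed form or by hand-trace: ladders of unit cells (caterpillar
#' nesting trees), recursively bisected squares (perfectly balanced
#' nesting trees), rectangular grids, and strictly tapering paths.
#' Coordinates are exact dyadic rationals wherever possible so that width
#' and angle comparisons involve no floating-point ties.
#'
#' @name fixtures
NULL

# Build a network from axis-aligned or general segments, inserting nodes
# where a segment endpoint lies on another segment (T-junctions). Segment
# k keeps width widths[k] across all its sub-edges; sub-edges inherit
# consecutive ids in segment order.
build_from_segments <- function(x1, y1, x2, y2, widths) {
  stopifnot(length(x1) == length(widths))
  key <- function(x, y) paste(format(x, digits = 15), format(y, digits = 15))
  px <- c(x1, x2); py <- c(y1, y2)
  kk <- key(px, py)
  uk <- !duplicated(kk)
  nodes <- data.frame(id = seq_len(sum(uk)), x = px[uk], y = py[uk])
  node_of <- stats::setNames(nodes$id, kk[uk])
  from <- to <- integer(0); wid <- numeric(0)
  for (k in seq_along(x1)) {
    on_seg <- point_segment_distance(nodes$x, nodes$y,
                                     x1[k], y1[k], x2[k], y2[k]) < 1e-9
    t <- ((nodes$x - x1[k]) * (x2[k] - x1[k]) +
          (nodes$y - y1[k]) * (y2[k] - y1[k])) /
      ((x2[k] - x1[k])^2 + (y2[k] - y1[k])^2)
    ord <- order(t[on_seg])
    chain <- nodes$id[on_seg][ord]
    from <- c(from, chain[-length(chain)])
    to <- c(to, chain[-1])
    wid <- c(wid, rep(widths[k], length(chain) - 1))
  }
  vein_network(nodes, data.frame(from = from, to = to, width = wid))
}

#' @rdname fixtures
#' @param n_cells number of unit cells in the ladder.
#' @param shared_widths widths (mm) of the `n_cells - 1` interior rungs,
#'   left to right; must all be thinner than `perimeter_width`.
#' @param perimeter_width width (mm) of the outer boundary veins.
#' @param cell_cm cell side length in cm.
#' @return a `vein_network`.
#' @export
make_ladder <- function(n_cells, shared_widths = seq_len(max(n_cells - 1, 0)),
                        perimeter_width = n_cells, cell_cm = 1) {
  stopifnot(n_cells >= 1, length(shared_widths) == n_cells - 1)
  if (n_cells > 1 && any(shared_widths >= perimeter_width))
    stop("shared widths must be thinner than the perimeter width")
  s <- cell_cm
  xs <- (0:n_cells) * s
  # perimeter: bottom, top, left, right
  x1 <- c(xs[-length(xs)], xs[-length(xs)], 0, n_cells * s)
  y1 <- c(rep(0, n_cells), rep(s, n_cells), 0, 0)
  x2 <- c(xs[-1], xs[-1], 0, n_cells * s)
  y2 <- c(rep(0, n_cells), rep(s, n_cells), s, s)
  w <- rep(perimeter_width, length(x1))
  if (n_cells > 1) {
    xi <- xs[2:n_cells]
    x1 <- c(x1, xi); y1 <- c(y1, rep(0, n_cells - 1))
    x2 <- c(x2, xi); y2 <- c(y2, rep(s, n_cells - 1))
    w <- c(w, shared_widths)
  }
  build_from_segments(x1, y1, x2, y2, w)
}

#' @rdname fixtures
#' @param depth number of bisection generations; `2^depth` areoles.
#' @param width_decay per-generation width multiplier in (0, 1):
#'   generation-g veins have width `width_decay^g` mm, the boundary
#'   (generation 0) width 1 mm, so later veins are strictly thinner.
#' @param side_cm side length of the initial square in cm.
#' @export
make_hierarchical <- function(depth, width_decay = 0.5, side_cm = 1) {
  stopifnot(depth >= 0, width_decay > 0, width_decay < 1)
  segs <- data.frame(x1 = c(0, 0, 0, side_cm),
                     y1 = c(0, side_cm, 0, 0),
                     x2 = c(side_cm, side_cm, 0, side_cm),
                     y2 = c(0, side_cm, side_cm, side_cm),
                     w = 1)
  subdivide <- function(x0, y0, x1, y1, g) {
    if (g > depth) return()
    if ((x1 - x0) >= (y1 - y0)) {          # split the longer (x) extent
      xm <- (x0 + x1) / 2
      segs <<- rbind(segs, data.frame(x1 = xm, y1 = y0, x2 = xm, y2 = y1,
                                      w = width_decay^g))
      subdivide(x0, y0, xm, y1, g + 1)
      subdivide(xm, y0, x1, y1, g + 1)
    } else {
      ym <- (y0 + y1) / 2
      segs <<- rbind(segs, data.frame(x1 = x0, y1 = ym, x2 = x1, y2 = ym,
                                      w = width_decay^g))
      subdivide(x0, y0, x1, ym, g + 1)
      subdivide(x0, ym, x1, y1, g + 1)
    }
  }
  subdivide(0, 0, side_cm, side_cm, 1)
  build_from_segments(segs$x1, segs$y1, segs$x2, segs$y2, segs$w)
}

#' @rdname fixtures
#' @param nx,ny number of cells per axis.
#' @param widths edge widths (mm): a single value, or a vector of length
#'   equal to the edge count, applied in deterministic construction order
#'   (horizontal segments row by row, then vertical segments column by
#'   column, each cut into unit edges).
#' @export
make_grid <- function(nx, ny, widths = 1, cell_cm = 1) {
  stopifnot(nx >= 1, ny >= 1)
  s <- cell_cm
  nodes <- expand.grid(ix = 0:nx, iy = 0:ny)
  nodes <- data.frame(id = seq_len(nrow(nodes)),
                      x = nodes$ix * s, y = nodes$iy * s)
  idx <- function(ix, iy) ix + 1 + (nx + 1) * iy
  from <- to <- integer(0)
  for (iy in 0:ny) for (ix in 0:(nx - 1)) {
    from <- c(from, idx(ix, iy)); to <- c(to, idx(ix + 1, iy))
  }
  for (ix in 0:nx) for (iy in 0:(ny - 1)) {
    from <- c(from, idx(ix, iy)); to <- c(to, idx(ix, iy + 1))
  }
  m <- length(from)
  if (length(widths) == 1) widths <- rep(widths, m)
  stopifnot(length(widths) == m)
  vein_network(nodes, data.frame(from = from, to = to, width = widths))
}

#' @rdname fixtures
#' @param n number of path edges.
#' @param path_widths edge widths (mm) along the path; defaults to the
#'   strictly tapering sequence `n, n-1, ..., 1`.
#' @export
make_tapered_path <- function(n, path_widths = rev(seq_len(n)), cell_cm = 1) {
  stopifnot(n >= 1, length(path_widths) == n)
  nodes <- data.frame(id = seq_len(n + 1), x = (0:n) * cell_cm, y = 0)
  vein_network(nodes, data.frame(from = seq_len(n), to = seq_len(n) + 1,
                                 width = path_widths))
}
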
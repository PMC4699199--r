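#' Extract the areoles (internal faces) of a pruned network
#'
#' Traverses the combinatorial embedding induced by the node coordinates:
#' at every node the incident edges are sorted by angle, and each directed
#' edge is followed to the rotationally next edge at its head until the
#' walk closes. Every face of the planar embedding is traced exactly once.
#' The outer face — the unique face with negative signed area under the
#' traversal orientation — is excluded from the areole list but kept as an
#' attribute (its boundary polygon is the leaf outline).
#'
#' @param net a pruned, connected `vein_network` (see [prune_to_cycles()]).
#' @return an object of class `vein_facets`: a list with elements
#'   \describe{
#'     \item{facets}{list of areoles, each a list with `id` (integer),
#'       `nodes` (boundary node ids, in traversal order), `edges`
#'       (boundary edge ids) and `area` (cm^2).}
#'     \item{outer}{the outer face in the same form, `area` holding the
#'       enclosed (leaf) area in cm^2.}
#'     \item{edge_faces}{data.frame mapping every `edge_id` to the two
#'       face indices `f1`, `f2` it borders (0 denotes the outer face).}
#'   }
#' @export
extract_facets <- function(net) {
  V <- nrow(net$nodes)
  E <- nrow(net$edges)
  if (E == 0) stop("empty network: no facets")
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  # darts 2k-1: from->to, 2k: to->from
  tail_ <- integer(2 * E); head_ <- integer(2 * E)
  tail_[seq(1, 2 * E, 2)] <- ii; head_[seq(1, 2 * E, 2)] <- jj
  tail_[seq(2, 2 * E, 2)] <- jj; head_[seq(2, 2 * E, 2)] <- ii
  ang <- atan2(net$nodes$y[head_] - net$nodes$y[tail_],
               net$nodes$x[head_] - net$nodes$x[tail_])
  ord <- order(tail_, ang)
  # rotation system: darts at each node in counterclockwise angular order
  rot_start <- c(1L, 1L + cumsum(tabulate(tail_, V)))
  pos <- integer(2 * E); pos[ord] <- seq_len(2 * E)
  # position of dart within its node block, and block bounds
  blk_of <- tail_
  idx_in_blk <- pos - rot_start[blk_of]  # 0-based
  blk_len <- tabulate(tail_, V)
  rev_ <- seq_len(2 * E) + rep(c(1L, -1L), E)
  # next dart of a face walk arriving along d: the dart clockwise-next
  # from rev(d) in the rotation at head(d)
  nxt <- integer(2 * E)
  r <- rev_
  v <- tail_[r]
  prev_idx <- (idx_in_blk[r] - 1L) %% blk_len[v]
  nxt <- ord[rot_start[v] + prev_idx]
  # trace faces
  face_of <- integer(2 * E)
  faces <- list()
  nf <- 0L
  for (d0 in seq_len(2 * E)) {
    if (face_of[d0] != 0L) next
    nf <- nf + 1L
    walk <- integer(0)
    d <- d0
    repeat {
      face_of[d] <- nf
      walk <- c(walk, d)
      d <- nxt[d]
      if (d == d0) break
      if (face_of[d] != 0L) stop("internal error: face traversal collision")
    }
    faces[[nf]] <- walk
  }
  if (nf != E - V + 2L)
    stop(sprintf(paste0("face count %d != E - V + 2 = %d: ",
                        "network must be pruned and connected"),
                 nf, E - V + 2L))
  areas <- vapply(faces, function(w) {
    polygon_signed_area(net$nodes$x[tail_[w]], net$nodes$y[tail_[w]])
  }, numeric(1))
  outer_idx <- which.min(areas)
  if (sum(areas < -1e-12 * max(abs(areas))) != 1L)
    stop("embedding error: expected exactly one outer face with negative area")
  face_edge_ids <- lapply(faces, function(w) net$edges$id[(w + 1L) %/% 2L])
  face_node_ids <- lapply(faces, function(w) net$nodes$id[tail_[w]])
  mk <- function(k, id) list(id = id, nodes = face_node_ids[[k]],
                             edges = face_edge_ids[[k]], area = abs(areas[k]))
  internal <- setdiff(seq_len(nf), outer_idx)
  # renumber internal faces 1..F in traversal order
  new_id <- integer(nf)
  new_id[internal] <- seq_along(internal)
  facets <- lapply(seq_along(internal), function(k) mk(internal[k], k))
  d1 <- seq(1, 2 * E, 2)
  edge_faces <- data.frame(edge_id = net$edges$id,
                           f1 = new_id[face_of[d1]],
                           f2 = new_id[face_of[d1 + 1L]])
  if (any(edge_faces$f1 == edge_faces$f2))
    stop("bridge edge found (same face on both sides): network must be pruned")
  structure(list(facets = facets, outer = mk(outer_idx, 0L),
                 edge_faces = edge_faces),
            class = "vein_facets")
}

#' @export
print.vein_facets <- function(x, ...) {
  ar <- vapply(x$facets, `[[`, numeric(1), "area")
  cat(sprintf("vein_facets: %d areoles, leaf area %.4g cm^2\n",
              length(x$facets), x$outer$area))
  if (length(ar))
    cat(sprintf("  areole areas [cm^2]: %.4g - %.4g (mean %.4g)\n",
                min(ar), max(ar), mean(ar)))
  invisible(x)
}

#' Areole areas of a facet set
#'
#' @param facets a `vein_facets` object.
#' @return numeric vector of areole areas in cm^2.
#' @export
areole_areas <- function(facets) {
  vapply(facets$facets, `[[`, numeric(1), "area")
}
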
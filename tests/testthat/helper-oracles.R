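# Independent oracles and random fixture generators for the test suite.

# Random small rectilinear network: a grid topology (<= 6 cells) with
# distinct random widths on every edge.
random_small_network <- function() {
  shapes <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(1, 4), c(2, 2),
                 c(1, 5), c(1, 6), c(2, 3), c(3, 2))
  sh <- shapes[[sample.int(length(shapes), 1)]]
  n_e <- sh[1] * (sh[2] + 1) + sh[2] * (sh[1] + 1)
  make_grid(sh[1], sh[2], widths = stats::runif(n_e, 0.1, 10))
}

# Brute-force hierarchical decomposition by literal edge deletion: delete
# the globally thinnest edge separating two distinct internal faces,
# re-prune the graph, re-extract the faces from scratch, and record which
# groups of original areoles merged. Tracks original areoles by their
# boundary-node centroids (interior for the rectilinear faces used in the
# tests). Returns canonical clade strings comparable to
# veintop:::tree_clades().
oracle_clades <- function(net) {
  net <- prune_to_cycles(net)
  fc0 <- extract_facets(net)
  F <- length(fc0$facets)
  centers <- t(vapply(fc0$facets, function(f) {
    nd <- unique(f$nodes)
    c(mean(net$nodes$x[match(nd, net$nodes$id)]),
      mean(net$nodes$y[match(nd, net$nodes$id)]))
  }, numeric(2)))
  clades <- character(0)
  cur <- net
  repeat {
    fc <- extract_facets(cur)
    if (length(fc$facets) <= 1) break
    ef <- fc$edge_faces
    cand <- ef$edge_id[ef$f1 > 0 & ef$f2 > 0]
    stopifnot(length(cand) > 0)
    w <- cur$edges$width[match(cand, cur$edges$id)]
    victim <- cand[order(w, cand)[1]]
    cur <- veintop:::subset_edges(cur, cur$edges$id != victim)
    cur <- suppressWarnings(prune_to_cycles(cur))
    fc2 <- extract_facets(cur)
    # locate every original areole center in the new face set
    memb <- vapply(seq_len(F), function(i) {
      for (k in seq_along(fc2$facets)) {
        f <- fc2$facets[[k]]
        if (veintop:::point_in_polygon(
              centers[i, 1], centers[i, 2],
              cur$nodes$x[match(f$nodes, cur$nodes$id)],
              cur$nodes$y[match(f$nodes, cur$nodes$id)])) return(k)
      }
      stop("oracle: center not inside any face")
    }, integer(1))
    parts <- split(seq_len(F), memb)
    parts <- parts[lengths(parts) > 1]
    clades <- unique(c(clades, vapply(parts, function(p)
      paste(sort(p), collapse = ","), character(1))))
  }
  # the root clade (all leaves) is always present once decomposition ends
  clades <- unique(c(clades, paste(seq_len(F), collapse = ",")))
  sort(clades)
}

# Memo-free greedy tapering walk, recomputed literally for each start
# edge; independent of the memoised implementation.
oracle_topological_lengths <- function(net) {
  e <- net$edges
  nb_of <- function(k) {
    which(e$from == e$from[k] | e$to == e$from[k] |
          e$from == e$to[k] | e$to == e$to[k])
  }
  vapply(seq_len(nrow(e)), function(k) {
    steps <- 0L
    cur <- k
    repeat {
      nb <- setdiff(nb_of(cur), cur)
      nb <- nb[e$width[nb] < e$width[cur]]
      if (length(nb) == 0) break
      cur <- nb[order(-e$width[nb], e$id[nb])[1]]
      steps <- steps + 1L
    }
    steps
  }, integer(1))
}

# Clade strings of the implementation's nesting tree, with leaves labelled
# by initial facet index (same labelling as oracle_clades).
impl_clades <- function(net) {
  tree <- build_nesting_tree(prune_to_cycles(net))
  sort(unique(c(veintop:::tree_clades(tree),
                paste(seq_len(tree$n_leaves), collapse = ","))))
}
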
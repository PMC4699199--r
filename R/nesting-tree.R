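#' Hierarchical loop decomposition of a pruned vein network
#'
#' Builds the binary *nesting tree* that records the hierarchy of nested
#' loops. Every areole starts as a leaf node. Repeatedly, the thinnest
#' vein segment separating two distinct current facets is found (ties are
#' broken by the smaller edge id, so the decomposition is deterministic on
#' quantized width data); the two facets merge into one, their tree
#' representatives are joined under a new internal node, and the entire
#' shared boundary between the pair is removed. Edges that end up inside a
#' merged facet separate nothing and are discarded without creating tree
#' nodes. The procedure runs until a single facet — the whole blade,
#' identified with the root — remains.
#'
#' Each internal node `j` carries the leaf counts of its larger and
#' smaller subtree (`r_j >= s_j >= 1`), the nesting ratio `q_j = s_j/r_j`,
#' the subtree degree `d_j = r_j + s_j`, and the width of the vein whose
#' removal created it. The tree depends only on the *rank order* of the
#' widths, not on their values, and is unchanged by geometric deformations
#' that preserve the embedding.
#'
#' @param net a pruned, connected `vein_network` with at least one facet,
#'   or a `vein_facets` object from [extract_facets()] (the widths are
#'   then taken from `edge_widths`).
#' @param pair_weight how to weight a facet pair that shares several
#'   boundary edges when selecting the next merge: by the thinnest shared
#'   edge (default), or by the mean or thickest one.
#' @param edge_widths optional named width vector (names = edge ids) when
#'   `net` is a `vein_facets` object.
#' @return an object of class `nesting_tree`: a list with `n_leaves`,
#'   `leaf_facet` (facet id per leaf node), and per-internal-node vectors
#'   `children` (2-column matrix of node ids, larger subtree first), `r`,
#'   `s`, `q`, `d`, `merge_width`. Node ids 1..n_leaves are leaves;
#'   internal nodes follow in merge order, the root last.
#' @export
build_nesting_tree <- function(net, pair_weight = c("min", "mean", "max"),
                               edge_widths = NULL) {
  pair_weight <- match.arg(pair_weight)
  if (inherits(net, "vein_facets")) {
    fc <- net
    if (is.null(edge_widths)) stop("edge_widths required for vein_facets input")
    widths <- edge_widths[as.character(fc$edge_faces$edge_id)]
  } else {
    fc <- extract_facets(net)
    widths <- net$edges$width[match(fc$edge_faces$edge_id, net$edges$id)]
  }
  F <- length(fc$facets)
  ef <- fc$edge_faces
  if (F < 1) stop("no facets to decompose")

  n_nodes_total <- 2L * F - 1L
  children <- matrix(NA_integer_, nrow = max(F - 1L, 0L), ncol = 2L)
  r <- s <- q <- mw <- numeric(max(F - 1L, 0L))
  leaf_count <- rep(1L, n_nodes_total)

  parent_grp <- seq_len(F)            # union-find over facets
  find <- function(i) {
    while (parent_grp[i] != i) i <- parent_grp[i]
    i
  }
  tree_rep <- seq_len(F)              # current tree node per group root
  min_leaf <- seq_len(F)              # smallest facet id per group (tie-breaks)

  active <- ef$f1 > 0L & ef$f2 > 0L   # perimeter edges never trigger merges
  eid <- ef$edge_id
  f1 <- ef$f1; f2 <- ef$f2

  k <- 0L
  n_groups <- F
  while (n_groups > 1L) {
    idx <- which(active)
    if (length(idx)) {
      g1 <- vapply(f1[idx], find, integer(1))
      g2 <- vapply(f2[idx], find, integer(1))
      sep <- g1 != g2
      # edges swallowed inside a merged facet separate nothing: drop them
      active[idx[!sep]] <- FALSE
      idx <- idx[sep]; g1 <- g1[sep]; g2 <- g2[sep]
    }
    if (length(idx) == 0L) {
      warning("facets remain that share no boundary edge (cut-vertex ",
              "junction); joining remaining groups deterministically")
      roots <- unique(vapply(seq_len(F), find, integer(1)))
      roots <- roots[order(min_leaf[roots])]
      ga <- roots[1]; gb <- roots[2]
      w_merge <- NA_real_
    } else if (pair_weight == "min") {
      best <- idx[order(widths[idx], eid[idx])[1]]
      pos <- match(best, idx)
      ga <- g1[pos]; gb <- g2[pos]
      w_merge <- widths[best]
    } else {
      pair_key <- paste(pmin(g1, g2), pmax(g1, g2))
      agg <- if (pair_weight == "mean") {
        tapply(widths[idx], pair_key, mean)
      } else {
        tapply(widths[idx], pair_key, max)
      }
      tie <- tapply(eid[idx], pair_key, min)
      best_key <- names(agg)[order(unname(agg), unname(tie))[1]]
      pos <- which(pair_key == best_key)[1]
      ga <- g1[pos]; gb <- g2[pos]
      w_merge <- unname(agg[best_key])
    }
    k <- k + 1L
    node_a <- tree_rep[ga]; node_b <- tree_rep[gb]
    la <- leaf_count[node_a]; lb <- leaf_count[node_b]
    bigger_first <- la > lb || (la == lb && min_leaf[ga] <= min_leaf[gb])
    children[k, ] <- if (bigger_first) c(node_a, node_b) else c(node_b, node_a)
    r[k] <- max(la, lb); s[k] <- min(la, lb)
    q[k] <- s[k] / r[k]
    mw[k] <- w_merge
    new_node <- F + k
    leaf_count[new_node] <- la + lb
    parent_grp[gb] <- ga
    tree_rep[ga] <- new_node
    min_leaf[ga] <- min(min_leaf[ga], min_leaf[gb])
    n_groups <- n_groups - 1L
  }
  structure(list(n_leaves = F,
                 leaf_facet = seq_len(F),
                 children = children,
                 r = r, s = s, q = q, d = r + s,
                 merge_width = mw,
                 root = if (F == 1L) 1L else 2L * F - 1L),
            class = "nesting_tree")
}

n_internal <- function(tree) tree$n_leaves - 1L

#' @export
print.nesting_tree <- function(x, ...) {
  cat(sprintf("nesting_tree: %d leaves (areoles), %d internal nodes\n",
              x$n_leaves, n_internal(x)))
  if (n_internal(x) > 0)
    cat(sprintf("  nesting ratios q: mean %.4f, range [%.4f, %.4f]\n",
                mean(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
summary.nesting_tree <- function(object, ...) {
  print(object)
  if (n_internal(object) > 0) {
    cat(sprintf("  i_u = %.4f, i_w = %.4f (no degree threshold)\n",
                nesting_number(object, "unweighted", Inf),
                nesting_number(object, "degree_weighted", Inf)))
    cat("  subtree degree d quartiles:",
        paste(signif(stats::quantile(object$d), 4), collapse = " "), "\n")
  }
  invisible(object)
}

#' Newick serialization of a nesting tree
#'
#' Child order is deterministic: the larger subtree comes first, ties
#' broken by the smallest facet id below each child. Internal node labels
#' carry the nesting ratio and subtree degree as `'q=<val>|d=<val>'`
#' (quoted, so standard Newick parsers accept them).
#'
#' @param tree a `nesting_tree`.
#' @return a single Newick string (terminated by `;`).
#' @export
nesting_tree_newick <- function(tree) {
  F <- tree$n_leaves
  lab <- function(node) {
    if (node <= F) return(sprintf("a%d", tree$leaf_facet[node]))
    k <- node - F
    ch <- tree$children[k, ]
    sprintf("(%s,%s)'q=%.6g|d=%d'", lab(ch[1]), lab(ch[2]),
            tree$q[k], as.integer(tree$d[k]))
  }
  paste0(lab(tree$root), ";")
}

#' Write a nesting tree as a Newick file
#'
#' @param tree a `nesting_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(nesting_tree_newick(tree), path)
  invisible(path)
}

# Canonical form for tree-topology comparison: the sorted list of leaf
# (facet-id) sets below each internal node.
tree_clades <- function(tree) {
  F <- tree$n_leaves
  below <- function(node) {
    if (node <= F) return(tree$leaf_facet[node])
    k <- node - F
    sort(c(below(tree$children[k, 1]), below(tree$children[k, 2])))
  }
  if (n_internal(tree) == 0) return(character(0))
  sort(vapply(seq_len(n_internal(tree)) + F,
              function(n) paste(below(n), collapse = ","), character(1)))
}

#' Compare two nesting trees topologically
#'
#' Two trees are equivalent when they induce the same set of clades
#' (leaf groupings under internal nodes), with leaves matched by facet id.
#'
#' @param a,b `nesting_tree` objects.
#' @return TRUE or FALSE.
#' @export
same_tree <- function(a, b) {
  a$n_leaves == b$n_leaves && identical(tree_clades(a), tree_clades(b))
}
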
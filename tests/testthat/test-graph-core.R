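unit_square <- function(width = 0.1) {
  vein_network(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
               data.frame(from = 1:4, to = c(2, 3, 4, 1), width = width))
}

test_that("GraphML round-trips and validates required attributes", {
  path <- tempfile(fileext = ".graphml")
  net <- unit_square()
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  # external GraphML with the documented attributes
  writeLines(c(
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="k0" for="node" attr.name="x"/>',
    '<key id="k1" for="node" attr.name="y"/>',
    '<key id="k2" for="edge" attr.name="width"/>',
    '<graph edgedefault="undirected">',
    sprintf('<node id="v%d"><data key="k0">%d</data><data key="k1">%d</data></node>',
            1:4, c(0, 1, 1, 0), c(0, 0, 1, 1)),
    sprintf('<edge source="v%d" target="v%d"><data key="k2">0.1</data></edge>',
            1:4, c(2, 3, 4, 1)),
    '</graph></graphml>'), path)
  ext <- read_network(path)
  expect_equal(nrow(ext$edges), 4)
  expect_equal(ext$edges$width, rep(0.1, 4))
  expect_equal(ext$edges$length, rep(10, 4))  # 1 cm sides in mm
  # missing width attribute is a format error
  writeLines(c(
    '<graphml><graph>',
    '<node id="a"><data key="x">0</data><data key="y">0</data></node>',
    '<node id="b"><data key="x">1</data><data key="y">0</data></node>',
    '<edge source="a" target="b"/>',
    '</graph></graphml>'), path)
  expect_error(read_network(path), "width")
})

test_that("TSV round-trips and rejects non-positive widths", {
  path <- tempfile(fileext = ".tsv")
  net <- unit_square()
  write_network(net, path, format = "tsv")
  back <- read_network(path, format = "tsv")
  expect_equal(back$edges$width, net$edges$width)
  expect_equal(back$nodes, net$nodes)
  # negative width fails validation
  writeLines(c("node_a\tnode_b\twidth", "1\t2\t-0.5"), path)
  writeLines(c("node_id\tx\ty", "1\t0\t0", "2\t1\t0"),
             sub("\\.tsv$", "_nodes.tsv", path))
  expect_error(read_network(path, format = "tsv"), "positive")
})

test_that("constructor rejects self-loops, duplicate pairs and crossings", {
  nodes <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_error(vein_network(nodes, data.frame(from = 1, to = 1, width = 1)),
               "self-loop")
  expect_error(vein_network(nodes, data.frame(from = c(1, 2), to = c(2, 1),
                                              width = 1)), "parallel")
  # two crossing diagonals with no shared node
  cross <- vein_network(nodes, data.frame(from = c(1, 2), to = c(3, 4),
                                          width = 1),
                        validate = FALSE)
  expect_error(validate_network(cross, check_crossings = TRUE), "cross")
  # a T-junction without a node is also an embedding error
  tj <- vein_network(data.frame(x = c(0, 2, 1, 1), y = c(0, 0, -1, 1)),
                     data.frame(from = c(1, 3), to = c(2, 4), width = 1),
                     validate = FALSE)
  expect_error(validate_network(tj, check_crossings = TRUE), "cross")
})

test_that("pruning keeps exactly the cycle-supported edges", {
  # square + dangling spur
  net <- vein_network(data.frame(x = c(0, 1, 1, 0, 2), y = c(0, 0, 1, 1, 0)),
                      data.frame(from = c(1, 2, 3, 4, 2), to = c(2, 3, 4, 1, 5),
                                 width = 1))
  pruned <- prune_to_cycles(net)
  expect_equal(sort(pruned$edges$id), 1:4)
  expect_false(5 %in% pruned$nodes$id)
  # a tree has no cycles at all
  tree <- vein_network(data.frame(x = c(0, 1, 2, 1), y = c(0, 0, 0, 1)),
                       data.frame(from = c(1, 2, 2), to = c(2, 3, 4), width = 1))
  expect_true(is_empty_network(prune_to_cycles(tree)))
  # two squares sharing an edge are fully cycle-supported
  two <- make_grid(2, 1)
  expect_equal(nrow(two$edges), 7)
  expect_equal(prune_to_cycles(two)$edges, two$edges)
})

test_that("pruning is idempotent and keeps the facet-richest component", {
  set.seed(11)
  for (i in 1:20) {
    net <- random_small_network()
    p1 <- prune_to_cycles(net)
    expect_equal(prune_to_cycles(p1)$edges, p1$edges)
  }
  # grid plus a distant disjoint single square: grid wins
  sq <- unit_square()
  sq$nodes$x <- sq$nodes$x + 50
  combo <- vein_network(
    rbind(make_grid(2, 2)$nodes,
          data.frame(id = 100:103, x = sq$nodes$x, y = sq$nodes$y)),
    rbind(make_grid(2, 2)$edges[, c("from", "to", "width")],
          data.frame(from = c(100, 101, 102, 103),
                     to = c(101, 102, 103, 100), width = 1)))
  expect_warning(kept <- prune_to_cycles(combo), "components")
  expect_equal(nrow(kept$edges), 12)
})

test_that("facet extraction satisfies Euler's formula and known counts", {
  fc <- extract_facets(unit_square())
  expect_length(fc$facets, 1)
  expect_equal(fc$facets[[1]]$area, 1)
  expect_equal(fc$outer$area, 1)

  grid <- make_grid(2, 2)
  fc2 <- extract_facets(grid)
  expect_length(fc2$facets, 12 - 9 + 1)
  expect_equal(areole_areas(fc2), rep(1, 4))

  expect_length(extract_facets(make_ladder(3, c(1, 2), 3))$facets, 3)

  set.seed(7)
  for (i in 1:20) {
    net <- random_small_network()
    fc <- extract_facets(net)
    expect_length(fc$facets, nrow(net$edges) - nrow(net$nodes) + 1)
    # every edge borders exactly two distinct faces
    expect_true(all(fc$edge_faces$f1 != fc$edge_faces$f2))
  }
})

test_that("facets are invariant under rigid motion and scale as k^2", {
  net <- make_grid(3, 2, widths = stats::runif(17, 0.5, 2))
  fc <- extract_facets(net)
  th <- 0.7
  rigid <- transform_coords(net, function(x, y) {
    list(x = cos(th) * x - sin(th) * y + 5, y = sin(th) * x + cos(th) * y - 2)
  })
  fcr <- extract_facets(rigid)
  expect_length(fcr$facets, length(fc$facets))
  expect_equal(sort(areole_areas(fcr)), sort(areole_areas(fc)), tolerance = 1e-10)
  k <- 2.5
  scaled <- transform_coords(net, function(x, y) list(x = k * x, y = k * y))
  expect_equal(sort(areole_areas(extract_facets(scaled))),
               k^2 * sort(areole_areas(fc)), tolerance = 1e-10)
})

test_that("disconnected or unpruned input is refused by facet extraction", {
  sq2 <- vein_network(data.frame(x = c(0, 1, 1, 0, 5, 6, 6, 5),
                                 y = c(0, 0, 1, 1, 0, 0, 1, 1)),
                      data.frame(from = c(1, 2, 3, 4, 5, 6, 7, 8),
                                 to = c(2, 3, 4, 1, 6, 7, 8, 5), width = 1))
  expect_error(extract_facets(sq2), "connected")
  spur <- vein_network(data.frame(x = c(0, 1, 1, 0, 2), y = c(0, 0, 1, 1, 0)),
                       data.frame(from = c(1, 2, 3, 4, 2),
                                  to = c(2, 3, 4, 1, 5), width = 1))
  expect_error(extract_facets(spur), "pruned|connected")
})
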
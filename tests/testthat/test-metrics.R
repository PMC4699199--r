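test_that("nesting ratios respect the subtree-degree threshold", {
  tr_bal <- build_nesting_tree(make_hierarchical(2))
  expect_equal(nesting_ratios(tr_bal, 256), c(1, 1, 1))
  tr_lad <- build_nesting_tree(make_ladder(3, c(1, 2), 3))
  expect_equal(sort(nesting_ratios(tr_lad, 256)), c(0.5, 1))
  expect_equal(nesting_ratios(tr_lad, 2), 1)
  tr_cat <- build_nesting_tree(make_ladder(4, c(1, 2, 3), 4))
  expect_equal(sort(nesting_ratios(tr_cat)), sort(c(1, 1 / 2, 1 / 3)))
  # single areole: empty multiset with a warning
  expect_warning(q0 <- nesting_ratios(build_nesting_tree(make_grid(1, 1))),
                 "no internal")
  expect_length(q0, 0)
})

test_that("nesting numbers match hand computations", {
  tr_bal <- build_nesting_tree(make_hierarchical(2))
  expect_equal(nesting_number(tr_bal, "unweighted"), 1)
  expect_equal(nesting_number(tr_bal, "degree_weighted"), 1)
  tr_cat <- build_nesting_tree(make_ladder(4, c(1, 2, 3), 4))
  expect_equal(nesting_number(tr_cat, "unweighted"), 11 / 18)
  expect_equal(nesting_number(tr_cat, "degree_weighted"), 0.5)
  # degree filter that excludes everything yields NA with a warning
  expect_warning(iu <- nesting_number(tr_cat, "unweighted", max_degree = 2 - 1e-9))
  expect_true(is.na(iu))
})

test_that("topological lengths follow the strictly-decreasing greedy walk", {
  # uniform widths: nothing strictly thinner anywhere
  expect_equal(unname(topological_lengths(make_grid(2, 2))), rep(0L, 12))
  expect_equal(mean_topological_length(make_grid(2, 2)), 0)
  # tapering path 3,2,1
  expect_equal(unname(topological_lengths(make_tapered_path(3, c(3, 2, 1)))),
               c(2L, 1L, 0L))
  expect_equal(mean_topological_length(make_tapered_path(3, c(3, 2, 1))), 1)
  # star with widths 4,3,2,1 around a hub
  star <- vein_network(
    data.frame(x = c(0, 1, 0, -1, 0), y = c(0, 0, 1, 0, -1)),
    data.frame(from = 1, to = 2:5, width = c(4, 3, 2, 1)))
  expect_equal(unname(topological_lengths(star)), c(3L, 2L, 1L, 0L))
  # closed form for a strictly tapering n-path: mean = (n-1)/2
  for (n in c(2, 5, 9)) {
    expect_equal(mean_topological_length(make_tapered_path(n)), (n - 1) / 2)
  }
})

test_that("memoised walk equals literal memo-free recomputation", {
  set.seed(12)
  for (i in 1:15) {
    net <- random_small_network()
    expect_equal(unname(topological_lengths(net)),
                 oracle_topological_lengths(net))
  }
  # including tied widths (quantized data)
  net <- make_grid(3, 2, widths = sample(rep(c(1, 2, 3), length.out = 17)))
  expect_equal(unname(topological_lengths(net)),
               oracle_topological_lengths(net))
})

test_that("geometric metrics of the unit square match closed forms", {
  sq <- make_grid(1, 1, widths = 0.1)
  g <- geometric_metrics(sq)
  expect_equal(g$sigma, 40 / 100)            # 40 mm of vein over 100 mm^2
  expect_equal(g$A, 100)                     # one 100 mm^2 areole
  expect_equal(g$rho_A, 0.01)
  expect_equal(g$d, 0.1)
  # mean nearest-boundary distance of a unit square is side/6
  expect_equal(g$a, 10 / 6, tolerance = 0.01)
})

test_that("metrics scale correctly under uniform spatial scaling", {
  set.seed(21)
  net <- make_grid(3, 2, widths = stats::runif(17, 0.3, 2))
  k <- 3
  scaled <- transform_coords(net, function(x, y) list(x = k * x, y = k * y))
  g1 <- geometric_metrics(net)
  g2 <- geometric_metrics(scaled)
  expect_equal(g2$sigma, g1$sigma / k, tolerance = 1e-10)
  expect_equal(g2$A, k^2 * g1$A, tolerance = 1e-10)
  expect_equal(g2$rho_A, g1$rho_A / k^2, tolerance = 1e-10)
  expect_equal(g2$d, g1$d, tolerance = 1e-10)
  expect_equal(g2$a, k * g1$a, tolerance = 0.02)
  expect_equal(mean_topological_length(scaled), mean_topological_length(net))
})

test_that("areole cover never exceeds the leaf area (A * rho_A <= 1)", {
  set.seed(31)
  for (i in 1:10) {
    net <- random_small_network()
    g <- geometric_metrics(net, max_points = 500)
    expect_lte(g$A * g$rho_A, 1 + 1e-12)
  }
  sim <- simulate_growth(growth_params(target_areoles = 64, seed = 14))
  g <- geometric_metrics(sim$network, max_points = 500)
  expect_lte(g$A * g$rho_A, 1 + 1e-12)
})

test_that("fingerprint assembles 8 metrics and honours rank invariance", {
  set.seed(41)
  net <- make_grid(3, 3, widths = stats::runif(24, 0.2, 3))
  fp <- fingerprint(net, max_points = 2000)
  expect_named(unclass(fp), c("sigma", "a", "A", "rho_A", "d",
                              "L_top", "i_u", "i_w"))
  expect_true(all(fp > 0))
  expect_true(fp["i_u"] <= 1 && fp["i_w"] <= 1)
  # rank-equivalent widths: topology-derived entries identical, d differs
  fp2 <- fingerprint(map_widths(net, function(w) w^2 + 1), max_points = 2000)
  expect_equal(fp2[c("L_top", "i_u", "i_w")], fp[c("L_top", "i_u", "i_w")])
  expect_false(isTRUE(all.equal(fp2[["d"]], fp[["d"]])))
  # degenerate inputs are refused
  expect_error(fingerprint(make_grid(1, 1)), "2 facets")
  expect_error(suppressWarnings(fingerprint(prune_to_cycles(
    make_tapered_path(3)))), "")
})

test_that("near-deterministic growth yields an almost perfectly nested leaf", {
  sim <- simulate_growth(growth_params(rho = 0, f_n = 0, beta = 0.001,
                                       target_areoles = 64, seed = 2))
  fp <- fingerprint(prune_to_cycles(sim$network), max_points = 1000)
  expect_gte(fp[["i_u"]], 0.95)
})
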
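test_that("KS distance matches hand cases and the reference implementation", {
  expect_equal(ks_distance(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 0)
  expect_equal(ks_distance(c(0.1, 0.2), c(0.3, 0.4)), 1)
  expect_equal(ks_distance(c(0.1, 0.3), c(0.2, 0.4)), 0.5)
  expect_error(ks_distance(numeric(0), 1), "empty")
  set.seed(8)
  for (i in 1:10) {
    x <- stats::runif(sample(3:40, 1))
    y <- stats::rbeta(sample(3:40, 1), 2, 5)
    ref <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
    expect_equal(ks_distance(x, y), ref, tolerance = 1e-12)
    expect_equal(ks_distance(x, y), ks_distance(y, x))
    expect_true(ks_distance(x, y) >= 0 && ks_distance(x, y) <= 1)
  }
})

test_that("nearest neighbors rank by KS distance with deterministic ties", {
  samples <- list(a = c(0.2, 0.4, 0.9), b = c(0.5, 0.7),
                  dup = c(0.2, 0.4, 0.9), far = c(0.01, 0.02, 0.03))
  nn <- nearest_neighbors("a", samples, k = 3)
  expect_equal(nn$id[1], "dup")
  expect_equal(nn$D_KS[1], 0)
  # brute-force check of the full ranking
  D <- vapply(c("b", "dup", "far"),
              function(id) ks_distance(samples$a, samples[[id]]), numeric(1))
  expect_equal(nn$id, names(sort(D)))
  expect_error(nearest_neighbors("a", samples, k = 5), "fewer")
  expect_error(nearest_neighbors("zz", samples, k = 1), "unknown")
})

make_feature_table <- function(n_per_class, centers, sd = 1, seed = 1) {
  set.seed(seed)
  cols <- c("sigma", "a", "A", "rho_A", "d", "L_top", "i_u", "i_w")
  rows <- lapply(seq_along(centers), function(ci) {
    X <- matrix(stats::rnorm(n_per_class * 8, mean = centers[[ci]], sd = sd),
                ncol = 8, byrow = TRUE)
    colnames(X) <- cols
    cbind(data.frame(specimen_id = sprintf("s%02d", ci),
                     species = sprintf("sp%02d", ci)),
          as.data.frame(X))
  })
  do.call(rbind, rows)
}

test_that("PCA of fingerprints: standardization, rank-1 and isotropic cases", {
  # all metrics perfect multiples of one latent factor: PC1 explains all
  set.seed(2)
  z <- stats::rnorm(40)
  tab <- as.data.frame(sapply(1:8, function(k) k * z))
  names(tab) <- c("sigma", "a", "A", "rho_A", "d", "L_top", "i_u", "i_w")
  p <- pca_fingerprints(tab)
  expect_equal(p$explained[1], 1)
  expect_equal(sum(p$explained), 1)
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  # isotropic noise: every component near 1/8
  tab2 <- as.data.frame(matrix(stats::rnorm(10000 * 8), ncol = 8))
  names(tab2) <- names(tab)
  p2 <- pca_fingerprints(tab2)
  expect_true(all(abs(p2$explained - 1 / 8) < 0.02))
  # constant column is refused by name
  tab$i_w <- 1
  expect_error(pca_fingerprints(tab), "i_w")
})

test_that("LDA cross-validation separates blobs and is honest at chance", {
  # two unit-variance blobs 10 units apart: every fold perfect
  tab <- make_feature_table(100, list(rep(0, 8), rep(10, 8)), seed = 5)
  acc <- lda_cv(tab, "specimen_id", "geometry+topology", folds = 10, seed = 1)
  expect_length(acc, 10)
  expect_equal(acc, rep(1, 10))
  # identical distributions: mean accuracy near 0.5
  tab0 <- make_feature_table(150, list(rep(0, 8), rep(0, 8)), seed = 6)
  acc0 <- lda_cv(tab0, "specimen_id", "geometry+topology", folds = 10, seed = 2)
  se <- sqrt(0.25 / 300)
  expect_lt(abs(mean(acc0) - 0.5), 3 * se)
  # reproducible for a fixed seed, different for another
  expect_identical(acc0, lda_cv(tab0, "specimen_id", folds = 10, seed = 2))
  # geometry feature set uses only the 5 geometric columns
  accg <- lda_cv(tab, "specimen_id", "geometry", folds = 10, seed = 1)
  expect_equal(accg, rep(1, 10))
})

test_that("LDA drops undersized classes and rejects degenerate tables", {
  tab <- make_feature_table(20, list(rep(0, 8), rep(5, 8)), seed = 7)
  small <- make_feature_table(3, list(rep(9, 8)), seed = 8)
  small$specimen_id <- "tiny"
  expect_warning(acc <- lda_cv(rbind(tab, small), "specimen_id", folds = 10,
                               seed = 1), "dropping")
  expect_length(acc, 10)
  one <- make_feature_table(30, list(rep(0, 8)), seed = 9)
  expect_error(lda_cv(one, "specimen_id"), "2 classes")
})

test_that("pairwise LDA reflects class separability", {
  # 3 identical-distribution classes: mean pairwise accuracy near 1/2
  tab0 <- make_feature_table(60, list(rep(0, 8), rep(0, 8), rep(0, 8)),
                             seed = 10)
  expect_lt(abs(pairwise_lda(tab0, "specimen_id", seed = 3) - 0.5), 0.08)
  # two separable classes plus one overlapping the first
  tab <- make_feature_table(40, list(rep(0, 8), rep(10, 8), rep(0.5, 8)),
                            seed = 11)
  y <- "specimen_id"
  p12 <- mean(lda_cv(tab[tab[[y]] %in% c("s01", "s02"), ], y, seed = 4))
  p13 <- mean(lda_cv(tab[tab[[y]] %in% c("s01", "s03"), ], y, seed = 4))
  expect_gt(p12, p13)
  expect_error(pairwise_lda(make_feature_table(30, list(rep(0, 8))), y), "2 classes")
})

test_that("Welch's t matches hand computation", {
  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  expect_equal(w$p, 2 * stats::pt(-abs(w$t), 4), tolerance = 1e-12)
})

test_that("fingerprint tables are validated on read", {
  path <- tempfile(fileext = ".csv")
  tab <- make_feature_table(3, list(rep(1, 8)), seed = 12)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  back <- read_fingerprint_table(path)
  expect_equal(nrow(back), 3)
  bad <- tab
  names(bad)[names(bad) == "i_u"] <- "nesting"
  utils::write.table(bad, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_fingerprint_table(path), "i_u")
  expect_error(read_fingerprint_table("no/such/file.csv"), "not found")
})
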
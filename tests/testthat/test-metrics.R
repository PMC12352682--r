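test_that("gene-wise PCC handles perfect, inverted and affine predictions", {
  truth <- cbind(a = c(1, 2, 3, 4), b = c(4, 1, 3, 2))
  expect_equal(unname(genewise_pcc(truth, truth)$per_gene_pcc), c(1, 1))
  expect_equal(unname(genewise_pcc(truth, -truth)$per_gene_pcc), c(-1, -1))
  ## affine invariance: pred = 2 * truth has PCC exactly 1
  expect_equal(unname(genewise_pcc(truth, 2 * truth)$per_gene_pcc), c(1, 1))
  r <- genewise_pcc(truth, truth + matrix(rnorm(8, sd = 1e-3), 4))
  expect_true(all(abs(r$per_gene_pcc) <= 1))
  expect_error(genewise_pcc(truth[1, , drop = FALSE], truth[1, , drop = FALSE]),
               class = "resolvst_parameter")
})

test_that("zero-variance genes are flagged and excluded from the median", {
  truth <- cbind(c(1, 2, 3), c(5, 5, 5), c(3, 1, 2))
  pred <- cbind(c(1, 2, 3), c(1, 2, 3), c(3, 1, 2))
  r <- genewise_pcc(truth, pred)
  expect_true(is.na(r$per_gene_pcc[2]))
  expect_equal(r$n_undefined, 1L)
  expect_equal(r$median_pcc, 1)
})

test_that("silhouette matches brute force and the reference implementation", {
  ## hand-enumerable line case: {0, 1} vs {10, 11}
  emb <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  ## outer points: a = 1, b = mean(10, 11) = 10.5 -> sc = 9.5/10.5
  ## inner points: a = 1, b = mean(9, 10) = 9.5  -> sc = 8.5/9.5
  expect_equal(silhouette_score(emb, lab), (9.5 / 10.5 + 8.5 / 9.5) / 2)
  expect_equal(silhouette_score(emb, lab), silhouette_oracle(emb, lab))
  set.seed(40)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    e <- matrix(rnorm(n * 2), n, 2)
    l <- sample(1:3, n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- 1:2
    expect_equal(silhouette_score(e, l), silhouette_oracle(e, l),
                 tolerance = 1e-12)
    skip_if_not_installed("cluster")
    ref <- mean(cluster::silhouette(l, dist(e))[, "sil_width"])
    ## reference treats singletons as 0 as well
    expect_equal(silhouette_score(e, l), ref, tolerance = 1e-12)
  }
})

test_that("silhouette hits its limit cases", {
  ## tight far-separated clusters -> near 1
  set.seed(41)
  e <- rbind(matrix(rnorm(20, 0, 0.01), 10), matrix(rnorm(20, 50, 0.01), 10))
  l <- rep(1:2, each = 10)
  expect_gt(silhouette_score(e, l), 0.99)
  ## random labels on one blob -> near 0
  e2 <- matrix(rnorm(200), 100, 2)
  l2 <- sample(1:2, 100, replace = TRUE)
  expect_lt(abs(silhouette_score(e2, l2)), 0.15)
  expect_error(silhouette_score(e, rep(1, 20)), class = "resolvst_parameter")
})

test_that("Davies-Bouldin matches brute force and is scale invariant", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    e <- matrix(rnorm(n * 2, sd = 2), n, 2)
    l <- sample(1:3, n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- 1:2
    db <- davies_bouldin(e, l)
    expect_equal(db, davies_bouldin_oracle(e, l), tolerance = 1e-12)
    expect_gte(db, 0)
    ## doubling all coordinates leaves the index unchanged
    expect_equal(davies_bouldin(2 * e, l), db, tolerance = 1e-12)
    ## translation invariance
    expect_equal(davies_bouldin(sweep(e, 2, c(5, -3), "+"), l), db,
                 tolerance = 1e-10)
  }
  ## zero-scatter point clusters score exactly 0
  e0 <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_equal(davies_bouldin(e0, rep(1:2, each = 3)), 0)
  ## coincident centroids are a guarded division
  expect_error(davies_bouldin(rbind(e0, e0), rep(1:4, each = 3)),
               class = "resolvst_degenerate")
})

test_that("the clustering pipeline recovers well-separated synthetic domains", {
  sim <- simulate_spots(height = 14L, width = 14L, n_genes = 6L,
                        n_domains = 2L, patterns = "domain_constant",
                        noise = "gaussian", noise_level = 0.02, seed = 43)
  cm <- cluster_metrics(t(sim$table$expr), labels = sim$domains)
  expect_gt(cm$silhouette, 0.8)
  expect_lt(cm$davies_bouldin, 0.5)
  ## k-means route is reproducible
  cm1 <- cluster_metrics(t(sim$table$expr), k = 2L, seed = 7)
  cm2 <- cluster_metrics(t(sim$table$expr), k = 2L, seed = 7)
  expect_identical(cm1$silhouette, cm2$silhouette)
})
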
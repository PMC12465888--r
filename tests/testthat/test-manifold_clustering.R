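test_that("umap embedding has the right shape and is seed-deterministic", {
  b <- make_blobs(2, 15, dim = 4, seed = 1)
  u1 <- umap_embed(b$X, n_components = 3, seed = 5)
  u2 <- umap_embed(b$X, n_components = 3, seed = 5)
  expect_identical(dim(u1$coords), c(30L, 3L))
  expect_identical(u1$coords, u2$coords)
  expect_error(umap_embed(b$X[1:2, ], n_components = 3), "at least")
})

test_that("well-separated blobs keep near-perfect neighbor purity in 3D UMAP", {
  b <- make_blobs(2, 40, dim = 6, sep = 30, seed = 2)
  u <- umap_embed(b$X, n_components = 3, seed = 1)
  nn <- snvae:::knn_indices(u$coords, 1)
  purity <- mean(b$labels[nn[, 1]] == b$labels)
  expect_gte(purity, 0.99)
})

test_that("automatic k-means matches an exhaustive silhouette scan", {
  b <- make_blobs(3, 20, dim = 4, sep = 25, seed = 3)
  cl <- cluster_cells(b$X, method = "kmeans", k = "auto", k_range = 2:6,
                      seed = 1)
  expect_identical(cl$K, 3L)
  # oracle: same scan done directly (each k fitted as the better, by total
  # within-SS, of 10 random restarts and a Ward-tree-initialized run)
  dmat <- dist(b$X)
  hc <- hclust(dmat, method = "ward.D2")
  sil <- sapply(2:6, function(k) {
    set.seed(1 + k)
    km <- kmeans(b$X, k, nstart = 10, iter.max = 100)
    lab <- cutree(hc, k)
    cent <- t(sapply(seq_len(k),
                     function(g) colMeans(b$X[lab == g, , drop = FALSE])))
    km_h <- tryCatch(kmeans(b$X, centers = cent, iter.max = 100),
                     error = function(e) NULL)
    if (!is.null(km_h) && km_h$tot.withinss < km$tot.withinss) km <- km_h
    mean(cluster::silhouette(km$cluster, dmat)[, 3])
  })
  expect_identical(cl$parameters$k, (2:6)[which.max(sil)])
  expect_equal(cl$scan$silhouette, sil, tolerance = 1e-12)
})

test_that("k-means guards and determinism", {
  b <- make_blobs(2, 5, dim = 3, sep = 20, seed = 4)
  expect_error(cluster_cells(b$X, method = "kmeans", k = 20), "exceeds")
  c1 <- cluster_cells(b$X, method = "kmeans", k = 2, seed = 3)
  c2 <- cluster_cells(b$X, method = "kmeans", k = 2, seed = 3)
  expect_identical(c1$labels, c2$labels)
  # the auto scan never evaluates k = n (silhouette undefined there)
  cl <- cluster_cells(b$X, method = "kmeans", k = "auto", k_range = 2:30,
                      seed = 1)
  expect_true(all(cl$scan$k <= nrow(b$X) - 1))
})

test_that("leiden at resolution 1 recovers well-separated blobs", {
  b <- make_blobs(4, 30, dim = 5, sep = 25, seed = 5)
  cl <- cluster_cells(b$X, method = "leiden", space = "latent",
                      resolution = 1, seed = 1)
  expect_identical(cl$K, 4L)
  expect_equal(label_accuracy(cl, b$labels), 1.0)
  # vanishing resolution collapses a connected cloud into one community
  set.seed(10)
  one_cloud <- matrix(rnorm(120 * 3), 120, 3)
  cl0 <- cluster_cells(one_cloud, method = "leiden", space = "latent",
                       resolution = 1e-9, seed = 1)
  expect_identical(cl0$K, 1L)
  # determinism
  c1 <- cluster_cells(b$X, method = "leiden", space = "umap3d", seed = 2)
  c2 <- cluster_cells(b$X, method = "leiden", space = "umap3d", seed = 2)
  expect_identical(c1$labels, c2$labels)
})

test_that("degenerate identical points yield a single cluster", {
  X <- matrix(1, 20, 3)
  cl <- cluster_cells(X, method = "leiden", space = "latent", seed = 1)
  expect_identical(cl$K, 1L)
})

test_that("silhouette behaves at its limits and guards", {
  b <- make_blobs(2, 25, dim = 4, sep = 50, seed = 6)
  expect_gt(silhouette_score(b$X, b$labels), 0.95)
  # random labels on a single blob score near zero (Monte-Carlo reference)
  set.seed(7)
  X <- matrix(rnorm(200 * 3), 200, 3)
  vals <- replicate(5, silhouette_score(X, sample(1:2, 200, TRUE)))
  expect_lt(max(abs(vals)), 0.05)
  expect_error(silhouette_score(X, rep(1, 200)), "single cluster")
})

test_that("majority-mapping accuracy follows its definition", {
  truth <- c("A", "A", "A", "A", "B", "B", "B", "B")
  # relabeled truth scores 1; splitting a true group is not penalized
  expect_equal(label_accuracy(c(2, 2, 2, 2, 1, 1, 1, 1), truth), 1.0)
  expect_equal(label_accuracy(c(1, 1, 3, 3, 2, 2, 2, 2), truth), 1.0)
  # one of 10 cells off -> 0.9
  truth10 <- rep(c("A", "B"), each = 5)
  pred10 <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  expect_equal(label_accuracy(pred10, truth10), 0.9)
  # invariance under any relabeling of predicted ids
  set.seed(8)
  pred <- sample(1:3, 30, TRUE); tr <- sample(c("x", "y"), 30, TRUE)
  base <- label_accuracy(pred, tr)
  for (i in 1:5) {
    perm <- sample(3)
    expect_equal(label_accuracy(perm[pred], tr), base)
  }
})

test_that("one-to-one matching penalizes cluster splitting", {
  truth <- rep(c("A", "B"), each = 4)
  split_pred <- c(1, 1, 3, 3, 2, 2, 2, 2)
  expect_equal(label_accuracy(split_pred, truth, method = "one_to_one"),
               6 / 8)
  expect_equal(label_accuracy(c(1, 1, 1, 1, 2, 2, 2, 2), truth,
                              method = "one_to_one"), 1.0)
})

test_that("confusion matrix columns sum to one under column normalization", {
  pred <- c(1, 1, 2, 2, 2, 3)
  truth <- c("A", "A", "B", "B", "A", "B")
  cm <- cluster_confusion(pred, truth)
  expect_equal(unname(colSums(cm)), rep(1, 3))
  raw <- cluster_confusion(pred, truth, normalize = "none")
  expect_identical(sum(raw), 6L)
})
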
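test_that("cluster pair distances equal brute-force enumeration", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5, 3)
  labels <- c(1, 1, 1, 2, 2)
  # 3 x 2 cells: 6 pairwise distances, below the k_pairs truncation
  got <- cluster_pair_distances(X, labels, k_pairs = 100)
  ref <- pair_dist_oracle(X[1:3, ], X[4:5, ], 100)
  expect_equal(got$d[1, 2], ref, tolerance = 1e-12)
  expect_equal(got$d, t(got$d))
  expect_equal(diag(got$d), c(0, 0), ignore_attr = TRUE)
  # truncation active: |p| * |q| > k_pairs
  set.seed(2)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  lab2 <- rep(1:2, each = 30)  # 900 pairs
  got2 <- cluster_pair_distances(Y, lab2, k_pairs = 100)
  ref2 <- pair_dist_oracle(Y[1:30, ], Y[31:60, ], 100)
  expect_equal(got2$d[1, 2], ref2, tolerance = 1e-12)
  # two singleton clusters: their single distance
  got3 <- cluster_pair_distances(X[1:2, ], c(1, 2))
  expect_equal(got3$d[1, 2], sqrt(sum((X[1, ] - X[2, ])^2)),
               tolerance = 1e-12)
})

test_that("greedy joining equals the exhaustive minimum spanning tree", {
  # hand case: d(A,B)=1, d(B,C)=2, d(A,C)=3 -> edges A-B, B-C, length 3
  dm <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)
  cd <- structure(list(d = dm, sizes = c(1, 1, 1), k_pairs = 100,
                       cluster_ids = 1:3), class = "snv_cluster_dist")
  tr <- cluster_tree(cd, kind = "multifurcating")
  expect_identical(edge_key(tr$edges$from, tr$edges$to),
                   edge_key(c(1, 2), c(2, 3)))
  expect_equal(sum(tr$edges$length), 3)

  # random distance matrices, K in 3..6, against exhaustive enumeration
  set.seed(3)
  for (trial in 1:100) {
    K <- sample(3:6, 1)
    P <- matrix(runif(K * 2) * 10, K, 2)
    dm <- as.matrix(dist(P))
    cd <- structure(list(d = dm, sizes = rep(1, K), k_pairs = 100,
                         cluster_ids = seq_len(K)),
                    class = "snv_cluster_dist")
    tr <- cluster_tree(cd, kind = "multifurcating")
    ref <- mst_oracle(dm)
    expect_equal(sum(tr$edges$length), ref$weight, tolerance = 1e-10)
    expect_identical(nrow(tr$edges), K - 1L)
  }
})

test_that("tree contract: connected, acyclic, deterministic tie-breaks", {
  # equal distances: tie-break yields identical output across runs
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  cd <- structure(list(d = dm, sizes = rep(2, 4), k_pairs = 100,
                       cluster_ids = 1:4), class = "snv_cluster_dist")
  t1 <- cluster_tree(cd, kind = "multifurcating")
  t2 <- cluster_tree(cd, kind = "multifurcating")
  expect_identical(t1$edges, t2$edges)
  # smallest-index pairs win the ties
  expect_identical(edge_key(t1$edges$from, t1$edges$to),
                   edge_key(c(1, 1, 1), c(2, 3, 4)))
  g <- igraph::graph_from_data_frame(t1$edges[, 1:2], directed = FALSE)
  # connected with K - 1 edges <=> a tree (acyclic)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), 3, ignore_attr = TRUE)
  # total length is invariant under cluster relabeling
  perm <- c(3, 1, 4, 2)
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  labels <- rep(1:4, each = 10)
  t_orig <- cluster_tree(X, labels, kind = "multifurcating")
  t_perm <- cluster_tree(X, perm[labels], kind = "multifurcating")
  expect_equal(sum(t_orig$edges$length), sum(t_perm$edges$length),
               tolerance = 1e-12)
  # non-finite distances are rejected
  dm_bad <- dm; dm_bad[1, 2] <- dm_bad[2, 1] <- Inf
  cd$d <- dm_bad
  expect_error(cluster_tree(cd, kind = "multifurcating"), "non-finite")
})

test_that("bifurcating dendrogram reproduces ultrametric inputs", {
  # ultrametric: heights 1 (A,B), 1 (C,D), 2 for the root join
  dm <- matrix(2, 4, 4)
  dm[1, 2] <- dm[2, 1] <- 1
  dm[3, 4] <- dm[4, 3] <- 1
  diag(dm) <- 0
  cd <- structure(list(d = dm, sizes = rep(1, 4), k_pairs = 100,
                       cluster_ids = 1:4), class = "snv_cluster_dist")
  tr <- cluster_tree(cd, kind = "bifurcating")
  coph <- as.matrix(cophenetic(tr$hclust))
  expect_equal(unname(coph), unname(dm), tolerance = 1e-12)
  # Newick round-trips through ape with 4 leaves
  phy <- ape::read.tree(text = tree_newick(tr))
  expect_identical(ape::Ntip(phy), 4L)
  # 2 clusters: a single join at their distance
  cd2 <- structure(list(d = matrix(c(0, 5, 5, 0), 2), sizes = c(1, 1),
                        k_pairs = 100, cluster_ids = 1:2),
                   class = "snv_cluster_dist")
  tr2 <- cluster_tree(cd2, kind = "bifurcating")
  expect_equal(tr2$hclust$height, 5)
})

test_that("abundance overlay rows sum to one and match hand computation", {
  labels <- c(1, 1, 2, 2, 2, 3)
  cats <- c("T", "B", "T", "T", "B", "B")
  X <- matrix(rnorm(12), 6, 2)
  tr <- cluster_tree(X, labels, kind = "multifurcating")
  ab <- tree_abundance_overlay(tr, labels, cats)
  expect_equal(unname(rowSums(ab)), c(1, 1))
  expect_equal(ab["T", ], c(`1` = 1 / 3, `2` = 2 / 3, `3` = 0))
  expect_equal(ab["B", ], c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3))
  # single-category data distribute as the cluster sizes
  ab1 <- tree_abundance_overlay(tr, labels, rep("only", 6))
  expect_equal(unname(ab1[1, ]), c(2, 3, 1) / 6)
})

test_that("a chain of clones is recovered exactly by the latent-space tree", {
  # sequential subclonal evolution: each clone descends from the previous
  sim <- simulate_lineages(c(NA, 1, 2, 3, 4), cells_per_clone = 200,
                           n_private_snvs = c(6, 10, 10, 10, 10),
                           n_noise_snvs = 10, het_af_range = c(0.4, 0.9),
                           depth_mean = 20, seed = 1)
  m <- snv_vae(sim$counts, seed = 1)
  tr <- cluster_tree(m, sim$labels, kind = "multifurcating")
  expect_identical(edge_key(tr$edges$from, tr$edges$to),
                   edge_key(sim$tree$edges$from, sim$tree$edges$to))
})
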
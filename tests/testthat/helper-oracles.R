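# Fixture builders and independent oracles, deliberately coded without
# reference to the package internals they check.

# tiny allele-counts fixture with reproducible random contents
random_counts <- function(n_cells, n_snps, depth_mean = 3, seed = 1) {
  set.seed(seed)
  D <- matrix(rpois(n_cells * n_snps, depth_mean), n_cells, n_snps)
  A <- matrix(rbinom(n_cells * n_snps, size = as.vector(D), prob = 0.4),
              n_cells, n_snps)
  allele_counts(A, D)
}

# two-group one-way ANOVA through R's linear-model machinery: group 1 is the
# cluster's observed cells, group 2 the bulk (all observed cells, duplicated)
anova_oracle <- function(af_values, cluster_mask, observed_mask = NULL) {
  if (is.null(observed_mask)) observed_mask <- rep(TRUE, length(af_values))
  y <- c(af_values[observed_mask & cluster_mask], af_values[observed_mask])
  g <- factor(rep(c("cluster", "bulk"),
                  c(sum(observed_mask & cluster_mask), sum(observed_mask))))
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
}

# exhaustive minimum spanning tree: try every (K-1)-subset of edges
mst_oracle <- function(dm) {
  K <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  best <- NULL; best_w <- Inf
  for (comb in utils::combn(nrow(pairs), K - 1, simplify = FALSE)) {
    e <- pairs[comb, , drop = FALSE]
    parent <- seq_len(K)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(e))) {
      ra <- find(e[r, 1]); rb <- find(e[r, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    w <- sum(dm[e])
    if (w < best_w) { best_w <- w; best <- e }
  }
  list(weight = best_w, edges = best)
}

# brute-force shortest-k average distance between two point sets
pair_dist_oracle <- function(Xp, Xq, k_pairs) {
  d <- numeric(0)
  for (i in seq_len(nrow(Xp))) {
    for (j in seq_len(nrow(Xq))) {
      d <- c(d, sqrt(sum((Xp[i, ] - Xq[j, ])^2)))
    }
  }
  d <- sort(d)
  mean(d[seq_len(min(k_pairs, length(d)))])
}

# canonical edge set of a tree over labeled nodes, for topology comparison
edge_key <- function(from, to) {
  sort(paste(pmin(from, to), pmax(from, to), sep = "-"))
}

# well-separated Gaussian blobs for clustering tests
make_blobs <- function(k, n_per, dim = 5, sep = 20, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k, dim) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * dim), n_per, dim), 2, centers[i, ], "+")
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}
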
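# Clustering of cells with similar genotypes in the latent space, plus the
# evaluation metrics used for benchmarking against ground-truth labels.
#
# Two methods: k-means (k chosen automatically by maximal mean silhouette
# over a scan range) on the full-dimensional latent space, and Leiden
# community detection on a k-nearest-neighbor graph built on a 3D UMAP of
# the latent space (resolution 1 by default).

latent_matrix <- function(x) {
  if (inherits(x, "snv_vae")) return(x$embedding$mu)
  if (inherits(x, "snv_embedding")) return(x$mu)
  if (inherits(x, "snv_umap")) return(x$coords)
  as.matrix(x)
}

cells_of <- function(x) {
  if (inherits(x, "snv_vae")) return(x$cells)
  if (inherits(x, "snv_embedding")) return(x$cells)
  if (inherits(x, "snv_umap")) return(x$cells)
  rownames(as.matrix(x))
}

#' UMAP embedding of the latent space
#'
#' 2D embeddings are used for visualization, 3D embeddings as the default
#' space for graph-based (Leiden) clustering. Deterministic for a fixed seed
#' (single-threaded layout).
#'
#' @param x a fitted [snv_vae], an `snv_embedding`, or a numeric matrix of
#'   per-cell coordinates.
#' @param n_components 2 or 3.
#' @param n_neighbors UMAP neighborhood size (default 15, clamped to
#'   `n_cells - 1`).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed integer seed.
#' @return An object of class `snv_umap`: list with `coords`
#'   (cells x n_components) and `parameters`.
#' @export
umap_embed <- function(x, n_components = 2, n_neighbors = 15,
                       min_dist = 0.1, seed = 1) {
  X <- latent_matrix(x)
  if (!n_components %in% c(2L, 3L)) stop_snvae("n_components must be 2 or 3")
  n <- nrow(X)
  if (n < n_components + 1) {
    stop_snvae("need at least ", n_components + 1, " cells for a ",
               n_components, "D embedding, got ", n)
  }
  nb <- max(2L, min(as.integer(n_neighbors), n - 1L))
  set.seed(seed)
  coords <- uwot::umap(X, n_components = n_components, n_neighbors = nb,
                       min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  structure(list(coords = coords, cells = cells_of(x),
                 parameters = list(n_components = n_components,
                                   n_neighbors = nb, min_dist = min_dist,
                                   seed = seed)),
            class = "snv_umap")
}

#' @export
print.snv_umap <- function(x, ...) {
  cat("snv_umap: ", nrow(x$coords), " cells x ", ncol(x$coords),
      " components (n_neighbors=", x$parameters$n_neighbors, ")\n", sep = "")
  invisible(x)
}

# k nearest neighbors (excluding self) by chunked exact Euclidean search
knn_indices <- function(X, k, chunk = 512L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances of chunk rows to all points
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Cluster cells on the latent manifold
#'
#' `method = "leiden"` (the default) builds a k-nearest-neighbor graph on a
#' 3D UMAP of the latent space and runs Leiden community detection with the
#' modularity objective at the given resolution. `method = "kmeans"` runs
#' k-means on the full-dimensional latent space; with `k = "auto"` every k in
#' `k_range` is fitted and the assignment with maximal mean silhouette is
#' returned (ties broken toward the smallest k).
#'
#' @param x a fitted [snv_vae], an `snv_embedding`, an `snv_umap`, or a
#'   numeric matrix.
#' @param method `"leiden"` or `"kmeans"`.
#' @param space `"umap3d"` (default for Leiden) or `"latent"` (default for
#'   k-means).
#' @param k number of k-means clusters, or `"auto"`.
#' @param k_range candidate k values for the automatic scan (default 2..30,
#'   clamped to `n_cells - 1`).
#' @param resolution Leiden resolution (default 1), or `"auto"` to select the
#'   resolution maximizing the mean silhouette over `resolution_grid` (the
#'   graph-clustering analog of the automatic k rule; coarsest wins ties).
#' @param resolution_grid candidate resolutions for `resolution = "auto"`.
#' @param n_neighbors neighborhood size for the kNN graph and the UMAP.
#' @param seed integer seed (UMAP layout, k-means starts, Leiden refinement).
#' @param umap optionally, a precomputed 3D `snv_umap` to reuse.
#' @return An object of class `snv_clusters`: integer `labels` in `1..K`,
#'   `K`, `method`, `space`, `parameters`, `cells`, and for the automatic
#'   scan a `scan` data.frame of (k, silhouette).
#' @export
cluster_cells <- function(x, method = c("leiden", "kmeans"), space = NULL,
                          k = "auto", k_range = 2:30, resolution = 1,
                          resolution_grid = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                              0.5, 1, 2),
                          n_neighbors = 15, seed = 1, umap = NULL) {
  method <- match.arg(method)
  if (is.null(space)) space <- if (method == "leiden") "umap3d" else "latent"
  space <- match.arg(space, c("umap3d", "latent"))
  cells <- cells_of(x)
  if (space == "umap3d") {
    if (is.null(umap)) umap <- umap_embed(x, n_components = 3,
                                          n_neighbors = n_neighbors,
                                          seed = seed)
    S <- umap$coords
  } else {
    S <- latent_matrix(x)
  }
  n <- nrow(S)
  if (method == "kmeans") {
    res <- kmeans_auto(S, k, k_range, seed)
    labels <- res$labels; params <- res$parameters; scan <- res$scan
  } else if (identical(resolution, "auto")) {
    sil <- rep(NA_real_, length(resolution_grid))
    fits <- vector("list", length(resolution_grid))
    dmat <- stats::dist(S)
    for (i in seq_along(resolution_grid)) {
      fits[[i]] <- leiden_knn(S, resolution_grid[i], n_neighbors, seed)
      if (length(unique(fits[[i]]$labels)) < 2) next
      sil[i] <- mean(cluster::silhouette(as.integer(factor(fits[[i]]$labels)),
                                         dmat)[, 3])
    }
    if (all(is.na(sil))) {
      # every resolution collapsed to one community
      labels <- fits[[1]]$labels
      best <- 1L
    } else {
      best <- which.max(sil)  # first maximum = coarsest resolution on ties
      labels <- fits[[best]]$labels
    }
    params <- list(resolution = resolution_grid[best],
                   n_neighbors = n_neighbors, seed = seed,
                   selected = "silhouette")
    scan <- data.frame(resolution = resolution_grid, silhouette = sil)
  } else {
    res <- leiden_knn(S, resolution, n_neighbors, seed)
    labels <- res$labels
    params <- list(resolution = resolution, n_neighbors = n_neighbors,
                   seed = seed)
    scan <- NULL
  }
  structure(list(labels = as.integer(labels), K = length(unique(labels)),
                 method = method, space = space, parameters = params,
                 scan = scan, cells = cells),
            class = "snv_clusters")
}

# One k-means fit: the better (by total within-SS) of 10 random restarts and
# a run initialized from Ward-tree centroids. High-dimensional latent spaces
# give k-means hard local optima; the deterministic hierarchical start
# reliably lands in the basin of the cluster structure.
kmeans_fit <- function(S, k, seed, hc = NULL) {
  set.seed(seed + k)
  fit <- suppressWarnings(stats::kmeans(S, centers = k, nstart = 10,
                                        iter.max = 100))
  if (!is.null(hc)) {
    lab <- stats::cutree(hc, k)
    if (length(unique(lab)) == k) {
      cent <- t(sapply(seq_len(k),
                       function(g) colMeans(S[lab == g, , drop = FALSE])))
      fit_h <- tryCatch(
        suppressWarnings(stats::kmeans(S, centers = cent, iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(fit_h) && fit_h$tot.withinss < fit$tot.withinss) {
        fit <- fit_h
      }
    }
  }
  fit
}

kmeans_auto <- function(S, k, k_range, seed) {
  n <- nrow(S)
  if (identical(k, "auto")) {
    ks <- k_range[k_range >= 2 & k_range <= n - 1]
    if (!length(ks)) stop_snvae("no valid k in k_range for ", n, " cells")
    dmat <- stats::dist(S)
    hc <- stats::hclust(dmat, method = "ward.D2")
    sil <- rep(NA_real_, length(ks))
    fits <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      fits[[i]] <- kmeans_fit(S, ks[i], seed, hc)
      # a k-means fit can return fewer than k non-empty clusters; silhouette
      # needs at least 2 distinct labels
      if (length(unique(fits[[i]]$cluster)) < 2) next
      sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, dmat)[, 3])
    }
    if (all(is.na(sil))) stop_snvae("silhouette undefined for every k scanned")
    best <- which.max(sil)  # first maximum = smallest k on ties
    list(labels = fits[[best]]$cluster,
         parameters = list(k = ks[best], seed = seed, selected = "silhouette"),
         scan = data.frame(k = ks, silhouette = sil))
  } else {
    k <- as.integer(k)
    if (k > n) stop_snvae("k = ", k, " exceeds the number of cells (", n, ")")
    hc <- if (n <= 5000) stats::hclust(stats::dist(S), method = "ward.D2")
    fit <- kmeans_fit(S, k, seed, hc)
    list(labels = fit$cluster, parameters = list(k = k, seed = seed),
         scan = NULL)
  }
}

leiden_knn <- function(S, resolution, n_neighbors, seed) {
  n <- nrow(S)
  if (n < 2 || nrow(unique(S)) == 1) {
    # degenerate: all points identical
    return(list(labels = rep(1L, n)))
  }
  nn <- knn_indices(S, n_neighbors)
  edges <- cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  list(labels = igraph::membership(cl))
}

#' @export
print.snv_clusters <- function(x, ...) {
  cat("snv_clusters: ", length(x$labels), " cells in ", x$K, " clusters (",
      x$method, " on ", x$space, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Mean silhouette score of a labeling
#'
#' Per cell, `(b - a) / max(a, b)` with `a` the mean distance to cells with
#' the same label and `b` the mean distance to the nearest other label;
#' averaged over cells. Used as the compactness metric for latent embeddings
#' of ground-truth labels.
#'
#' @param x a fitted [snv_vae], an `snv_embedding`/`snv_umap`, or a matrix.
#' @param labels per-cell labels (any atomic type, at least 2 distinct).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  S <- latent_matrix(x)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(S)) stop_snvae("labels length != cell count")
  if (length(unique(labels)) < 2) {
    stop_snvae("silhouette is undefined for a single cluster")
  }
  mean(cluster::silhouette(labels, stats::dist(S))[, 3])
}

#' Clustering accuracy against ground-truth labels
#'
#' `method = "majority"` (default) maps every predicted cluster to its most
#' frequent ground-truth label and scores the fraction of cells whose mapped
#' label matches the truth; splitting one true group over several clusters is
#' not penalized, matching how confusion matrices are read in
#' donor-demultiplexing benchmarks. `method = "one_to_one"` forces an
#' optimal one-to-one cluster-to-label assignment instead.
#'
#' @param predicted an `snv_clusters` object or an atomic label vector.
#' @param truth ground-truth labels, same length.
#' @param method `"majority"` or `"one_to_one"`.
#' @return accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(predicted, truth,
                           method = c("majority", "one_to_one")) {
  method <- match.arg(method)
  pred <- if (inherits(predicted, "snv_clusters")) predicted$labels else
    predicted
  if (length(pred) != length(truth)) {
    stop_snvae("predicted and truth have different lengths")
  }
  tab <- table(pred, truth)
  if (method == "majority") {
    sum(apply(tab, 1, max)) / length(pred)
  } else {
    best_assignment_score(unclass(tab)) / length(pred)
  }
}

# Exact maximum-weight one-to-one assignment by bitmask dynamic programming
# over the smaller dimension (fine for the cluster counts seen here).
best_assignment_score <- function(M) {
  if (nrow(M) < ncol(M)) M <- t(M)
  nr <- nrow(M); nc <- ncol(M)
  if (nc > 20) stop_snvae("one_to_one matching supports at most 20 labels")
  full <- bitwShiftL(1L, nc)
  dp <- rep(-Inf, full); dp[1] <- 0
  for (i in seq_len(nr)) {
    ndp <- dp  # row i may be left unassigned
    for (mask in 0:(full - 1)) {
      if (!is.finite(dp[mask + 1])) next
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0) {
          nm <- bitwOr(mask, bit)
          cand <- dp[mask + 1] + M[i, j]
          if (cand > ndp[nm + 1]) ndp[nm + 1] <- cand
        }
      }
    }
    dp <- ndp
  }
  max(dp)
}

#' Confusion matrix between predicted clusters and ground-truth labels
#'
#' @param predicted an `snv_clusters` object or a label vector.
#' @param truth ground-truth labels.
#' @param normalize `"column"` (each predicted cluster's column sums to 1,
#'   the convention of the demultiplexing benchmarks) or `"none"`.
#' @return matrix with true labels as rows and predicted clusters as columns.
#' @export
cluster_confusion <- function(predicted, truth,
                              normalize = c("column", "none")) {
  normalize <- match.arg(normalize)
  pred <- if (inherits(predicted, "snv_clusters")) predicted$labels else
    predicted
  tab <- unclass(table(truth = truth, predicted = pred))
  if (normalize == "column") {
    cs <- colSums(tab)
    cs[cs == 0] <- 1
    tab <- sweep(tab, 2, cs, "/")
  }
  tab
}
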
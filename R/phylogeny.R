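# Cluster-level phylogeny in the full-dimensional latent space.
#
# Cluster pair distances are the mean of the shortest k (default 100)
# Euclidean distances between the posterior-mean vectors of cells in the two
# clusters. The multifurcating tree joins cluster pairs greedily in order of
# increasing distance, skipping joins that would close a cycle, until all
# clusters form one acyclic connected graph — i.e. a minimum spanning tree
# of the cluster distance graph. The bifurcating tree is an average-linkage
# dendrogram on the same distances, exportable as Newick.

#' Average shortest cell-pair distances between clusters
#'
#' Entry (p, q) is the mean of the `min(k_pairs, n_p * n_q)` smallest
#' Euclidean distances between latent posterior means of cells in cluster p
#' and cells in cluster q.
#'
#' @param x a fitted [snv_vae], an `snv_embedding`, or a matrix of per-cell
#'   latent coordinates.
#' @param clusters an `snv_clusters` object or label vector.
#' @param k_pairs number of shortest pairs averaged (default 100).
#' @return An object of class `snv_cluster_dist`: list with `d` (K x K
#'   symmetric matrix, zero diagonal, cluster ids as dimnames), `sizes`
#'   (cells per cluster) and `k_pairs`.
#' @export
cluster_pair_distances <- function(x, clusters, k_pairs = 100) {
  X <- latent_matrix(x)
  labels <- if (inherits(clusters, "snv_clusters")) clusters$labels else
    clusters
  if (length(labels) != nrow(X)) stop_snvae("labels length != cell count")
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2) stop_snvae("need at least 2 clusters")
  idx <- lapply(ks, function(k) which(labels == k))
  dm <- matrix(0, K, K, dimnames = list(ks, ks))
  for (p in seq_len(K - 1)) {
    Xp <- X[idx[[p]], , drop = FALSE]
    sp <- rowSums(Xp^2)
    for (q in (p + 1):K) {
      Xq <- X[idx[[q]], , drop = FALSE]
      d2 <- outer(sp, rowSums(Xq^2), "+") - 2 * tcrossprod(Xp, Xq)
      d <- sqrt(pmax(d2, 0))
      m <- min(k_pairs, length(d))
      val <- mean(sort(as.vector(d), partial = m)[seq_len(m)])
      dm[p, q] <- dm[q, p] <- val
    }
  }
  structure(list(d = dm, sizes = lengths(idx), k_pairs = k_pairs,
                 cluster_ids = ks),
            class = "snv_cluster_dist")
}

#' @export
print.snv_cluster_dist <- function(x, ...) {
  cat("snv_cluster_dist: ", nrow(x$d), " clusters, mean of shortest ",
      x$k_pairs, " cell-pair distances\n", sep = "")
  print(round(x$d, 3))
  invisible(x)
}

#' Cluster phylogeny from latent-space distances
#'
#' `kind = "multifurcating"` (default) greedily inserts cluster-pair edges in
#' ascending distance order, skipping any edge that would close a cycle,
#' until the K clusters form one connected acyclic graph with K - 1 edges
#' (ties broken deterministically by the smaller cluster-index pair).
#' `kind = "bifurcating"` builds an agglomerative dendrogram on the distance
#' matrix (average linkage by default), serializable as Newick via
#' [tree_newick()].
#'
#' @param dist an `snv_cluster_dist` from [cluster_pair_distances()], or a
#'   fitted [snv_vae]/matrix (in which case `clusters` must be given and the
#'   distances are computed first).
#' @param clusters an `snv_clusters` object or label vector; only needed when
#'   `dist` is not already an `snv_cluster_dist`.
#' @param kind `"multifurcating"` or `"bifurcating"`.
#' @param k_pairs passed to [cluster_pair_distances()] when distances are
#'   computed here.
#' @param linkage hierarchical linkage for the bifurcating tree (default
#'   `"average"`).
#' @return An object of class `snv_tree`: `kind`, `edges` (data.frame
#'   `from`, `to`, `length` — for the bifurcating kind the `hclust` merge
#'   expressed as edges from internal nodes), `sizes`, and for the
#'   bifurcating kind the `hclust` object and its Newick string.
#' @export
cluster_tree <- function(dist, clusters = NULL,
                         kind = c("multifurcating", "bifurcating"),
                         k_pairs = 100, linkage = "average") {
  kind <- match.arg(kind)
  if (!inherits(dist, "snv_cluster_dist")) {
    if (is.null(clusters)) stop_snvae("clusters must be supplied when dist ",
                                      "is not an snv_cluster_dist")
    dist <- cluster_pair_distances(dist, clusters, k_pairs = k_pairs)
  }
  dm <- dist$d
  if (any(!is.finite(dm))) stop_snvae("non-finite cluster distances")
  K <- nrow(dm)
  if (kind == "multifurcating") {
    edges <- greedy_acyclic_join(dm)
    edges$from <- dist$cluster_ids[edges$from]
    edges$to <- dist$cluster_ids[edges$to]
    structure(list(kind = kind, edges = edges, sizes = dist$sizes,
                   cluster_ids = dist$cluster_ids),
              class = "snv_tree")
  } else {
    hc <- stats::hclust(stats::as.dist(dm), method = linkage)
    hc$labels <- as.character(dist$cluster_ids)
    phy <- ape::as.phylo(hc)
    edges <- data.frame(from = phy$edge[, 1], to = phy$edge[, 2],
                        length = phy$edge.length)
    structure(list(kind = kind, edges = edges, sizes = dist$sizes,
                   cluster_ids = dist$cluster_ids, hclust = hc,
                   phylo = phy, newick = ape::write.tree(phy)),
              class = "snv_tree")
  }
}

# Greedy ascending-edge insertion with cycle skipping (Kruskal): ties broken
# by (smaller first index, smaller second index).
greedy_acyclic_join <- function(dm) {
  K <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  ord <- order(dm[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  edges <- data.frame(from = integer(0), to = integer(0), length = numeric(0))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      edges <- rbind(edges, data.frame(from = a, to = b,
                                       length = dm[a, b]))
      if (nrow(edges) == K - 1) break
    }
  }
  edges
}

#' Newick serialization of a bifurcating cluster tree
#'
#' @param tree an `snv_tree` of kind `"bifurcating"`.
#' @return Newick string.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "snv_tree"))
  if (tree$kind != "bifurcating") {
    stop_snvae("Newick export is defined for the bifurcating dendrogram")
  }
  tree$newick
}

#' Relative abundance of cell categories across tree nodes
#'
#' For each cluster node and each metadata category (e.g. cell type or
#' sampling time), the fraction of that category's cells falling in the
#' cluster; each category's row sums to 1 over clusters. Used to color
#' relative abundance on the phylogeny.
#'
#' @param tree an `snv_tree`.
#' @param clusters an `snv_clusters` object or label vector.
#' @param categories per-cell metadata labels.
#' @return matrix (categories x clusters) of relative abundances.
#' @export
tree_abundance_overlay <- function(tree, clusters, categories) {
  labels <- if (inherits(clusters, "snv_clusters")) clusters$labels else
    clusters
  if (length(labels) != length(categories)) {
    stop_snvae("categories length != cell count")
  }
  tab <- unclass(table(category = categories, cluster = labels))
  tot <- rowSums(tab)
  tot[tot == 0] <- 1
  out <- sweep(tab, 1, tot, "/")
  # ensure every tree node appears, even if empty for all categories
  missing_cl <- setdiff(as.character(tree$cluster_ids), colnames(out))
  if (length(missing_cl)) {
    out <- cbind(out, matrix(0, nrow(out), length(missing_cl),
                             dimnames = list(NULL, missing_cl)))
  }
  out[, as.character(tree$cluster_ids), drop = FALSE]
}

#' @export
print.snv_tree <- function(x, ...) {
  cat("snv_tree (", x$kind, "): ", length(x$cluster_ids), " clusters, ",
      nrow(x$edges), " edges, total length ",
      format(sum(x$edges$length), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot a cluster phylogeny
#'
#' Multifurcating trees are drawn as a graph with node sizes proportional to
#' cluster cell counts and edges labeled by latent-space distance;
#' bifurcating trees as a dendrogram.
#'
#' @param x an `snv_tree`.
#' @param ... passed to the underlying plot call.
#' @export
plot.snv_tree <- function(x, ...) {
  if (x$kind == "bifurcating") {
    plot(x$hclust, xlab = "cluster", sub = "", ...)
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    x$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = x$cluster_ids))
  sizes <- x$sizes / max(x$sizes)
  set.seed(1)
  igraph::plot.igraph(
    g, vertex.size = 10 + 25 * sizes,
    vertex.label = x$cluster_ids,
    edge.label = format(x$edges$length, digits = 3),
    layout = igraph::layout_with_fr(g), ...)
  invisible(x)
}

#' Write a tree's edge list as TSV
#'
#' @param tree an `snv_tree`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_tree_edges <- function(tree, file) {
  stopifnot(inherits(tree, "snv_tree"))
  write_tsv(data.frame(cluster_a = tree$edges$from,
                       cluster_b = tree$edges$to,
                       length = tree$edges$length), file)
}
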
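# Ranking of informative SNPs against cluster labels.
#
# For each SNP and each cluster, a one-way ANOVA F-test compares the smoothed
# allele frequencies of the observed cells in the cluster (group 1) against
# the bulk, taken literally as all observed cells including the cluster
# (group 2). Per SNP, the smallest p-value over clusters is kept, SNPs are
# ranked by ascending p, and — as a numerical guard, not an inference
# correction — F is capped at 20 and p floored at 1e-16.

#' Cluster-versus-bulk F-test for one SNP
#'
#' One-way ANOVA with two groups: the observed (depth > 0) cells of one
#' cluster, and the bulk of all observed cells (the cluster included, per the
#' method's definition of bulk; set `exclude_cluster_from_bulk = TRUE` for
#' the disjoint variant). The p-value comes from the F distribution with
#' `(1, n1 + n2 - 2)` degrees of freedom, computed before capping.
#'
#' @param af_values numeric vector of smoothed allele frequencies, one per
#'   cell, for a single SNP.
#' @param cluster_mask logical vector marking the cluster's cells.
#' @param observed_mask logical vector marking cells with depth > 0 at this
#'   SNP (default: all observed).
#' @param cap_f cap on the F statistic (default 20; `Inf` disables).
#' @param p_floor floor on the p-value (default 1e-16; `0` disables).
#' @param exclude_cluster_from_bulk use the disjoint bulk variant.
#' @return list with `F`, `p` and `flag` (`TRUE` when either group had fewer
#'   than 2 observed cells, in which case `F = 0`, `p = 1`).
#' @export
cluster_bulk_f_test <- function(af_values, cluster_mask, observed_mask = NULL,
                                cap_f = 20, p_floor = 1e-16,
                                exclude_cluster_from_bulk = FALSE) {
  if (is.null(observed_mask)) observed_mask <- rep(TRUE, length(af_values))
  stopifnot(length(cluster_mask) == length(af_values),
            length(observed_mask) == length(af_values))
  g1 <- af_values[observed_mask & cluster_mask]
  g2 <- if (exclude_cluster_from_bulk) {
    af_values[observed_mask & !cluster_mask]
  } else {
    af_values[observed_mask]
  }
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) {
    return(list(F = 0, p = 1, flag = TRUE))
  }
  m1 <- mean(g1); m2 <- mean(g2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
  df2 <- n1 + n2 - 2
  if (ssw == 0) {
    Fstat <- if (ssb == 0) 0 else Inf
  } else {
    Fstat <- (ssb / 1) / (ssw / df2)
  }
  p <- if (Fstat == 0) 1 else
    stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  list(F = min(Fstat, cap_f), p = max(p, p_floor), flag = FALSE)
}

#' Rank SNPs by cluster-versus-bulk F-tests
#'
#' Runs [cluster_bulk_f_test()] for every SNP against every cluster
#' (vectorized over SNPs), keeps per SNP the minimum p-value over clusters
#' with the corresponding F and cluster, and ranks SNPs by ascending p (ties
#' broken by descending F, then column order). Tests use the smoothed allele
#' frequencies of observed cells only, since the allele frequency is
#' undefined at zero depth.
#'
#' @param af an `af_matrix` from [compute_af()].
#' @param clusters an `snv_clusters` object or an integer label vector.
#' @param cap_f,p_floor numerical caps (defaults 20 and 1e-16).
#' @param exclude_cluster_from_bulk use the disjoint bulk variant.
#' @return An object of class `snv_rank_table`: data.frame with columns
#'   `snp_id`, `chrom`, `pos`, `F`, `p`, `best_cluster`, `rank`, `flag`,
#'   ordered by rank, with the full per-cluster p-value matrix in
#'   `attr(, "per_cluster_p")`.
#' @export
rank_snps <- function(af, clusters, cap_f = 20, p_floor = 1e-16,
                      exclude_cluster_from_bulk = FALSE) {
  stopifnot(inherits(af, "af_matrix"))
  labels <- if (inherits(clusters, "snv_clusters")) clusters$labels else
    as.integer(clusters)
  X <- af$values
  obs <- !af$missing_mask
  if (length(labels) != nrow(X)) stop_snvae("labels length != cell count")
  ks <- sort(unique(labels))
  if (length(ks) < 2) {
    stop_snvae("SNP ranking needs at least 2 clusters (no contrast otherwise)")
  }
  p_snps <- ncol(X)
  Xo <- X * obs
  Xo2 <- X^2 * obs
  # bulk (all observed cells) moments per SNP
  n2 <- colSums(obs); s2 <- colSums(Xo); q2 <- colSums(Xo2)

  Fmat <- matrix(0, p_snps, length(ks))
  Pmat <- matrix(1, p_snps, length(ks))
  flag <- matrix(FALSE, p_snps, length(ks))
  for (ci in seq_along(ks)) {
    in_k <- labels == ks[ci]
    n1 <- colSums(obs[in_k, , drop = FALSE])
    s1 <- colSums(Xo[in_k, , drop = FALSE])
    q1 <- colSums(Xo2[in_k, , drop = FALSE])
    if (exclude_cluster_from_bulk) {
      nb <- n2 - n1; sb <- s2 - s1; qb <- q2 - q1
    } else {
      nb <- n2; sb <- s2; qb <- q2
    }
    ok <- n1 >= 2 & nb >= 2
    m1 <- ifelse(n1 > 0, s1 / n1, 0)
    mb <- ifelse(nb > 0, sb / nb, 0)
    gm <- ifelse(n1 + nb > 0, (s1 + sb) / (n1 + nb), 0)
    ssb <- n1 * (m1 - gm)^2 + nb * (mb - gm)^2
    ssw <- pmax(0, (q1 - n1 * m1^2)) + pmax(0, (qb - nb * mb^2))
    df2 <- n1 + nb - 2
    Fr <- ifelse(ssw > 0, ssb * df2 / ssw, ifelse(ssb > 0, Inf, 0))
    pr <- ifelse(Fr == 0, 1, stats::pf(Fr, 1, df2, lower.tail = FALSE))
    Fr[!ok] <- 0; pr[!ok] <- 1
    Fmat[, ci] <- pmin(Fr, cap_f)
    Pmat[, ci] <- pmax(pr, p_floor)
    flag[, ci] <- !ok
  }
  best <- max.col(-Pmat, ties.method = "first")
  sel <- cbind(seq_len(p_snps), best)
  tbl <- data.frame(
    snp_id = af_snp_ids(af),
    chrom = attr_or_na(af, "chrom", p_snps),
    pos = attr_or_na(af, "pos", p_snps),
    F = Fmat[sel], p = Pmat[sel],
    best_cluster = ks[best],
    flag = flag[sel],
    stringsAsFactors = FALSE)
  ord <- order(tbl$p, -tbl$F, seq_len(p_snps))
  tbl$rank <- NA_integer_
  tbl$rank[ord] <- seq_len(p_snps)
  tbl <- tbl[ord, c("snp_id", "chrom", "pos", "F", "p", "best_cluster",
                    "rank", "flag")]
  rownames(tbl) <- NULL
  colnames(Pmat) <- paste0("cluster_", ks)
  attr(tbl, "per_cluster_p") <- Pmat
  class(tbl) <- c("snv_rank_table", "data.frame")
  tbl
}

af_snp_ids <- function(af) {
  colnames(af$values) %||% paste0("snp_", seq_len(ncol(af$values)))
}

attr_or_na <- function(af, field, p) {
  v <- attr(af, "variants")
  if (!is.null(v) && field %in% names(v)) v[[field]] else rep(NA, p)
}

#' @export
print.snv_rank_table <- function(x, n = 10, ...) {
  cat("snv_rank_table: ", nrow(x), " SNPs ranked by cluster-vs-bulk F-test\n",
      sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Order the allele-frequency matrix for heatmap display
#'
#' Rows (cells) grouped by cluster, columns (SNPs) by ascending p-value rank
#' so informative SNPs appear first; unobserved entries carry a mask for
#' distinct rendering.
#'
#' @param af an `af_matrix`.
#' @param table an `snv_rank_table` from [rank_snps()].
#' @param clusters an `snv_clusters` object or label vector.
#' @param top_n keep only the first `top_n` ranked SNPs (default all).
#' @return An object of class `snv_heatmap`: list with `values` (ordered
#'   matrix), `missing_mask`, `row_clusters`, `snp_order`.
#' @export
order_heatmap <- function(af, table, clusters, top_n = NULL) {
  stopifnot(inherits(af, "af_matrix"), inherits(table, "snv_rank_table"))
  labels <- if (inherits(clusters, "snv_clusters")) clusters$labels else
    as.integer(clusters)
  ids <- af_snp_ids(af)
  snp_order <- match(table$snp_id, ids)
  if (!is.null(top_n)) snp_order <- snp_order[seq_len(min(top_n,
                                                          length(snp_order)))]
  row_order <- order(labels)
  structure(list(values = af$values[row_order, snp_order, drop = FALSE],
                 missing_mask = af$missing_mask[row_order, snp_order,
                                                drop = FALSE],
                 row_clusters = labels[row_order],
                 snp_order = snp_order),
            class = "snv_heatmap")
}

#' Plot the cluster-ordered allele-frequency heatmap
#'
#' Allele frequency rendered from white (0) to red (1); unobserved entries
#' (depth 0) in blue.
#'
#' @param x an `snv_heatmap` from [order_heatmap()].
#' @param max_snps show at most this many top-ranked SNPs (default 50).
#' @param ... unused.
#' @export
plot.snv_heatmap <- function(x, max_snps = 50, ...) {
  js <- seq_len(min(max_snps, ncol(x$values)))
  V <- x$values[, js, drop = FALSE]
  V[x$missing_mask[, js, drop = FALSE]] <- NA
  pal <- grDevices::colorRampPalette(c("white", "red"))(100)
  # image() draws columns bottom-up; flip so the top-ranked SNP is on top
  graphics::image(seq_len(nrow(V)), seq_along(js),
                  V[, rev(seq_along(js)), drop = FALSE],
                  col = pal, zlim = c(0, 1), useRaster = FALSE,
                  xlab = "cells (grouped by cluster)", ylab = "SNP rank",
                  main = "allele frequencies by cluster")
  M <- x$missing_mask[, rev(js), drop = FALSE]
  if (any(M)) {
    idx <- which(M, arr.ind = TRUE)
    graphics::points(idx[, 1], idx[, 2], pch = 15, col = "blue", cex = 0.2)
  }
  invisible(x)
}
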
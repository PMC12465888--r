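# Pre-filtering of SNPs and cells.
#
# Three diagnostic quantities guide cutoff choice: the number of observed
# SNPs per cell, the mean coverage per SNP, and the logit-variance per SNP
# (variance of the logit of the smoothed allele frequency across the cells
# in which the SNP was observed). Filtering keeps high-quality SNPs first,
# then re-assesses cells on the retained SNP panel.

#' Number of observed SNPs per cell
#'
#' Entry `i` is the number of SNPs with depth `> 0` in cell `i`.
#'
#' @param counts an [allele_counts] object.
#' @return integer vector, one entry per cell.
#' @export
observed_snps_per_cell <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  as.integer(Matrix::rowSums(counts$D > 0))
}

#' Mean coverage per SNP
#'
#' Entry `j` is the mean depth of SNP `j` over all cells, zeros included.
#'
#' @param counts an [allele_counts] object.
#' @return numeric vector, one entry per SNP.
#' @export
mean_coverage_per_snp <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  as.numeric(Matrix::colMeans(counts$D))
}

#' Logit-variance per SNP
#'
#' For each SNP, the sample variance (denominator `n - 1`) of
#' `logit((a + c) / (d + 2c))` across the cells in which the SNP was observed
#' (depth `> 0`). SNPs observed in fewer than two cells get 0. Restricting to
#' observed cells keeps the pseudo-0.5 allele frequency of unobserved entries
#' from diluting the spread.
#'
#' @param counts an [allele_counts] object.
#' @param pseudocount smoothing constant `c > 0`.
#' @return numeric vector, one entry per SNP.
#' @export
logit_variance_per_snp <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "allele_counts"))
  if (pseudocount <= 0) stop_snvae("pseudocount must be > 0")
  A <- as_dense(counts$A); D <- as_dense(counts$D)
  obs <- D > 0
  lg <- logit((A + pseudocount) / (D + 2 * pseudocount))
  lg[!obs] <- 0
  n <- colSums(obs)
  s1 <- colSums(lg)
  s2 <- colSums(lg^2)
  v <- rep(0, ncol(D))
  ok <- n >= 2
  # sample variance from moments, guarded against tiny negative round-off
  v[ok] <- pmax(0, (s2[ok] - s1[ok]^2 / n[ok]) / (n[ok] - 1))
  v
}

#' Filter SNPs and cells on the three diagnostic quantities
#'
#' SNPs are filtered first (mean coverage and logit-variance thresholds,
#' computed over all current cells); cells are then filtered on their
#' observed-SNP count recomputed on the retained SNP panel, so cell quality
#' is judged on the SNPs actually used downstream.
#'
#' @param counts an [allele_counts] object.
#' @param min_cell_snps keep cells observing at least this many retained SNPs.
#' @param min_snp_coverage keep SNPs with mean coverage at least this.
#' @param min_logit_var keep SNPs with logit-variance at least this.
#' @param pseudocount smoothing constant for the logit-variance diagnostic.
#' @return list with `counts` (the filtered [allele_counts]) and `report`
#'   (class `snv_filter_report`): the three pre-filter diagnostic vectors,
#'   the cutoffs and the kept index sets.
#' @export
filter_counts <- function(counts, min_cell_snps = 0, min_snp_coverage = 0,
                          min_logit_var = 0, pseudocount = 1) {
  stopifnot(inherits(counts, "allele_counts"))
  if (min_cell_snps < 0 || min_snp_coverage < 0 || min_logit_var < 0) {
    stop_snvae("filter thresholds must be >= 0")
  }
  obs0 <- observed_snps_per_cell(counts)
  cov0 <- mean_coverage_per_snp(counts)
  lv0 <- logit_variance_per_snp(counts, pseudocount)

  keep_snps <- which(cov0 >= min_snp_coverage & lv0 >= min_logit_var)
  report <- structure(
    list(observed_snps_per_cell = obs0,
         mean_coverage_per_snp = cov0,
         logit_variance_per_snp = lv0,
         cutoffs = c(min_cell_snps = min_cell_snps,
                     min_snp_coverage = min_snp_coverage,
                     min_logit_var = min_logit_var),
         kept_cells = integer(0), kept_snps = keep_snps),
    class = "snv_filter_report")
  if (!length(keep_snps)) {
    cnd <- structure(
      class = c("snvae_empty_filter", "error", "condition"),
      list(message = "no SNPs survive the coverage/logit-variance thresholds",
           call = NULL, report = report))
    stop(cnd)
  }
  sub <- counts[, keep_snps]
  obs1 <- observed_snps_per_cell(sub)
  keep_cells <- which(obs1 >= min_cell_snps)
  report$kept_cells <- keep_cells
  if (!length(keep_cells)) {
    cnd <- structure(
      class = c("snvae_empty_filter", "error", "condition"),
      list(message = "no cells survive the observed-SNP threshold",
           call = NULL, report = report))
    stop(cnd)
  }
  list(counts = sub[keep_cells, ], report = report)
}

#' @export
print.snv_filter_report <- function(x, ...) {
  cat("snv_filter_report\n")
  cat("  cutoffs: min_cell_snps=", x$cutoffs["min_cell_snps"],
      ", min_snp_coverage=", x$cutoffs["min_snp_coverage"],
      ", min_logit_var=", x$cutoffs["min_logit_var"], "\n", sep = "")
  cat("  kept ", length(x$kept_cells), "/",
      length(x$observed_snps_per_cell), " cells, ",
      length(x$kept_snps), "/", length(x$mean_coverage_per_snp),
      " SNPs\n", sep = "")
  invisible(x)
}

#' Write the filter diagnostics as TSV tables
#'
#' Two tables are written: `<prefix>_cells.tsv` (observed SNPs per cell) and
#' `<prefix>_snps.tsv` (mean coverage and logit-variance per SNP), so cutoff
#' selection is scriptable.
#'
#' @param report an `snv_filter_report`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_filter_report <- function(report, prefix) {
  stopifnot(inherits(report, "snv_filter_report"))
  f1 <- paste0(prefix, "_cells.tsv")
  f2 <- paste0(prefix, "_snps.tsv")
  write_tsv(data.frame(cell_index = seq_along(report$observed_snps_per_cell),
                       observed_snps = report$observed_snps_per_cell,
                       kept = seq_along(report$observed_snps_per_cell) %in%
                         report$kept_cells), f1)
  write_tsv(data.frame(snp_index = seq_along(report$mean_coverage_per_snp),
                       mean_coverage = report$mean_coverage_per_snp,
                       logit_variance = report$logit_variance_per_snp,
                       kept = seq_along(report$mean_coverage_per_snp) %in%
                         report$kept_snps), f2)
  invisible(c(f1, f2))
}

#' Diagnostic plots for filter cutoff choice
#'
#' Draws the three pre-filter distributions (observed SNPs per cell, mean
#' coverage per SNP, logit-variance per SNP) with the chosen cutoffs marked,
#' the usual aid for picking knee/elbow points.
#'
#' @param x an `snv_filter_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.snv_filter_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  plot(sort(x$observed_snps_per_cell, decreasing = TRUE), type = "l",
       xlab = "cell rank", ylab = "observed SNPs", main = "cells", ...)
  graphics::abline(h = x$cutoffs["min_cell_snps"], col = 2, lty = 2)
  plot(sort(x$mean_coverage_per_snp, decreasing = TRUE), type = "l",
       xlab = "SNP rank", ylab = "mean coverage", main = "SNP coverage", ...)
  graphics::abline(h = x$cutoffs["min_snp_coverage"], col = 2, lty = 2)
  plot(sort(x$logit_variance_per_snp, decreasing = TRUE), type = "l",
       xlab = "SNP rank", ylab = "logit variance", main = "SNP variance", ...)
  graphics::abline(h = x$cutoffs["min_logit_var"], col = 2, lty = 2)
  invisible(x)
}
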
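#' Paired single-cell allele count matrices
#'
#' Container for the two count matrices the method consumes: `A`, per-cell
#' alternative-allele counts (often called AD), and `D`, per-cell total read
#' depth (DP), both oriented cells x SNPs, together with cell barcodes and a
#' variant table. `D[i, j] == 0` means SNP `j` was not observed in cell `i`.
#'
#' @param A cells x SNPs matrix of non-negative integer alt-allele counts
#'   (dense or `Matrix` sparse).
#' @param D cells x SNPs matrix of non-negative integer total depths, same
#'   shape as `A`, with `A <= D` elementwise.
#' @param cells character vector of cell barcodes (one per row). Defaults to
#'   `cell_1 .. cell_n`.
#' @param variants data.frame with one row per SNP and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt` and optionally `id`. Default ids are
#'   `"<pos><ref>><alt>"` (e.g. `"2593G>A"`), disambiguated by chromosome
#'   when needed.
#'
#' @return An object of class `allele_counts` with elements `A`, `D`
#'   (sparse `dgCMatrix`), `cells` and `variants`.
#' @export
allele_counts <- function(A, D, cells = NULL, variants = NULL) {
  A <- as_sparse(A)
  D <- as_sparse(D)
  if (!identical(dim(A), dim(D))) {
    stop_snvae("A and D must have identical shape (got ",
               paste(dim(A), collapse = "x"), " vs ",
               paste(dim(D), collapse = "x"), ")")
  }
  if (any(A@x < 0) || any(D@x < 0)) {
    stop_snvae("allele counts must be non-negative")
  }
  if (any((A - D)@x > 0)) {
    stop_snvae("A (alt counts) exceeds D (total depth) for at least one entry")
  }
  n <- nrow(A); p <- ncol(A)
  if (is.null(cells)) cells <- paste0("cell_", seq_len(n))
  cells <- as.character(cells)
  if (length(cells) != n) {
    stop_snvae("length(cells) = ", length(cells), " but matrices have ",
               n, " rows")
  }
  if (is.null(variants)) {
    variants <- data.frame(chrom = rep("chr1", p), pos = seq_len(p),
                           ref = rep("A", p), alt = rep("T", p),
                           stringsAsFactors = FALSE)
  }
  variants <- validate_variants(variants, p)
  structure(list(A = A, D = D, cells = cells, variants = variants),
            class = "allele_counts")
}

validate_variants <- function(variants, p) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop_snvae("variants lacks column(s): ",
                               paste(miss, collapse = ", "))
  if (nrow(variants) != p) {
    stop_snvae("variants has ", nrow(variants), " rows but matrices have ",
               p, " columns")
  }
  if (any(variants$pos < 1)) stop_snvae("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    stop_snvae("ref and alt allele must differ for every variant")
  }
  if (is.null(variants$id)) {
    variants$id <- variant_ids(variants)
  }
  if (anyDuplicated(variants$id)) {
    stop_snvae("variant ids are not unique")
  }
  rownames(variants) <- NULL
  variants
}

# display ids in the "2593G>A" style; chromosome-prefixed when ambiguous
variant_ids <- function(variants) {
  id <- paste0(variants$pos, variants$ref, ">", variants$alt)
  if (anyDuplicated(id)) {
    id <- paste0(variants$chrom, ":", id)
  }
  id
}

#' @export
dim.allele_counts <- function(x) dim(x$A)

#' @export
print.allele_counts <- function(x, ...) {
  d <- dim(x)
  obs <- Matrix::nnzero(x$D)
  cat("allele_counts: ", d[1], " cells x ", d[2], " SNPs; ",
      format(100 * obs / prod(d), digits = 3),
      "% of entries observed (depth > 0)\n", sep = "")
  invisible(x)
}

#' Subset an allele count object
#'
#' @param x an [allele_counts] object.
#' @param i cell (row) index.
#' @param j SNP (column) index.
#' @param ... unused.
#' @export
`[.allele_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$A))
  if (missing(j)) j <- seq_len(ncol(x$A))
  allele_counts(x$A[i, j, drop = FALSE], x$D[i, j, drop = FALSE],
                cells = x$cells[i], variants = x$variants[j, , drop = FALSE])
}

#' Smoothed allele-frequency matrix
#'
#' Computes the cells x SNPs allele-frequency matrix
#' `X = (A + c) / (D + 2c)` with a symmetric smoothing pseudo-count `c`.
#' Entries with zero depth (unobserved) get AF exactly 0.5, whose logit is 0,
#' so they contribute nothing to a linear encoder; they are marked in
#' `missing_mask`.
#'
#' @param counts an [allele_counts] object.
#' @param pseudocount smoothing constant `c >= 0`; must be positive when any
#'   depth is zero.
#'
#' @return An object of class `af_matrix`: list with `values` (dense matrix
#'   in `[0, 1]`), `pseudocount` and `missing_mask` (logical matrix,
#'   `TRUE` where depth is zero).
#' @export
compute_af <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "allele_counts"))
  if (pseudocount < 0) stop_snvae("pseudocount must be >= 0")
  A <- as_dense(counts$A)
  D <- as_dense(counts$D)
  miss <- D == 0
  if (pseudocount == 0 && any(miss)) {
    stop_snvae("pseudocount = 0 but the data contain zero-depth entries; ",
               "the allele frequency 0/0 is undefined")
  }
  values <- (A + pseudocount) / (D + 2 * pseudocount)
  dimnames(values) <- list(counts$cells, counts$variants$id)
  structure(list(values = values, pseudocount = pseudocount,
                 missing_mask = miss),
            variants = counts$variants,
            class = "af_matrix")
}

#' @export
print.af_matrix <- function(x, ...) {
  cat("af_matrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " SNPs, pseudocount = ", x$pseudocount, "\n", sep = "")
  invisible(x)
}
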
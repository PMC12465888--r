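# Readers and writers for the cellsnp-lite style input bundle
# (AD/DP Matrix Market files + VCF of variants + barcode list) and the
# tabular outputs of the downstream analyses.

find_one <- function(path, patterns, what) {
  files <- list.files(path, full.names = TRUE)
  for (pat in patterns) {
    hit <- grep(pat, basename(files), ignore.case = TRUE, value = FALSE)
    if (length(hit) == 1) return(files[hit])
    if (length(hit) > 1) {
      stop_snvae("multiple candidate ", what, " files in ", path, ": ",
                 paste(basename(files)[hit], collapse = ", "))
    }
  }
  stop_snvae("no ", what, " file found in ", path)
}

#' Read a cellsnp-lite output directory
#'
#' Loads paired AD (alt-allele count) and DP (total depth) Matrix Market
#' files, the VCF of variant records and the cell barcode list, and returns
#' an [allele_counts] object oriented cells x SNPs. cellsnp-lite writes
#' matrices SNPs x cells; the reader auto-orients by matching matrix
#' dimensions against the VCF record count and barcode count, so either
#' on-disk orientation is accepted. When the matrix is square the orientation
#' is ambiguous and must be stated explicitly.
#'
#' @param path directory containing `*AD*.mtx`, `*DP*.mtx`, a `.vcf` and a
#'   barcode list (`*barcodes*`/`*samples*` `.tsv`/`.txt`).
#' @param orientation one of `"auto"`, `"cells_by_snps"`, `"snps_by_cells"`;
#'   only consulted when the two dimensions are equal.
#' @return an [allele_counts] object.
#' @export
read_cellsnp <- function(path, orientation = c("auto", "cells_by_snps",
                                               "snps_by_cells")) {
  orientation <- match.arg(orientation)
  if (!dir.exists(path)) stop_snvae("directory not found: ", path)
  ad_file <- find_one(path, c("AD.*\\.mtx$", "\\bAD\\b"), "AD matrix")
  dp_file <- find_one(path, c("DP.*\\.mtx$", "\\bDP\\b"), "DP matrix")
  vcf_file <- find_one(path, c("\\.vcf(\\.gz)?$"), "VCF")
  bc_file <- find_one(path, c("barcode.*\\.(tsv|txt)$",
                              "samples.*\\.(tsv|txt)$"), "barcode list")

  A <- Matrix::readMM(ad_file)
  D <- Matrix::readMM(dp_file)
  if (!identical(dim(A), dim(D))) {
    stop_snvae("AD (", basename(ad_file), ") and DP (", basename(dp_file),
               ") have different shapes")
  }
  variants <- read_variants_vcf(vcf_file)
  cells <- readLines(bc_file)
  cells <- cells[nzchar(cells)]
  n_snps <- nrow(variants); n_cells <- length(cells)

  dm <- dim(A)
  if (dm[1] == dm[2]) {
    if (orientation == "auto") {
      stop_snvae("square matrix in ", basename(ad_file),
                 ": orientation is ambiguous, pass orientation=")
    }
    flip <- orientation == "snps_by_cells"
  } else if (dm[1] == n_snps && dm[2] == n_cells) {
    flip <- TRUE
  } else if (dm[1] == n_cells && dm[2] == n_snps) {
    flip <- FALSE
  } else {
    stop_snvae("matrix shape ", dm[1], "x", dm[2], " in ", basename(ad_file),
               " matches neither ", n_cells, " barcodes (", basename(bc_file),
               ") x ", n_snps, " VCF records (", basename(vcf_file), ")")
  }
  if (flip) { A <- Matrix::t(A); D <- Matrix::t(D) }
  allele_counts(A, D, cells = cells, variants = variants)
}

read_variants_vcf <- function(vcf_file) {
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             ref = as.character(fix[, "REF"]),
             alt = as.character(fix[, "ALT"]),
             stringsAsFactors = FALSE)
}

#' Write an allele count object as a cellsnp-lite style bundle
#'
#' Writes `cellSNP.tag.AD.mtx`, `cellSNP.tag.DP.mtx` (SNPs x cells, the
#' orientation cellsnp-lite uses), a minimal plain-text `cellSNP.base.vcf`
#' and `cellSNP.samples.tsv`, so that [read_cellsnp()] round-trips.
#'
#' @param counts an [allele_counts] object.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cellsnp <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_snvae("cannot create directory ", path)
  Matrix::writeMM(Matrix::t(counts$A), file.path(path, "cellSNP.tag.AD.mtx"))
  Matrix::writeMM(Matrix::t(counts$D), file.path(path, "cellSNP.tag.DP.mtx"))
  v <- counts$variants
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=snvae",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", sep = "\t"))
  writeLines(vcf_lines, file.path(path, "cellSNP.base.vcf"))
  writeLines(counts$cells, file.path(path, "cellSNP.samples.tsv"))
  invisible(path)
}

write_tsv <- function(df, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_snvae("cannot write ", file, ": ",
                              conditionMessage(ok))
  invisible(file)
}

#' Write per-cell cluster labels as TSV
#'
#' @param clusters an `snv_clusters` object (see [cluster_cells()]) or an
#'   atomic label vector.
#' @param file output file.
#' @param cells optional barcode vector when `clusters` is atomic.
#' @return the file path, invisibly.
#' @export
write_labels <- function(clusters, file, cells = NULL) {
  if (inherits(clusters, "snv_clusters")) {
    df <- data.frame(cell = clusters$cells %||%
                       sprintf("cell_%d", seq_along(clusters$labels)),
                     cluster = clusters$labels)
  } else {
    df <- data.frame(cell = cells %||% sprintf("cell_%d", seq_along(clusters)),
                     cluster = clusters)
  }
  write_tsv(df, file)
}
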
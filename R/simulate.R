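# Synthetic allele-count generators.
#
# Two designs, mirroring the statistical structure of the data the method
# targets: (a) donor-multiplexed scRNA-seq, where each donor has a fixed
# germline genotype (near-0 / 0.5 / near-1 expected allele frequency per SNP)
# and reads are binomially sampled at sparse per-cell depths; (b)
# mitochondrial lineage data, where clones on a known tree inherit all
# ancestral SNVs and carry private SNVs at continuous heteroplasmic allele
# frequencies, sequenced at higher depth, with optional 1:1 doublets.

random_variants <- function(p, chrom = "chr1") {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  data.frame(chrom = rep(chrom, p), pos = seq_len(p) * 10L,
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate donor-multiplexed single-cell allele counts
#'
#' Each donor gets a genotype vector drawn i.i.d. per SNP from
#' `af_levels` (defaults `{0.01, 0.5, 0.99}` for reference-homozygous,
#' heterozygous and alternate-homozygous, kept off exact 0/1 to model
#' sequencing error). Depths are Poisson per cell per SNP (zeros = unobserved
#' entries) and alt counts binomial at the donor's allele frequency.
#' Bit-reproducible for a fixed seed.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor integer scalar or vector of length `n_donors`
#'   (imbalanced designs allowed).
#' @param n_snps number of SNPs.
#' @param af_levels genotype allele-frequency levels in (0, 1).
#' @param level_probs sampling probabilities of the levels (default equal).
#' @param depth_mean mean of the Poisson per-entry depth (default 2,
#'   emulating sparse nuclear scRNA-seq coverage).
#' @param seed integer seed.
#' @return list with `counts` ([allele_counts]), `labels` (integer donor of
#'   each cell) and `genotypes` (donors x SNPs allele-frequency matrix).
#' @export
simulate_donors <- function(n_donors, cells_per_donor, n_snps,
                            af_levels = c(0.01, 0.5, 0.99),
                            level_probs = NULL, depth_mean = 2, seed = 1) {
  if (n_donors < 1 || n_snps < 1) stop_snvae("need n_donors, n_snps >= 1")
  if (any(af_levels <= 0) || any(af_levels >= 1)) {
    stop_snvae("af_levels must lie strictly inside (0, 1)")
  }
  if (length(cells_per_donor) == 1) {
    cells_per_donor <- rep(cells_per_donor, n_donors)
  }
  if (length(cells_per_donor) != n_donors || any(cells_per_donor < 1)) {
    stop_snvae("cells_per_donor must be positive, one entry per donor")
  }
  if (depth_mean < 0) stop_snvae("depth_mean must be >= 0")
  set.seed(seed)
  G <- matrix(sample(af_levels, n_donors * n_snps, replace = TRUE,
                     prob = level_probs), n_donors, n_snps)
  labels <- rep(seq_len(n_donors), times = cells_per_donor)
  n <- length(labels)
  D <- matrix(stats::rpois(n * n_snps, depth_mean), n, n_snps)
  A <- matrix(stats::rbinom(n * n_snps, size = as.vector(D),
                            prob = as.vector(G[labels, ])), n, n_snps)
  counts <- allele_counts(A, D,
                          cells = sprintf("cell_%05d", seq_len(n)),
                          variants = random_variants(n_snps))
  list(counts = counts, labels = labels, genotypes = G)
}

#' Simulate mitochondrial-lineage single-cell allele counts
#'
#' Clones sit on a rooted tree given as a parent vector (`NA` for the root).
#' Each clone acquires its own private SNVs, carried — at a single continuous
#' heteroplasmic allele frequency drawn per SNV from `het_af_range` — by the
#' clone and all of its descendants; the root's SNVs are therefore the
#' inherited set shared by every clone. Non-carriers show the sequencing
#' error rate `error_af`. Optional uninformative noise SNVs sit at
#' `error_af` everywhere; optional doublets are extra cells mixing two
#' distinct clones' expected allele frequencies 1:1.
#'
#' @param parent integer parent vector over clones, `NA` at the root.
#' @param cells_per_clone integer scalar or vector (one entry per clone).
#' @param n_private_snvs SNVs acquired by each clone (scalar or vector; the
#'   root's entry is the shared ancestral set).
#' @param n_noise_snvs extra SNVs with no clone signal (default 0).
#' @param het_af_range range of the per-SNV heteroplasmic allele frequency
#'   (default `c(0.1, 0.9)`).
#' @param error_af allele frequency in non-carrier cells (default 0.01).
#' @param depth_mean Poisson depth mean (default 20, reflecting the higher
#'   sequencing depth of mitochondrial SNVs).
#' @param doublet_rate fraction of extra doublet cells relative to the
#'   singlet total (default 0).
#' @param seed integer seed.
#' @return list with `counts`, `labels` (clone index per cell; doublets get
#'   `NA` and a `"doublet"` entry in `label_names`), `label_names`,
#'   `tree` (list with `parent` and an `edges` data.frame) and `clone_af`
#'   (clones x SNVs expected allele frequencies).
#' @export
simulate_lineages <- function(parent, cells_per_clone, n_private_snvs = 10,
                              n_noise_snvs = 0, het_af_range = c(0.1, 0.9),
                              error_af = 0.01, depth_mean = 20,
                              doublet_rate = 0, seed = 1) {
  K <- length(parent)
  if (sum(is.na(parent)) != 1) stop_snvae("parent must have exactly one NA root")
  root <- which(is.na(parent))
  if (length(cells_per_clone) == 1) cells_per_clone <- rep(cells_per_clone, K)
  if (length(n_private_snvs) == 1) n_private_snvs <- rep(n_private_snvs, K)
  stopifnot(length(cells_per_clone) == K, length(n_private_snvs) == K)
  set.seed(seed)

  # descendants (inclusive) of each clone
  desc <- lapply(seq_len(K), function(k) {
    out <- k
    repeat {
      add <- which(parent %in% out & !(seq_len(K) %in% out))
      if (!length(add)) break
      out <- c(out, add)
    }
    out
  })

  p <- sum(n_private_snvs) + n_noise_snvs
  clone_af <- matrix(error_af, K, p)
  col <- 0
  owner <- integer(0)
  for (k in seq_len(K)) {
    if (n_private_snvs[k] == 0) next
    js <- col + seq_len(n_private_snvs[k])
    af <- stats::runif(n_private_snvs[k], het_af_range[1], het_af_range[2])
    clone_af[desc[[k]], js] <- matrix(af, length(desc[[k]]),
                                      n_private_snvs[k], byrow = TRUE)
    owner <- c(owner, rep(k, n_private_snvs[k]))
    col <- col + n_private_snvs[k]
  }
  owner <- c(owner, rep(NA_integer_, n_noise_snvs))

  labels <- rep(seq_len(K), times = cells_per_clone)
  EA <- clone_af[labels, , drop = FALSE]
  label_names <- paste0("clone_", labels)

  n_doub <- round(doublet_rate * length(labels))
  if (n_doub > 0) {
    pair <- replicate(n_doub, sample(seq_len(K), 2))
    EA <- rbind(EA, (clone_af[pair[1, ], , drop = FALSE] +
                       clone_af[pair[2, ], , drop = FALSE]) / 2)
    labels <- c(labels, rep(NA_integer_, n_doub))
    label_names <- c(label_names,
                     paste0("doublet_", pair[1, ], "+", pair[2, ]))
  }
  n <- nrow(EA)
  D <- matrix(stats::rpois(n * p, depth_mean), n, p)
  A <- matrix(stats::rbinom(n * p, size = as.vector(D),
                            prob = as.vector(EA)), n, p)
  counts <- allele_counts(A, D,
                          cells = sprintf("cell_%05d", seq_len(n)),
                          variants = random_variants(p, chrom = "chrM"))
  edges <- data.frame(from = parent[-root], to = seq_len(K)[-root])
  list(counts = counts, labels = labels, label_names = label_names,
       tree = list(parent = parent, root = root, edges = edges),
       clone_af = clone_af, snv_owner = owner)
}

# Deterministic imbalanced donor sizes: fixed smallest and largest donors,
# remaining sizes geometric between the bounds, scaled to the target total.
imbalanced_sizes <- function(n, total, smin, smax) {
  stopifnot(n >= 3, total > smin + smax)
  mid <- exp(seq(log(smin), log(smax), length.out = n))[2:(n - 1)]
  mid <- mid * (total - smin - smax) / sum(mid)
  mid <- round(mid)
  mid[length(mid)] <- total - smin - smax - sum(mid[-length(mid)])
  sizes <- c(smin, mid, smax)
  stopifnot(sum(sizes) == total, all(sizes > 0))
  sizes
}

#' Preset simulation designs emulating the published dataset shapes
#'
#' Returns a fully populated specification (a named list of generator
#' arguments plus a `type` of `"donors"` or `"lineages"`) matching the
#' dimensions of the five dataset classes the method was demonstrated on:
#' donor-multiplexed designs of 734 cells x 1905 SNPs / 4 donors,
#' 13,939 x 929 / 8 donors, and 9,436 x 864 / 18 donors with imbalanced
#' sizes spanning 67 to 1519 cells; and two mitochondrial lineage designs
#' (1001 cells x 56 SNVs cell-line style, 9204 x 274 primary-sample style)
#' with clone trees, higher depth and continuous heteroplasmy.
#'
#' @param name one of `"donor4like"`, `"donor8like"`, `"donor18like"`,
#'   `"mito_cellline_like"`, `"mito_primary_like"`.
#' @return named list of generator arguments with an extra `type` element.
#' @seealso [simulate_preset()]
#' @export
sim_preset <- function(name = c("donor4like", "donor8like", "donor18like",
                                "mito_cellline_like", "mito_primary_like")) {
  name <- match.arg(name)
  switch(name,
    donor4like = list(type = "donors", n_donors = 4,
                      cells_per_donor = c(183, 183, 184, 184),
                      n_snps = 1905, depth_mean = 2),
    donor8like = list(type = "donors", n_donors = 8,
                      cells_per_donor = c(rep(1742, 5), rep(1743, 3)),
                      n_snps = 929, depth_mean = 2),
    donor18like = list(type = "donors", n_donors = 18,
                       cells_per_donor = imbalanced_sizes(18, 9436, 67, 1519),
                       n_snps = 864, depth_mean = 2),
    mito_cellline_like = list(type = "lineages",
                              parent = c(NA, 1, 1, 2, 2),
                              cells_per_clone = c(301, 200, 200, 150, 150),
                              n_private_snvs = c(6, 10, 10, 10, 10),
                              n_noise_snvs = 10, depth_mean = 20),
    mito_primary_like = list(type = "lineages",
                             parent = c(NA, 1, 1, 2, 2, 3, 3, 4),
                             cells_per_clone = c(2204, 1500, 1500, 1000,
                                                 1000, 800, 700, 500),
                             n_private_snvs = c(10, rep(20, 7)),
                             n_noise_snvs = 124, depth_mean = 20))
}

#' Run a preset simulation
#'
#' @param name preset name, see [sim_preset()].
#' @param seed integer seed.
#' @param ... overrides of preset fields (e.g. smaller `n_snps` or cell
#'   counts for quick runs).
#' @return the generator's result list (see [simulate_donors()] /
#'   [simulate_lineages()]).
#' @export
simulate_preset <- function(name, seed = 1, ...) {
  spec <- sim_preset(name)
  type <- spec$type
  spec$type <- NULL
  over <- list(...)
  spec[names(over)] <- over
  spec$seed <- seed
  if (type == "donors") do.call(simulate_donors, spec) else
    do.call(simulate_lineages, spec)
}
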
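Package: snvae
Title: Manifold Embedding of Single-Cell SNV Allele Counts with a Binomial
    Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Embeds sparse single-cell single-nucleotide-variant (SNV) allele
    count matrices (alternative-allele and total-depth counts, e.g. from
    cellsnp-lite) into a low-dimensional latent manifold using a binomial
    variational autoencoder with observed-SNP normalization, and performs
    three downstream analyses on the manifold: clustering of cells with
    similar genotypes (k-means with silhouette-selected k, or Leiden on a 3D
    UMAP), ranking of informative SNPs by cluster-versus-bulk F-tests, and
    construction of cluster-level phylogenies (a multifurcating tree from
    greedy joining of shortest average cell-pair distances, and a bifurcating
    average-linkage dendrogram). Includes pre-filtering of SNPs and cells,
    readers and writers for cellsnp-lite style inputs, synthetic-data
    generators for donor-multiplexed and mitochondrial-lineage designs, and
    an end-to-end pipeline with a reproducible run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    igraph,
    uwot,
    ape,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
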
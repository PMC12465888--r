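# End-to-end orchestration: filter -> fit VAE -> UMAP -> cluster -> rank ->
# tree, with every artifact written to disk and a machine-readable manifest
# (configuration, seeds, input hashes, package version) for reproducibility.

#' Pipeline configuration
#'
#' One document holding every stage's parameters; any field can be
#' overridden. All stochastic stages flow from `seed`.
#'
#' @param min_cell_snps,min_snp_coverage,min_logit_var pre-filter cutoffs
#'   (defaults 0: keep everything; choose cutoffs from the diagnostics).
#' @param pseudocount smoothing constant used throughout.
#' @param latent_dim,beta,epochs,learning_rate,n_hidden_layers VAE settings
#'   (see [snv_vae()]).
#' @param cluster_method,resolution,k,k_range clustering settings (see
#'   [cluster_cells()]).
#' @param k_pairs shortest-pair count for cluster distances.
#' @param seed master seed.
#' @return list of class `snv_pipeline_config`.
#' @export
snv_pipeline_config <- function(min_cell_snps = 0, min_snp_coverage = 0,
                                min_logit_var = 0, pseudocount = 1,
                                latent_dim = NULL, beta = 0, epochs = 2000,
                                learning_rate = 1e-4, n_hidden_layers = 0,
                                cluster_method = "leiden", resolution = 1,
                                k = "auto", k_range = 2:30, k_pairs = 100,
                                seed = 1) {
  structure(list(min_cell_snps = min_cell_snps,
                 min_snp_coverage = min_snp_coverage,
                 min_logit_var = min_logit_var, pseudocount = pseudocount,
                 latent_dim = latent_dim, beta = beta, epochs = epochs,
                 learning_rate = learning_rate,
                 n_hidden_layers = n_hidden_layers,
                 cluster_method = cluster_method, resolution = resolution,
                 k = k, k_range = k_range, k_pairs = k_pairs,
                 seed = as.integer(seed)),
            class = "snv_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Filters SNPs and cells, fits the binomial VAE, embeds the latent space in
#' 2D/3D UMAP, clusters cells, ranks SNPs and builds both cluster trees,
#' writing all artifacts under `output_dir`: the filtered count bundle,
#' latent embedding and UMAP TSVs, cluster labels, the SNP ranking, tree edge
#' lists, the Newick dendrogram, diagnostic figures and `manifest.json`.
#' Rerunning with identical config and inputs reproduces identical label
#' files. If `truth` labels are supplied, accuracy, silhouette and the
#' column-normalized confusion matrix are computed and written too.
#'
#' @param input an [allele_counts] object or a cellsnp-lite directory path.
#' @param output_dir output directory (created).
#' @param config an [snv_pipeline_config()].
#' @param truth optional ground-truth per-cell labels (full pre-filter
#'   length; subset to kept cells internally).
#' @param figures write PNG figures (default TRUE).
#' @return invisibly, a list with every intermediate object (`counts`,
#'   `report`, `model`, `umap2`, `umap3`, `clusters`, `ranking`, `tree_multi`,
#'   `tree_bi`, `evaluation`, `manifest`).
#' @export
run_snv_pipeline <- function(input, output_dir, config = snv_pipeline_config(),
                             truth = NULL, figures = TRUE) {
  stopifnot(inherits(config, "snv_pipeline_config"))
  input_files <- NULL
  if (is.character(input)) {
    input_files <- list.files(input, full.names = TRUE)
    counts0 <- read_cellsnp(input)
  } else {
    counts0 <- input
  }
  stopifnot(inherits(counts0, "allele_counts"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  fl <- filter_counts(counts0, config$min_cell_snps, config$min_snp_coverage,
                      config$min_logit_var, config$pseudocount)
  counts <- fl$counts
  write_filter_report(fl$report, file.path(output_dir, "filter_report"))
  write_cellsnp(counts, file.path(output_dir, "filtered_counts"))
  if (!is.null(truth)) {
    if (length(truth) != length(counts0$cells)) {
      stop_snvae("truth labels must cover the unfiltered cells")
    }
    truth <- truth[fl$report$kept_cells]
  }

  model <- snv_vae(counts, latent_dim = config$latent_dim, beta = config$beta,
                   epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   n_hidden_layers = config$n_hidden_layers,
                   pseudocount = config$pseudocount, seed = config$seed)
  mu <- model$embedding$mu
  write_tsv(data.frame(cell = counts$cells, round(mu, 6)),
            file.path(output_dir, "latent_mu.tsv"))

  umap2 <- umap_embed(model, n_components = 2, seed = config$seed)
  umap3 <- umap_embed(model, n_components = 3, seed = config$seed)
  write_tsv(data.frame(cell = counts$cells, umap2$coords),
            file.path(output_dir, "umap2.tsv"))

  clusters <- cluster_cells(model, method = config$cluster_method,
                            k = config$k, k_range = config$k_range,
                            resolution = config$resolution,
                            seed = config$seed, umap = umap3)
  write_labels(clusters, file.path(output_dir, "clusters.tsv"))

  af <- compute_af(counts, config$pseudocount)
  ranking <- NULL
  tree_multi <- NULL
  tree_bi <- NULL
  if (clusters$K >= 2) {
    ranking <- rank_snps(af, clusters)
    write_tsv(as.data.frame(ranking), file.path(output_dir, "snp_ranking.tsv"))
    dists <- cluster_pair_distances(model, clusters, k_pairs = config$k_pairs)
    tree_multi <- cluster_tree(dists, kind = "multifurcating")
    tree_bi <- cluster_tree(dists, kind = "bifurcating")
    write_tree_edges(tree_multi, file.path(output_dir, "tree_edges.tsv"))
    writeLines(tree_newick(tree_bi), file.path(output_dir, "tree.nwk"))
  } else {
    message("single cluster found; SNP ranking and trees skipped")
  }

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- list(
      accuracy = label_accuracy(clusters, truth),
      silhouette_truth = tryCatch(silhouette_score(model, truth),
                                  error = function(e) NA_real_),
      confusion = cluster_confusion(clusters, truth))
    write_tsv(data.frame(metric = c("accuracy", "silhouette_truth"),
                         value = c(evaluation$accuracy,
                                   evaluation$silhouette_truth)),
              file.path(output_dir, "evaluation.tsv"))
    write_tsv(as.data.frame.matrix(evaluation$confusion),
              file.path(output_dir, "confusion.tsv"))
  }

  if (figures) {
    grDevices::png(file.path(output_dir, "training_trace.png"), 700, 500)
    plot(model, type = "trace")
    grDevices::dev.off()
    grDevices::png(file.path(output_dir, "filter_report.png"), 900, 350)
    plot(fl$report)
    grDevices::dev.off()
    grDevices::png(file.path(output_dir, "umap_clusters.png"), 700, 600)
    plot(umap2$coords, col = clusters$labels, pch = 16, cex = 0.6,
         xlab = "UMAP 1", ylab = "UMAP 2", main = "clusters on the manifold")
    grDevices::dev.off()
    if (!is.null(ranking)) {
      grDevices::png(file.path(output_dir, "af_heatmap.png"), 800, 600)
      plot(order_heatmap(af, ranking, clusters))
      grDevices::dev.off()
    }
    if (!is.null(tree_multi)) {
      grDevices::png(file.path(output_dir, "tree.png"), 700, 600)
      plot(tree_multi)
      grDevices::dev.off()
    }
  }

  manifest <- list(
    package = "snvae",
    version = as.character(utils::packageVersion("snvae")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    seed = config$seed,
    input = if (!is.null(input_files)) {
      data.frame(file = basename(input_files),
                 md5 = unname(tools::md5sum(input_files)))
    } else {
      list(cells = length(counts0$cells), snps = nrow(counts0$variants))
    },
    n_cells_kept = length(counts$cells),
    n_snps_kept = nrow(counts$variants),
    n_clusters = clusters$K)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  invisible(list(counts = counts, report = fl$report, model = model,
                 umap2 = umap2, umap3 = umap3, clusters = clusters,
                 ranking = ranking, tree_multi = tree_multi,
                 tree_bi = tree_bi, evaluation = evaluation,
                 manifest = manifest))
}
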
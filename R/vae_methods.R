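# Standard modelling-object methods for the fitted VAE.

#' @export
print.snv_vae <- function(x, ...) {
  cfg <- x$config
  cat("Binomial variational autoencoder (observed-SNP normalized)\n")
  cat("  cells: ", length(x$cells), ", SNPs: ", cfg$n_snps,
      ", latent dim: ", cfg$latent_dim, "\n", sep = "")
  cat("  beta = ", cfg$beta, ", epochs = ", cfg$epochs,
      ", lr = ", cfg$learning_rate, ", seed = ", cfg$seed, "\n", sep = "")
  cat("  final cost: ", format(x$final_cost, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.snv_vae <- function(object, ...) {
  cfg <- object$config
  n_par <- sum(rapply(object$params, length, how = "unlist"))
  out <- list(
    n_cells = length(object$cells), n_snps = cfg$n_snps,
    latent_dim = cfg$latent_dim, beta = cfg$beta, epochs = cfg$epochs,
    n_parameters = n_par,
    initial_cost = object$trace[1], final_cost = object$final_cost,
    cost_reduction = object$trace[1] - object$final_cost,
    flagged_cells = sum(object$embedding$flagged))
  class(out) <- "summary.snv_vae"
  out
}

#' @export
print.summary.snv_vae <- function(x, ...) {
  cat("Binomial VAE fit\n")
  cat(sprintf("  %d cells x %d SNPs -> %d latent dimensions (%d parameters)\n",
              x$n_cells, x$n_snps, x$latent_dim, x$n_parameters))
  cat(sprintf("  beta = %g, %d epochs\n", x$beta, x$epochs))
  cat(sprintf("  cost: %.4f -> %.4f (reduced by %.4f)\n",
              x$initial_cost, x$final_cost, x$cost_reduction))
  if (x$flagged_cells > 0) {
    cat("  ", x$flagged_cells, " cells had no observed SNP\n", sep = "")
  }
  invisible(x)
}

#' Extract fitted encoder/decoder parameters
#'
#' @param object a fitted [snv_vae] object.
#' @param ... unused.
#' @return list with the encoder heads (`mu_head`, `lv_head`), decoder output
#'   layer (`out`) and any hidden layers, each a list of `W` and `b`.
#' @export
coef.snv_vae <- function(object, ...) object$params

#' Predict latent coordinates or reconstructed allele frequencies
#'
#' @param object a fitted [snv_vae] object.
#' @param newdata an [allele_counts] object on the model's SNP panel;
#'   defaults to the training data embedding.
#' @param type `"latent"` for normalized posterior means (cells x D),
#'   `"response"` for the reconstruction `decode(mu)` (cells x SNPs).
#' @param ... unused.
#' @export
predict.snv_vae <- function(object, newdata = NULL,
                            type = c("latent", "response"), ...) {
  type <- match.arg(type)
  emb <- if (is.null(newdata)) object$embedding else
    encode_cells(object, newdata)
  if (type == "latent") return(emb$mu)
  decode_latent(object, emb$mu)
}

#' @export
fitted.snv_vae <- function(object, ...) {
  decode_latent(object, object$embedding$mu)
}

#' Pearson residuals of the binomial reconstruction
#'
#' `(a - d * xhat) / sqrt(d * xhat * (1 - xhat))`, 0 where `d = 0`.
#'
#' @param object a fitted [snv_vae] object.
#' @param counts the training [allele_counts] (the fit does not store the
#'   raw counts).
#' @param ... unused.
#' @export
residuals.snv_vae <- function(object, counts, ...) {
  stopifnot(inherits(counts, "allele_counts"))
  check_width(object, counts)
  A <- as_dense(counts$A); D <- as_dense(counts$D)
  xhat <- decode_latent(object, encode_cells(object, counts)$mu)
  r <- (A - D * xhat) / sqrt(D * xhat * (1 - xhat))
  r[D == 0] <- 0
  r
}

#' Simulate allele counts from the fitted generative model
#'
#' Draws `a ~ Binomial(d, xhat)` at the given depths, with `xhat` the
#' reconstruction at the posterior means.
#'
#' @param object a fitted [snv_vae] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param counts an [allele_counts] object supplying the depths `D`.
#' @param ... unused.
#' @return list of `nsim` [allele_counts] objects.
#' @export
simulate.snv_vae <- function(object, nsim = 1, seed = 1, counts, ...) {
  stopifnot(inherits(counts, "allele_counts"))
  check_width(object, counts)
  D <- as_dense(counts$D)
  xhat <- decode_latent(object, encode_cells(object, counts)$mu)
  set.seed(seed)
  lapply(seq_len(nsim), function(s) {
    a <- matrix(stats::rbinom(length(D), size = as.vector(D),
                              prob = as.vector(xhat)), nrow(D), ncol(D))
    allele_counts(a, D, cells = counts$cells, variants = counts$variants)
  })
}

#' Binomial log-likelihood of the fit at the posterior means
#'
#' @param object a fitted [snv_vae] object.
#' @param counts the [allele_counts] to score.
#' @param ... unused.
#' @export
logLik.snv_vae <- function(object, counts, ...) {
  stopifnot(inherits(counts, "allele_counts"))
  xhat <- decode_latent(object, encode_cells(object, counts)$mu)
  ll <- -binomial_nll(as_dense(counts$A), as_dense(counts$D), xhat)
  structure(ll, df = sum(rapply(object$params, length, how = "unlist")),
            class = "logLik")
}

#' Plot the training trace or a 2D embedding of the latent space
#'
#' @param x a fitted [snv_vae] object.
#' @param type `"trace"` (cost per epoch) or `"umap"` (2D UMAP of the
#'   latent means).
#' @param labels optional per-cell labels to color the UMAP scatter.
#' @param seed seed for the UMAP layout.
#' @param ... passed to the underlying plot call.
#' @export
plot.snv_vae <- function(x, type = c("trace", "umap"), labels = NULL,
                         seed = 1, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
         ylab = "cost", main = "VAE training trace", ...)
  } else {
    xy <- umap_embed(x, n_components = 2, seed = seed)
    col <- if (is.null(labels)) 1 else as.integer(factor(labels))
    plot(xy$coords, col = col, pch = 16, cex = 0.6,
         xlab = "UMAP 1", ylab = "UMAP 2", main = "latent manifold", ...)
  }
  invisible(x)
}
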
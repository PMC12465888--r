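# Binomial variational autoencoder with observed-SNP normalization.
#
# Model, for each cell i with alt counts a_i, depths d_i and smoothed
# allele-frequency logits x_i = logit((a_i + c) / (d_i + 2c)) (exactly 0
# where d = 0):
#
#   (mu_raw, log sigma^2) = encoder_phi(x_i)
#   mu_i  = mu_raw / l_i,   l_i = #{j : d_ij > 0}   (observed-SNP norm.)
#   z_i   = mu_i + sigma_i * eps,  eps ~ N(0, I)    (one MC sample)
#   xhat_i = sigmoid(decoder_theta(z_i))
#   a_ij | d_ij, z_i ~ Binomial(d_ij, xhat_ij)
#
# cost = sum_i -log p(a_i | d_i, z_i) + beta * KL(q(z_i) || N(0, I)).
#
# The default architecture is a single affine map on each side (the logit
# and sigmoid are the only nonlinearities); deeper variants insert
# leaky-rectifier hidden layers. Training is full-batch Adam with exact
# analytic gradients; the binomial term is evaluated through the decoder
# logits (softplus form) for numerical stability, which never leaves (0,1).

init_linear <- function(fan_in, fan_out) {
  k <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -k, k), fan_in, fan_out),
       b = stats::runif(fan_out, -k, k))
}

linear_fwd <- function(X, layer) {
  Y <- X %*% layer$W
  Y + rep(layer$b, each = nrow(Y))
}

#' Fit a binomial variational autoencoder to single-cell allele counts
#'
#' Trains the model by full-batch Adam on the weighted sum of the binomial
#' reconstruction negative log-likelihood and `beta` times the KL divergence
#' of the variational posterior from a standard Gaussian prior, with one
#' Monte-Carlo sample per cell per epoch. The posterior mean head is divided
#' by each cell's observed-SNP count (observed-SNP normalization), which
#' makes the embedding insensitive to per-cell coverage.
#'
#' @param counts an [allele_counts] object (typically after [filter_counts()]).
#' @param latent_dim latent dimension `D`; default `floor(nSNP / 2)`, min 1.
#' @param beta weight of the KL term (default 0; the Monte-Carlo sampling
#'   step is kept even at 0).
#' @param epochs number of full-batch Adam steps (default 2000).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param weight_decay L2 penalty added to the gradients (default 0, off).
#' @param n_hidden_layers extra hidden layers with leaky-rectifier activation
#'   on each side (default 0: single affine encoder and decoder).
#' @param hidden_dim width of the optional hidden layers (default
#'   `2 * latent_dim`).
#' @param pseudocount smoothing constant for the input logit transform; with
#'   the symmetric smoothing `(a+c)/(d+2c)`, unobserved entries map to logit
#'   0 and contribute nothing to the affine encoder.
#' @param batch_size optional minibatch size; `NULL` (default) uses the full
#'   batch, which is exact for the data sizes this method targets.
#' @param seed integer seed governing initialization and Monte-Carlo
#'   sampling; fixed seed gives a bit-identical fit.
#' @param verbose print the cost every `ceiling(epochs / 10)` epochs.
#'
#' @return An object of class `snv_vae`: the fitted encoder/decoder
#'   parameters, the configuration, the per-epoch cost trace and the latent
#'   embedding of the training cells (`$embedding`, with posterior means
#'   `mu`, `log_var`, and the observed-SNP counts `l`).
#' @seealso [predict.snv_vae()], [cluster_cells()], [rank_snps()],
#'   [cluster_tree()]
#' @export
snv_vae <- function(counts, latent_dim = NULL, beta = 0, epochs = 2000,
                    learning_rate = 1e-4, weight_decay = 0,
                    n_hidden_layers = 0, hidden_dim = NULL, pseudocount = 1,
                    batch_size = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(counts, "allele_counts"))
  n <- nrow(counts$A); p <- ncol(counts$A)
  if (n < 1 || p < 1) stop_snvae("counts must be non-empty")
  if (is.null(latent_dim)) latent_dim <- max(1L, p %/% 2L)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1) stop_snvae("latent_dim must be >= 1")
  if (epochs < 1) stop_snvae("epochs must be >= 1")
  if (beta < 0 || learning_rate <= 0 || weight_decay < 0 || pseudocount <= 0) {
    stop_snvae("beta/weight_decay must be >= 0, learning_rate/pseudocount > 0")
  }
  if (is.null(hidden_dim)) hidden_dim <- 2L * latent_dim

  A <- as_dense(counts$A)
  D <- as_dense(counts$D)
  X <- logit((A + pseudocount) / (D + 2 * pseudocount))
  l_raw <- rowSums(D > 0)
  flagged <- l_raw == 0
  l <- pmax(l_raw, 1)

  config <- list(latent_dim = latent_dim, beta = beta, epochs = epochs,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_dim = as.integer(hidden_dim),
                 pseudocount = pseudocount, batch_size = batch_size,
                 seed = as.integer(seed), leaky_slope = 0.01, n_snps = p)

  set.seed(seed)
  params <- vae_init_params(p, config)
  opt <- adam_init(params)

  idx_all <- seq_len(n)
  batches <- if (is.null(batch_size)) list(idx_all) else
    unname(split(idx_all, ceiling(idx_all / batch_size)))
  full <- is.null(batch_size)
  trace <- numeric(epochs)
  trace_kl <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ep_cost <- 0
    ep_kl <- 0
    for (bi in batches) {
      if (full) {
        Xb <- X; Ab <- A; Db <- D; lb <- l
      } else {
        Xb <- X[bi, , drop = FALSE]; Ab <- A[bi, , drop = FALSE]
        Db <- D[bi, , drop = FALSE]; lb <- l[bi]
      }
      fw <- vae_forward(Xb, Ab, Db, lb, params, config, sample = TRUE)
      ep_cost <- ep_cost + fw$cost
      ep_kl <- ep_kl + fw$kl
      if (!is.finite(fw$cost)) {
        stop_snvae("non-finite cost at epoch ", ep,
                   "; reduce the learning rate or tighten pre-filtering")
      }
      grads <- vae_backward(fw, Ab, Db, lb, params, config)
      opt <- adam_step(params, grads, opt, learning_rate, weight_decay)
      params <- opt$params
    }
    trace[ep] <- ep_cost
    trace_kl[ep] <- ep_kl
    if (verbose && (ep %% max(1, ceiling(epochs / 10)) == 0 || ep == 1)) {
      message(sprintf("epoch %d / %d: cost = %.4f", ep, epochs, ep_cost))
    }
  }

  enc <- vae_encode_matrix(X, l, params, config)
  structure(list(
    params = params, config = config,
    embedding = list(mu = enc$mu, log_var = enc$log_var, l = l_raw,
                     flagged = flagged, cells = counts$cells),
    trace = trace, trace_kl = trace_kl, final_cost = trace[epochs],
    cells = counts$cells, variants = counts$variants,
    call = match.call()),
    class = "snv_vae")
}

vae_init_params <- function(p, config) {
  Dd <- config$latent_dim; h <- config$hidden_dim
  nh <- config$n_hidden_layers
  enc_hidden <- list(); dec_hidden <- list()
  w_in <- p
  if (nh > 0) {
    for (k in seq_len(nh)) {
      enc_hidden[[k]] <- init_linear(w_in, h)
      w_in <- h
    }
  }
  mu_head <- init_linear(w_in, Dd)
  lv_head <- init_linear(w_in, Dd)
  w_in <- Dd
  if (nh > 0) {
    for (k in seq_len(nh)) {
      dec_hidden[[k]] <- init_linear(w_in, h)
      w_in <- h
    }
  }
  out <- init_linear(w_in, p)
  list(enc_hidden = enc_hidden, mu_head = mu_head, lv_head = lv_head,
       dec_hidden = dec_hidden, out = out)
}

# Encoder pass shared by training and encode_cells()
vae_encode_matrix <- function(X, l, params, config) {
  H <- X
  pre <- list()
  for (k in seq_along(params$enc_hidden)) {
    pre[[k]] <- linear_fwd(H, params$enc_hidden[[k]])
    H <- leaky_relu(pre[[k]], config$leaky_slope)
  }
  mu_raw <- linear_fwd(H, params$mu_head)
  log_var <- linear_fwd(H, params$lv_head)
  mu <- mu_raw / l
  list(mu = mu, log_var = log_var, H = H, enc_pre = pre)
}

vae_decode_matrix <- function(Z, params, config) {
  G <- Z
  pre <- list()
  for (k in seq_along(params$dec_hidden)) {
    pre[[k]] <- linear_fwd(G, params$dec_hidden[[k]])
    G <- leaky_relu(pre[[k]], config$leaky_slope)
  }
  logits <- linear_fwd(G, params$out)
  list(logits = logits, G = G, dec_pre = pre)
}

vae_forward <- function(X, A, D, l, params, config, sample = TRUE) {
  enc <- vae_encode_matrix(X, l, params, config)
  sigma <- exp(0.5 * enc$log_var)
  eps <- if (sample) {
    matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
  } else {
    matrix(0, nrow(enc$mu), ncol(enc$mu))
  }
  Z <- enc$mu + sigma * eps
  dec <- vae_decode_matrix(Z, params, config)
  # binomial NLL through logits t: a*softplus(-t) + (d-a)*softplus(t),
  # folded into one softplus pass via softplus(t) = t + softplus(-t)
  nll <- sum((D - A) * dec$logits) + sum(D * softplus(-dec$logits))
  kl <- 0.5 * sum(sigma^2 + enc$mu^2 - enc$log_var - 1)
  cost <- nll + config$beta * kl
  c(enc, dec, list(X = X, sigma = sigma, eps = eps, Z = Z,
                   nll = nll, kl = kl, cost = cost))
}

vae_backward <- function(fw, A, D, l, params, config) {
  beta <- config$beta; slope <- config$leaky_slope
  g <- list(enc_hidden = list(), dec_hidden = list())

  dlogits <- D * sigmoid(fw$logits) - A
  g$out <- list(W = crossprod(fw$G, dlogits), b = colSums(dlogits))
  dG <- tcrossprod(dlogits, params$out$W)
  nh <- length(params$dec_hidden)
  if (nh > 0) {
    for (k in rev(seq_len(nh))) {
      dpre <- dG * leaky_relu_grad(fw$dec_pre[[k]], slope)
      inp <- if (k == 1) fw$Z else leaky_relu(fw$dec_pre[[k - 1]], slope)
      g$dec_hidden[[k]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
      dG <- tcrossprod(dpre, params$dec_hidden[[k]]$W)
    }
  }
  dZ <- dG
  dmu <- dZ + beta * fw$mu
  dlv <- dZ * fw$eps * 0.5 * fw$sigma + beta * 0.5 * (fw$sigma^2 - 1)
  dmu_raw <- dmu / l
  g$mu_head <- list(W = crossprod(fw$H, dmu_raw), b = colSums(dmu_raw))
  g$lv_head <- list(W = crossprod(fw$H, dlv), b = colSums(dlv))
  dH <- tcrossprod(dmu_raw, params$mu_head$W) +
    tcrossprod(dlv, params$lv_head$W)
  nh <- length(params$enc_hidden)
  if (nh > 0) {
    for (k in rev(seq_len(nh))) {
      dpre <- dH * leaky_relu_grad(fw$enc_pre[[k]], slope)
      inp <- if (k == 1) fw$X else leaky_relu(fw$enc_pre[[k - 1]], slope)
      g$enc_hidden[[k]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
      dH <- tcrossprod(dpre, params$enc_hidden[[k]]$W)
    }
  }
  g
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(params = params, m = zeros, v = zeros, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr, weight_decay = 0) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p) %||% seq_along(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      if (weight_decay > 0) g <- g + weight_decay * p
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$params <- r$p; opt$m <- r$m; opt$v <- r$v
  opt
}

# --- exported model-math pieces --------------------------------------------

#' Binomial reconstruction negative log-likelihood
#'
#' `-(a log xhat + (d - a) log(1 - xhat))` summed over entries; the binomial
#' coefficient, constant in `xhat`, is dropped. Entries with `d = 0`
#' contribute exactly 0.
#'
#' @param a alt-allele counts (vector or matrix), `0 <= a <= d`.
#' @param d total depths, same shape.
#' @param xhat reconstructed allele frequencies, strictly inside (0, 1);
#'   scalar or same shape.
#' @return non-negative scalar.
#' @export
binomial_nll <- function(a, d, xhat) {
  if (any(a < 0) || any(a > d)) stop_snvae("need 0 <= a <= d")
  if (any(xhat <= 0) || any(xhat >= 1)) {
    stop_snvae("xhat must lie strictly inside (0, 1)")
  }
  if (length(xhat) == 1) xhat <- array(xhat, dim = dim(as.matrix(a)))
  sum(-(a * log(xhat) + (d - a) * log1p(-xhat)))
}

#' KL divergence of a diagonal Gaussian from the standard Gaussian prior
#'
#' `0.5 * sum(sigma^2 + mu^2 - log sigma^2 - 1)`, the exact Kullback-Leibler
#' divergence `KL(N(mu, diag(sigma^2)) || N(0, I))`; non-negative, zero iff
#' `mu = 0` and `sigma^2 = 1`.
#'
#' @param mu posterior means (vector or matrix).
#' @param log_var posterior log-variances, same shape.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(mu, log_var) {
  sum(0.5 * (exp(log_var) + mu^2 - log_var - 1))
}

#' One-sample Monte-Carlo estimate of the training cost
#'
#' Encodes the cells, samples `z = mu + sigma * eps` once per cell with the
#' given seed, decodes, and returns the binomial NLL plus `beta` times the KL
#' term — exactly the quantity one training epoch optimizes.
#'
#' @param model a fitted [snv_vae] object.
#' @param counts an [allele_counts] object with the model's SNP panel.
#' @param beta KL weight; defaults to the model's configured value.
#' @param seed seed for the Monte-Carlo draw.
#' @return list with `cost`, `nll` and `kl`.
#' @export
vae_cost <- function(model, counts, beta = model$config$beta, seed = 1) {
  stopifnot(inherits(model, "snv_vae"), inherits(counts, "allele_counts"))
  check_width(model, counts)
  cfg <- model$config
  cfg$beta <- beta
  A <- as_dense(counts$A); D <- as_dense(counts$D)
  X <- logit((A + cfg$pseudocount) / (D + 2 * cfg$pseudocount))
  l <- pmax(rowSums(D > 0), 1)
  set.seed(seed)
  fw <- vae_forward(X, A, D, l, model$params, cfg, sample = TRUE)
  list(cost = fw$cost, nll = fw$nll, kl = fw$kl)
}

check_width <- function(model, counts) {
  p <- ncol(counts$A)
  if (p != model$config$n_snps) {
    stop_snvae("model was fit on ", model$config$n_snps,
               " SNPs but counts have ", p)
  }
}

#' Encode cells into the latent space
#'
#' Deterministic encoder pass (no sampling): per-cell posterior means after
#' observed-SNP normalization, posterior log-variances, and the observed-SNP
#' counts used as normalizers. Cells observing zero SNPs are encoded with
#' normalizer 1 and flagged; the pre-filter normally removes them.
#'
#' @param model a fitted [snv_vae] object.
#' @param counts an [allele_counts] object with the model's SNP panel.
#' @return An object of class `snv_embedding`: list with `mu` (cells x D),
#'   `log_var`, `l`, `flagged` and `cells`.
#' @export
encode_cells <- function(model, counts) {
  stopifnot(inherits(model, "snv_vae"), inherits(counts, "allele_counts"))
  check_width(model, counts)
  c <- model$config$pseudocount
  A <- as_dense(counts$A); D <- as_dense(counts$D)
  X <- logit((A + c) / (D + 2 * c))
  l_raw <- rowSums(D > 0)
  enc <- vae_encode_matrix(X, pmax(l_raw, 1), model$params, model$config)
  structure(list(mu = enc$mu, log_var = enc$log_var, l = l_raw,
                 flagged = l_raw == 0, cells = counts$cells),
            class = "snv_embedding")
}

#' Decode latent coordinates into reconstructed allele frequencies
#'
#' @param model a fitted [snv_vae] object.
#' @param z cells x D matrix of latent coordinates.
#' @return cells x SNPs matrix of reconstructed allele frequencies, strictly
#'   inside (0, 1).
#' @export
decode_latent <- function(model, z) {
  stopifnot(inherits(model, "snv_vae"))
  z <- as.matrix(z)
  if (ncol(z) != model$config$latent_dim) {
    stop_snvae("z has ", ncol(z), " columns; latent_dim is ",
               model$config$latent_dim)
  }
  dec <- vae_decode_matrix(z, model$params, model$config)
  xhat <- sigmoid(dec$logits)
  # keep strictly inside (0,1) against double rounding at extreme logits
  pmin(pmax(xhat, 1e-15), 1 - 1e-15)
}

#' @export
print.snv_embedding <- function(x, ...) {
  cat("snv_embedding: ", nrow(x$mu), " cells x ", ncol(x$mu),
      " latent dimensions", sep = "")
  if (any(x$flagged)) cat(" (", sum(x$flagged), " cells with no observed SNP)",
                          sep = "")
  cat("\n")
  invisible(x)
}
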
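test_that("binomial NLL matches the closed form and its edge cases", {
  # empty observation contributes nothing, whatever xhat is
  expect_equal(binomial_nll(0, 0, 0.3), 0)
  # a=1, d=2, xhat=0.5 -> -2 ln(0.5)
  expect_equal(binomial_nll(1, 2, 0.5), -2 * log(0.5), tolerance = 1e-12)
  # grid check against dbinom with the binomial coefficient removed
  for (d in c(1, 4, 9)) {
    for (a in 0:d) {
      for (x in c(0.05, 0.3, 0.77)) {
        ref <- -(dbinom(a, d, x, log = TRUE) - lchoose(d, a))
        expect_equal(binomial_nll(a, d, x), ref, tolerance = 1e-10)
      }
    }
  }
  # for a = d fixed, NLL is strictly decreasing in xhat
  xs <- seq(0.05, 0.95, by = 0.05)
  nlls <- sapply(xs, function(x) binomial_nll(3, 3, x))
  expect_true(all(diff(nlls) < 0))
  expect_error(binomial_nll(2, 1, 0.5), "a <= d")
  expect_error(binomial_nll(1, 2, 1), "strictly inside")
})

test_that("KL term is the exact Gaussian divergence, zero only at the prior", {
  expect_equal(kl_divergence(0, 0), 0)
  expect_equal(kl_divergence(1, 0), 0.5)
  # brute-force KL by numerical integration for a few (mu, sigma^2)
  for (mu in c(-1.2, 0.4)) {
    for (s2 in c(0.5, 1.7)) {
      f <- function(z) {
        q <- dnorm(z, mu, sqrt(s2))
        q * (dnorm(z, mu, sqrt(s2), log = TRUE) - dnorm(z, log = TRUE))
      }
      ref <- integrate(f, -20, 20)$value
      expect_equal(kl_divergence(mu, log(s2)), ref, tolerance = 1e-6)
    }
  }
  # non-negative on random inputs; zero iff mu = 0 and log_var = 0
  set.seed(1)
  for (i in 1:50) {
    mu <- rnorm(4); lv <- rnorm(4)
    expect_gte(kl_divergence(mu, lv), 0)
    expect_gt(kl_divergence(mu, lv), 0)  # almost surely off the minimum
  }
})

test_that("decoder output is strictly inside (0,1) and behaves at limits", {
  ac <- random_counts(5, 6, seed = 2)
  m <- snv_vae(ac, epochs = 2, seed = 1)
  # zero weights and bias -> 0.5 everywhere; z = 0 -> sigmoid(bias)
  m0 <- m
  m0$params$out$W[] <- 0; m0$params$out$b[] <- 0
  expect_true(all(decode_latent(m0, matrix(1, 2, m$config$latent_dim)) == 0.5))
  m0$params$out$b[] <- 2
  expect_equal(decode_latent(m0, matrix(0, 1, m$config$latent_dim))[1, 1],
               plogis(2), tolerance = 1e-12)
  # extreme latent inputs stay strictly inside (0,1)
  z <- matrix(1e6, 1, m$config$latent_dim)
  x <- decode_latent(m, z)
  expect_true(all(x > 0 & x < 1))
  # sigmoid monotone: larger logits, larger xhat
  m1 <- m
  m1$params$out$W[] <- 0
  out <- sapply(c(-3, 0, 3), function(b) {
    m1$params$out$b[] <- b
    decode_latent(m1, matrix(0, 1, m$config$latent_dim))[1, 1]
  })
  expect_true(all(diff(out) > 0))
})

test_that("encoder input handling and observed-SNP normalization", {
  # all-missing cell: encoder input is all zeros, mu = bias / 1, flagged
  D <- rbind(c(0, 0, 0), c(2, 1, 3))
  A <- rbind(c(0, 0, 0), c(1, 0, 2))
  ac <- allele_counts(A, D)
  m <- snv_vae(ac, latent_dim = 2, epochs = 2, seed = 3)
  emb <- encode_cells(m, ac)
  expect_true(emb$flagged[1] && !emb$flagged[2])
  expect_equal(emb$mu[1, ], m$params$mu_head$b, ignore_attr = TRUE,
               tolerance = 1e-12)
  # identical rows encode identically
  ac2 <- allele_counts(A[c(2, 2), ], D[c(2, 2), ])
  emb2 <- encode_cells(m, ac2)
  expect_identical(emb2$mu[1, ], emb2$mu[2, ])
  expect_identical(emb2$log_var[1, ], emb2$log_var[2, ])
})

test_that("embedding is insensitive to doubling the sequencing depth", {
  # strictly interior AFs and a tiny pseudo-count: doubling every depth (alt
  # counts scaled to keep AF) leaves the observed-SNP set and, up to O(c),
  # the logit inputs unchanged, so the normalized mu must match
  set.seed(4)
  D <- matrix(sample(c(4, 8, 12), 6 * 5, TRUE), 6, 5)
  A <- round(D * 0.5) + matrix(sample(c(-1, 1), 30, TRUE), 6, 5)
  ac <- allele_counts(A, D)
  m <- snv_vae(ac, latent_dim = 3, epochs = 2, pseudocount = 1e-8, seed = 1)
  doubled <- allele_counts(2 * A, 2 * D)
  mu1 <- encode_cells(m, ac)$mu
  mu2 <- encode_cells(m, doubled)$mu
  expect_equal(mu1, mu2, tolerance = 1e-6)
})

test_that("one-sample cost decomposes exactly and is reproducible", {
  ac <- random_counts(8, 6, seed = 5)
  m <- snv_vae(ac, epochs = 3, seed = 1)
  c0 <- vae_cost(m, ac, beta = 0, seed = 7)
  expect_identical(c0$cost, c0$nll)  # beta = 0: no hidden terms
  cb <- vae_cost(m, ac, beta = 0.5, seed = 7)
  expect_equal(cb$cost, cb$nll + 0.5 * cb$kl, tolerance = 1e-12)
  expect_identical(cb$nll, c0$nll)  # same seed, same Monte-Carlo draw
  # reproduce the sampled reconstruction NLL independently
  set.seed(7)
  emb <- encode_cells(m, ac)
  eps <- matrix(rnorm(length(emb$mu)), nrow(emb$mu), ncol(emb$mu))
  z <- emb$mu + exp(0.5 * emb$log_var) * eps
  ref <- binomial_nll(as.matrix(ac$A), as.matrix(ac$D), decode_latent(m, z))
  expect_equal(c0$cost, ref, tolerance = 1e-8)
  # zero-depth dataset: only the KL term remains
  zero <- allele_counts(matrix(0, 4, 6), matrix(0, 4, 6))
  cz <- vae_cost(m, zero, beta = 2, seed = 1)
  expect_identical(cz$nll, 0)
  expect_equal(cz$cost, 2 * cz$kl, tolerance = 1e-12)
})

test_that("training reduces the cost and is seed-deterministic", {
  sim <- simulate_donors(4, 50, 50, depth_mean = 2, seed = 1)
  for (seed in 1:3) {
    m <- snv_vae(sim$counts, epochs = 150, seed = seed)
    expect_lt(m$final_cost, m$trace[1])
  }
  m1 <- snv_vae(sim$counts, epochs = 60, seed = 9)
  m2 <- snv_vae(sim$counts, epochs = 60, seed = 9)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
})

test_that("a tiny beta perturbs the trace by no more than the KL magnitude", {
  sim <- simulate_donors(2, 20, 30, depth_mean = 2, seed = 2)
  beta <- 1e-6
  m0 <- snv_vae(sim$counts, epochs = 50, beta = 0, seed = 1)
  mb <- snv_vae(sim$counts, epochs = 50, beta = beta, seed = 1)
  # first epoch: same parameters and draws, so the difference is exactly
  # beta * KL of that forward pass
  expect_equal(mb$trace[1] - m0$trace[1], beta * mb$trace_kl[1],
               tolerance = 1e-9)
  # across the run the trajectories stay within the KL scale of each other
  expect_lt(max(abs(mb$trace - m0$trace)),
            2 * beta * max(mb$trace_kl) + 1e-6)
})

test_that("column permutation symmetry: permuting SNPs and weights preserves cost", {
  ac <- random_counts(6, 8, seed = 6)
  m <- snv_vae(ac, latent_dim = 3, epochs = 2, seed = 1)
  perm <- sample(8)
  acp <- ac[, perm]
  mp <- m
  mp$params$mu_head$W <- m$params$mu_head$W[perm, ]
  mp$params$lv_head$W <- m$params$lv_head$W[perm, ]
  mp$params$out$W <- m$params$out$W[, perm]
  mp$params$out$b <- m$params$out$b[perm]
  c1 <- vae_cost(m, ac, seed = 3)
  c2 <- vae_cost(mp, acp, seed = 3)
  expect_equal(c1$cost, c2$cost, tolerance = 1e-8)
})

test_that("hidden-layer variants train and keep gradients consistent", {
  ac <- random_counts(12, 10, seed = 8)
  m <- snv_vae(ac, latent_dim = 2, epochs = 40, n_hidden_layers = 1,
               hidden_dim = 6, seed = 2)
  expect_lt(m$final_cost, m$trace[1])
  # finite-difference check of one encoder weight under a fixed draw
  cfg <- m$config
  A <- as.matrix(ac$A); D <- as.matrix(ac$D)
  X <- qlogis((A + 1) / (D + 2))
  l <- pmax(rowSums(D > 0), 1)
  fwd_cost <- function(params, seed = 5) {
    set.seed(seed)
    snvae:::vae_forward(X, A, D, l, params, cfg, sample = TRUE)$cost
  }
  set.seed(5)
  fw <- snvae:::vae_forward(X, A, D, l, m$params, cfg, sample = TRUE)
  gr <- snvae:::vae_backward(fw, A, D, l, m$params, cfg)
  h <- 1e-5
  for (probe in list(c(1, 1), c(3, 2))) {
    pp <- pm <- m$params
    pp$enc_hidden[[1]]$W[probe[1], probe[2]] <-
      pp$enc_hidden[[1]]$W[probe[1], probe[2]] + h
    pm$enc_hidden[[1]]$W[probe[1], probe[2]] <-
      pm$enc_hidden[[1]]$W[probe[1], probe[2]] - h
    num <- (fwd_cost(pp) - fwd_cost(pm)) / (2 * h)
    expect_equal(gr$enc_hidden[[1]]$W[probe[1], probe[2]], num,
                 tolerance = 1e-4)
  }
})

test_that("non-finite cost aborts with the epoch index", {
  ac <- random_counts(5, 4, seed = 1)
  expect_error(snv_vae(ac, epochs = 50, learning_rate = 1e6, seed = 1),
               "epoch")
})
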
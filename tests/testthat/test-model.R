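test_that("M1 posterior parameters are affine in the encoding", {
  zm <- zero_model()
  p <- m1_infer(zm, rep(1, zm$config$d_h))
  expect_identical(drop(p$mu), rep(0, zm$config$d_z))
  expect_identical(drop(p$logvar), rep(0, zm$config$d_z))

  cfg <- cantm_config(vocab_size = 2L, n_classes = 2L, d_h = 1L,
                      d_z = 1L, d_zs = 1L, d_m = 1L)
  m <- init_cantm(cfg, make_vocab(c("aa", "bb")), c("x", "y"), seed = 1)
  m$w$W1 <- matrix(2); m$w$b1 <- 1
  expect_equal(drop(m1_infer(m, 3)$mu), 7)

  m2 <- random_model()
  h <- rnorm(m2$config$d_h)
  expect_identical(m1_infer(m2, h), m1_infer(m2, h))
  expect_error(m1_infer(m2, c(NaN, 1, 1)), "finite")
})

test_that("reparameterisation reproduces z = mu + sigma * eps", {
  p <- structure(list(mu = c(0, 0), logvar = c(0, 0)), class = "cantm_gauss")
  s <- reparameterize(p, n_samples = 1L, eps = matrix(0.5, 1, 2))
  expect_equal(drop(s$z), c(0.5, 0.5))

  # sigma -> 0 limit collapses onto the mean
  p2 <- structure(list(mu = c(3, -1), logvar = c(-40, -40)), class = "cantm_gauss")
  s2 <- reparameterize(p2, n_samples = 1L, seed = 4L)
  expect_equal(drop(s2$z), c(3, -1), tolerance = 1e-6)

  expect_identical(reparameterize(p, 5L, seed = 9L)$z,
                   reparameterize(p, 5L, seed = 9L)$z)

  # Monte-Carlo mean approaches mu at the stated normal rate
  p3 <- structure(list(mu = c(1.5), logvar = c(0.4)), class = "cantm_gauss")
  draws <- reparameterize(p3, n_samples = 1e5L, seed = 2L)$z
  se <- exp(0.4 / 2) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 1.5), 3 * se)
})

test_that("M1 reconstruction is the multinomial bag-of-words log-likelihood", {
  zm <- zero_model(V = 4L)
  x <- c(2, 0, 1, 0)
  expect_equal(m1_reconstruct_logprob(zm, rep(0, 2), x), 3 * log(1 / 4))

  m <- random_model()
  z <- rnorm(m$config$d_z)
  xx <- c(1, 0, 2, 1, 0, 3)
  expect_lte(m1_reconstruct_logprob(m, z, xx), 0)

  # |V| = 2 with logits [ln 3, 0]
  cfg <- cantm_config(vocab_size = 2L, n_classes = 2L, d_h = 1L,
                      d_z = 1L, d_zs = 1L, d_m = 1L)
  m2 <- init_cantm(cfg, make_vocab(c("aa", "bb")), c("x", "y"), seed = 1)
  m2$w$R <- matrix(c(log(3), 0), 1, 2); m2$w$bR <- c(0, 0)
  expect_equal(m1_reconstruct_logprob(m2, 1, c(1, 1)),
               log(3 / 4) + log(1 / 4))
  expect_error(m1_reconstruct_logprob(m2, 1, c(0, 0)), "zero bag-of-words")
})

test_that("classifier softmax normalises and matches hand values", {
  zm <- zero_model(K = 2L)
  expect_equal(drop(classify(zm, c(0, 0))), c(c01 = 0.5, c02 = 0.5))

  cfg <- cantm_config(vocab_size = 2L, n_classes = 2L, d_h = 1L,
                      d_z = 1L, d_zs = 1L, d_m = 1L)
  m <- init_cantm(cfg, make_vocab(c("aa", "bb")), c("x", "y"), seed = 1)
  m$w$Wc <- matrix(c(0, log(3)), 1, 2)
  expect_equal(unname(drop(classify(m, 1))), c(0.25, 0.75))

  mr <- random_model(K = 2L)
  P <- classify(mr, matrix(rnorm(10 * mr$config$d_z), 10))
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-6)
})

test_that("one-hot predictions select a single class-topic row exactly", {
  m <- random_model(V = 5L, K = 3L)
  x <- c(1, 0, 2, 0, 1)
  for (k in 1:3) {
    onehot <- as.numeric(seq_len(3) == k)
    logits <- m$w$Rct[k, ] + m$w$bct
    logp <- logits - max(logits) - log(sum(exp(logits - max(logits))))
    expect_equal(class_decoder_logprob(m, onehot, x), sum(x * logp))
  }
  # uniform logits, 3 tokens
  zm <- zero_model(V = 4L)
  expect_equal(class_decoder_logprob(zm, c(0.5, 0.5), c(1, 1, 1, 0)),
               3 * log(1 / 4))
  # mixture of rows
  yh <- c(0.5, 0.5, 0)
  mix_logits <- drop(yh %*% m$w$Rct) + m$w$bct
  logp <- mix_logits - max(mix_logits) -
    log(sum(exp(mix_logits - max(mix_logits))))
  expect_equal(class_decoder_logprob(m, yh, x), sum(x * logp))
})

test_that("M2 encoder merges the encoding with the predicted label", {
  zm <- zero_model()
  r <- m2_infer(zm, rep(0, zm$config$d_h), c(0.5, 0.5))
  expect_identical(drop(r$m), rep(0, zm$config$d_m))
  expect_identical(drop(r$params$mu), rep(0, zm$config$d_zs))
  expect_identical(drop(r$params$logvar), rep(0, zm$config$d_zs))

  # hand-computed 2-d toy with a negative pre-activation
  cfg <- cantm_config(vocab_size = 2L, n_classes = 2L, d_h = 1L,
                      d_z = 1L, d_zs = 1L, d_m = 2L)
  m <- init_cantm(cfg, make_vocab(c("aa", "bb")), c("x", "y"), seed = 1)
  m$w$Wm <- matrix(c(1, 0, 0.5, # column 1: h, y1, y2
                     -2, 1, 0), 3, 2)
  m$w$bm <- c(0, 0)
  r2 <- m2_infer(m, h = 2, yhat = c(0.25, 0.75))
  # pre-activations: [2*1 + 0.25*0 + 0.75*0.5, 2*-2 + 0.25*1 + 0.75*0]
  expect_equal(drop(r2$m), c(2.375, 0.01 * -3.75))
  expect_error(m2_infer(m, h = c(1, 2), yhat = c(1, 0, 0)), "mismatch")
})

test_that("M2 decoder likelihoods are valid log-probabilities", {
  zm <- zero_model(V = 4L)
  r <- m2_reconstruct_logprob(zm, c(1, 0), rep(0, 2), c(2, 1, 0, 0))
  expect_equal(r$logprob, 3 * log(1 / 4))

  m <- random_model()
  out <- m2_reconstruct_logprob(m, c(0.3, 0.7), rnorm(2), c(1, 2, 0, 0, 1, 0))
  expect_lte(out$logprob, 0)

  # label term: uniform M2 softmax gives log(1/|y|) for any yhat
  expect_equal(m2_label_logprob(zm, rep(0, 2), c(0.9, 0.1)), log(1 / 2))
  # one-hot selection
  zs <- rnorm(m$config$d_zs)
  lsm <- drop(zs %*% m$w$Wy2) + m$w$by2
  lsm <- lsm - max(lsm) - log(sum(exp(lsm - max(lsm))))
  expect_equal(m2_label_logprob(m, zs, c(1, 0)), lsm[1])
  # soft-label mixture
  expect_equal(m2_label_logprob(zm, rep(0, 2), c(0.25, 0.75)), log(0.5))
})

test_that("forward pass is sampled in training and deterministic at test time", {
  m <- random_model(V = 6L, K = 2L)
  x <- c(2, 0, 1, 1, 0, 1)
  te1 <- cantm_forward(m, x, mode = "test")
  te2 <- cantm_forward(m, x, mode = "test")
  expect_identical(te1$yhat, te2$yhat)
  expect_equal(te1$yhat_mean, classify(m, te1$m1_params$mu)[1, ])

  tr1 <- cantm_forward(m, x, n_samples = 10L, mode = "train", seed = 5L)
  tr2 <- cantm_forward(m, x, n_samples = 10L, mode = "train", seed = 5L)
  expect_identical(tr1$z, tr2$z)
  expect_identical(nrow(tr1$z), 10L)
  expect_length(tr1$recon_m1, 10L)
  expect_length(tr1$recon_m2, 10L)
  expect_equal(unname(rowSums(tr1$yhat)), rep(1, 10), tolerance = 1e-6)
  expect_true(all(tr1$recon_m1 <= 0 & tr1$recon_m2 <= 0 & tr1$recon_ct <= 0))
  expect_true(all(is.finite(tr1$z)) && all(is.finite(tr1$zs)))
  expect_error(cantm_forward(m, rep(0, 6)), "empty document")
})

test_that("latent samples reproduce from their stored noise draws", {
  m <- random_model()
  x <- c(1, 1, 0, 2, 0, 0)
  fo <- cantm_forward(m, x, n_samples = 4L, mode = "train", seed = 8L)
  mu <- drop(fo$m1_params$mu)
  sg <- exp(drop(fo$m1_params$logvar) / 2)
  rebuilt <- sweep(sweep(fo$eps, 2, sg, "*"), 2, mu, "+")
  expect_equal(fo$z, rebuilt)
})
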
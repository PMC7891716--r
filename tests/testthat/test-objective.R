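test_that("closed-form KL against N(0, I) matches hand values and is non-negative", {
  p0 <- structure(list(mu = c(0, 0), logvar = c(0, 0)), class = "cantm_gauss")
  expect_equal(kl_diag_gaussian(p0), 0)
  p1 <- structure(list(mu = 1, logvar = 0), class = "cantm_gauss")
  expect_equal(kl_diag_gaussian(p1), 0.5)
  set.seed(31)
  for (i in 1:100) {
    p <- structure(list(mu = rnorm(4), logvar = rnorm(4)), class = "cantm_gauss")
    expect_gte(kl_diag_gaussian(p), 0)
  }
  expect_error(kl_diag_gaussian(list(mu = Inf, logvar = 0)), "finite")
})

test_that("classifier cross-entropy averages over latent samples", {
  expect_equal(cross_entropy_cls(c(1, 0), 1L), 0)
  expect_equal(cross_entropy_cls(rep(1 / 10, 10), 3L), log(10))
  yh <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy_cls(yh, 1L), (log(2) + log(4)) / 2)
  colnames(yh) <- c("x", "y")
  expect_equal(cross_entropy_cls(yh, "x"), (log(2) + log(4)) / 2)
  expect_error(cross_entropy_cls(yh, "zz"), "label")
})

test_that("loss components satisfy the assembly identity on random forwards", {
  m <- random_model(V = 6L, K = 2L)
  set.seed(13)
  for (i in 1:20) {
    x <- rmultinom(1, 8, rep(1 / 6, 6))[, 1]
    fo <- cantm_forward(m, x, n_samples = 3L, mode = "train")
    lc <- loss_components(fo, gold = sample(2, 1), lambda = m$config$lambda)
    expect_equal(lc$total,
                 lc$lambda * lc$l_cls - lc$recon_m1 + lc$kl_m1 - lc$recon_m2 -
                   lc$label_m2 + lc$kl_m2 - lc$recon_ct,
                 tolerance = 1e-6)
    expect_gte(lc$l_cls, 0)
    expect_gte(lc$kl_m1, 0)
    expect_gte(lc$kl_m2, 0)
    expect_lte(lc$recon_m1, 0)
  }
})

test_that("the objective is linear in the classifier weight", {
  m <- random_model(V = 6L, K = 2L)
  x <- c(2, 1, 0, 0, 1, 1)
  fo <- cantm_forward(m, x, n_samples = 2L, mode = "train", seed = 3L)
  l1 <- loss_components(fo, gold = 1L, lambda = 10)
  l2 <- loss_components(fo, gold = 1L, lambda = 20)
  expect_equal(l2$total - l1$total, 10 * l1$l_cls)
})

test_that("with supervision and stacking disabled the loss is the document-model bound", {
  m <- random_model(V = 6L, K = 2L)
  x <- c(1, 0, 2, 1, 0, 1)
  fo <- cantm_forward(m, x, n_samples = 5L, mode = "train", seed = 6L)
  lc <- loss_components(fo, gold = NULL, include_m2 = FALSE,
                        include_class_decoder = FALSE)
  expect_equal(lc$total, -lc$recon_m1 + lc$kl_m1)
  expect_identical(lc$recon_m2, 0)
  expect_identical(lc$recon_ct, 0)
  # and equals the independently coded unsupervised ELBO on shared draws
  oracle <- nvdm_neg_elbo(m$w, x, fo$eps)
  expect_equal(lc$total, oracle, tolerance = 1e-6)
})

test_that("training reduces the loss and is reproducible", {
  spec <- synthetic_spec(n_docs = 120L, n_classes = 4L, vocab_size = 40L,
                         signature_size = 5L, separation = 0.9,
                         doc_length = c(8L, 15L), seed = 2L)
  gen <- generate_corpus(spec)
  voc <- build_vocabulary(gen$corpus, max_size = 40L)
  cfg <- train_config(epochs = 10L, seed = 5L, val_fraction = 0,
                      n_samples_train = 5L)
  fit <- train_supervised(gen$corpus, vocab = voc, cfg = cfg)
  log <- attr(fit, "train_log")
  expect_lt(log$total[nrow(log)], log$total[1])
  fit2 <- train_supervised(gen$corpus, vocab = voc, cfg = cfg)
  expect_identical(fit$w, fit2$w)
})

test_that("a large classifier weight buys training accuracy over none", {
  spec <- synthetic_spec(n_docs = 120L, n_classes = 4L, vocab_size = 40L,
                         signature_size = 5L, separation = 0.8,
                         doc_length = c(8L, 15L), seed = 3L)
  gen <- generate_corpus(spec)
  voc <- build_vocabulary(gen$corpus, max_size = 40L)
  acc_for <- function(lambda) {
    cfg <- train_config(epochs = 12L, seed = 5L, val_fraction = 0,
                        n_samples_train = 5L, lambda = lambda)
    fit <- train_supervised(gen$corpus, vocab = voc, cfg = cfg)
    mean(predict_corpus(fit, gen$corpus)$label == gen$corpus$label)
  }
  expect_gt(acc_for(100), acc_for(0))
})

test_that("small corpora fall back to a single smaller batch with a warning", {
  spec <- synthetic_spec(n_docs = 12L, n_classes = 2L, vocab_size = 20L,
                         signature_size = 4L, separation = 0.9,
                         doc_length = c(6L, 10L), seed = 4L)
  gen <- generate_corpus(spec)
  voc <- build_vocabulary(gen$corpus, max_size = 20L)
  cfg <- train_config(epochs = 2L, seed = 1L, val_fraction = 0)
  expect_warning(train_supervised(gen$corpus, vocab = voc, cfg = cfg),
                 "smaller than one batch")
})

test_that("unlabelled adaptation freezes the M1 stack and updates only M2 paths", {
  spec <- synthetic_spec(n_docs = 80L, n_classes = 3L, vocab_size = 30L,
                         signature_size = 5L, separation = 0.9,
                         doc_length = c(8L, 14L), seed = 6L)
  gen <- generate_corpus(spec)
  lab <- gen$corpus[1:50, ]
  unlab <- gen$corpus[51:80, ]
  unlab$label <- NA_character_
  voc <- build_vocabulary(lab, max_size = 30L)
  fit <- train_supervised(lab, vocab = voc,
                          cfg = train_config(epochs = 4L, seed = 2L,
                                             val_fraction = 0,
                                             n_samples_train = 3L))
  frozen_before <- fit$w[cantm:::.m1_param_names()]
  hash_before <- m1_parameter_hash(fit)
  pred_before <- predict_corpus(fit, gen$corpus)
  ad <- suppressWarnings(
    adapt_unlabelled(fit, unlab,
                     cfg = train_config(epochs = 4L, seed = 3L,
                                        val_fraction = 0,
                                        n_samples_train = 3L)))
  expect_identical(ad$w[cantm:::.m1_param_names()], frozen_before)
  expect_identical(m1_parameter_hash(ad), hash_before)
  expect_identical(predict_corpus(ad, gen$corpus), pred_before)
  # at least one trainable parameter moved
  expect_false(identical(ad$w$Rs, fit$w$Rs))
  expect_false(identical(ad$w$Rct, fit$w$Rct))
  # restricting to M2 only leaves the class decoder untouched as well
  ad2 <- suppressWarnings(
    adapt_unlabelled(fit, unlab,
                     cfg = train_config(epochs = 2L, seed = 3L,
                                        val_fraction = 0,
                                        n_samples_train = 3L,
                                        include_class_decoder = FALSE)))
  expect_identical(ad2$w$Rct, fit$w$Rct)
})
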
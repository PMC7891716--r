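# Training objective and optimisation.
#
# Per document the loss is
#   L = lambda * L_cls - E_z[log p(x|z)] + KL(q(z|x) || N(0,I))
#       - E[log p(x|yhat, z_s)] - E[log p(yhat|z_s)] + KL(q(z_s|x,yhat) || N(0,I))
#       - E[log p(x|yhat)]
# with sample-averaged expectations, closed-form KLs against standard-normal
# priors, and lambda defaulting to |V| / |y|.

#' Closed-form KL divergence of a diagonal Gaussian against N(0, I)
#'
#' `0.5 * sum(mu^2 + sigma^2 - logvar - 1)` with `sigma^2 = exp(logvar)`;
#' non-negative for every input.
#'
#' @param params A `cantm_gauss` (or list with `mu`, `logvar`); matrices give
#'   one value per row.
#' @return Numeric vector of KL divergences.
#' @export
kl_diag_gaussian <- function(params) {
  mu <- .as_row(params$mu); lv <- .as_row(params$logvar)
  if (any(!is.finite(mu)) || any(!is.finite(lv))) stop("non-finite Gaussian parameters")
  0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
}

#' Classifier cross-entropy, averaged over latent samples
#'
#' @param yhat Per-sample class-probability matrix (rows = samples) or vector.
#' @param gold Gold label: class name (matched against column names) or
#'   1-based index.
#' @return `-log yhat[gold]` averaged over the sample rows.
#' @export
cross_entropy_cls <- function(yhat, gold) {
  Y <- .as_row(yhat)
  if (is.character(gold)) {
    if (is.null(colnames(Y)) || !gold %in% colnames(Y)) {
      stop("gold label not in label set: ", gold)
    }
    gold <- match(gold, colnames(Y))
  }
  if (is.na(gold) || gold < 1L || gold > ncol(Y)) stop("gold label out of range")
  mean(-log(pmax(Y[, gold], 1e-12)))
}

#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (experimental default 32).
#' @param n_samples_train,n_samples_test Latent draws during training /
#'   evaluation (experimental defaults 10 and 1).
#' @param lr Adam step size.
#' @param lambda Classifier-loss weight; `NULL` = model default `|V|/|y|`.
#' @param seed Seed governing shuffling, initial noise and validation split.
#' @param val_fraction Fraction held out for early stopping (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param include_m2,include_class_decoder Toggle the stacked-M2 and
#'   class-decoder loss terms (both on for the full model; both off with
#'   `lambda = 0` reduces the objective to the unsupervised NVDM bound).
#' @param verbose Print per-epoch losses?
#' @return A `cantm_train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         n_samples_train = 10L, n_samples_test = 1L,
                         lr = 1e-3, lambda = NULL, seed = 1L,
                         val_fraction = 0.1, patience = 5L,
                         include_m2 = TRUE, include_class_decoder = TRUE,
                         verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_samples_train = as.integer(n_samples_train),
                 n_samples_test = as.integer(n_samples_test),
                 lr = lr, lambda = lambda, seed = as.integer(seed),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 include_m2 = include_m2,
                 include_class_decoder = include_class_decoder,
                 verbose = verbose),
            class = "cantm_train_config")
}

#' Assemble the loss components for one forward pass
#'
#' @param fo A [cantm_forward()] result.
#' @param gold Gold label name/index, or `NULL` for the unsupervised terms
#'   only (classifier term dropped).
#' @param lambda Classifier weight; `NULL` = `|V|/|y|` from the forward pass
#'   dimensions is NOT inferable here, so pass the model's `config$lambda`
#'   (the exported [total_loss()] wrapper does this for you).
#' @param include_m2,include_class_decoder Term toggles.
#' @return Object of class `cantm_loss`: the seven named terms (`l_cls`,
#'   `recon_m1`, `kl_m1`, `recon_m2`, `label_m2`, `kl_m2`, `recon_ct`, all
#'   sample-averaged, reconstruction/label terms stored as log-likelihoods)
#'   and `total` satisfying
#'   `total = lambda*l_cls - recon_m1 + kl_m1 - recon_m2 - label_m2 + kl_m2 - recon_ct`.
#' @export
loss_components <- function(fo, gold = NULL, lambda = 1,
                            include_m2 = TRUE, include_class_decoder = TRUE) {
  stopifnot(inherits(fo, "cantm_forward"))
  f2 <- as.numeric(include_m2); fct <- as.numeric(include_class_decoder)
  l_cls <- if (is.null(gold)) 0 else cross_entropy_cls(fo$yhat, gold)
  if (is.null(gold)) lambda <- 0
  comp <- list(
    l_cls = l_cls,
    recon_m1 = mean(fo$recon_m1),
    kl_m1 = fo$kl_m1,
    recon_m2 = f2 * mean(fo$recon_m2),
    label_m2 = f2 * mean(fo$label_m2),
    kl_m2 = f2 * fo$kl_m2,
    recon_ct = fct * mean(fo$recon_ct),
    lambda = lambda
  )
  comp$total <- lambda * comp$l_cls - comp$recon_m1 + comp$kl_m1 -
    comp$recon_m2 - comp$label_m2 + comp$kl_m2 - comp$recon_ct
  structure(comp, class = "cantm_loss")
}

#' Total loss for one document under a model
#'
#' Convenience wrapper running [cantm_forward()] then [loss_components()]
#' with the model's configured `lambda`.
#'
#' @param model A `cantm_model`.
#' @param x_bow Document count vector.
#' @param gold Gold label or `NULL`.
#' @param n_samples Latent draws.
#' @param seed Optional seed.
#' @inheritParams loss_components
#' @return A `cantm_loss`.
#' @export
total_loss <- function(model, x_bow, gold = NULL, n_samples = 10L,
                       seed = NULL, include_m2 = TRUE,
                       include_class_decoder = TRUE) {
  fo <- cantm_forward(model, x_bow, n_samples = n_samples, mode = "train",
                      seed = seed)
  loss_components(fo, gold = gold, lambda = model$config$lambda,
                  include_m2 = include_m2,
                  include_class_decoder = include_class_decoder)
}

#' @export
print.cantm_loss <- function(x, ...) {
  cat(sprintf(paste0("<cantm_loss> total = %.4f\n",
                     "  l_cls %.4f | recon_m1 %.2f | kl_m1 %.3f | recon_m2 %.2f",
                     " | label_m2 %.3f | kl_m2 %.3f | recon_ct %.2f\n"),
              x$total, x$l_cls, x$recon_m1, x$kl_m1, x$recon_m2,
              x$label_m2, x$kl_m2, x$recon_ct))
  invisible(x)
}

# --- Adam ------------------------------------------------------------------

.adam_init <- function(w, names) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names) {
    st$m[[nm]] <- w[[nm]] * 0
    st$v[[nm]] <- w[[nm]] * 0
  }
  st
}

.adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(st$m)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(w = w, st = st)
}

# --- training loops --------------------------------------------------------

# deterministic evaluation loss (z = mu paths) over a document set
.eval_loss <- function(model, X, gold_idx, cfg) {
  fo <- .forward_batch(model, X, S = 1L, sample = FALSE)
  lr <- .loss_rows(fo, gold_idx, lambda = .cfg_lambda(model, cfg),
                   include_m2 = cfg$include_m2,
                   include_class_decoder = cfg$include_class_decoder)
  mean(lr$total)
}

.cfg_lambda <- function(model, cfg) {
  if (is.null(cfg$lambda)) model$config$lambda else cfg$lambda
}

# core minibatch loop; gold_idx NULL => unsupervised (adaptation)
.train_loop <- function(model, X, gold_idx, cfg, trainable,
                        X_val = NULL, gold_val = NULL) {
  rng <- .local_rng(cfg$seed + 1L)
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  if (bs < cfg$batch_size) {
    warning(sprintf("corpus (%d docs) smaller than one batch; using batch size %d", n, bs))
  }
  st <- .adam_init(model$w, trainable)
  lambda <- .cfg_lambda(model, cfg)
  S <- cfg$n_samples_train
  log <- list()
  best <- list(loss = Inf, w = model$w, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- rng$sample(n)
    comp_sum <- NULL; n_rows <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      gb <- if (is.null(gold_idx)) NULL else gold_idx[idx]
      N <- nrow(Xb) * S
      eps <- matrix(rng$rnorm(N * model$config$d_z), N, model$config$d_z)
      eps_s <- matrix(rng$rnorm(N * model$config$d_zs), N, model$config$d_zs)
      fo <- .forward_batch(model, Xb, S = S, sample = TRUE,
                           eps = eps, eps_s = eps_s)
      grad <- .backward_batch(model, fo, gb, lambda,
                              include_m2 = cfg$include_m2,
                              include_class_decoder = cfg$include_class_decoder)
      upd <- .adam_step(model$w, grad[trainable], st, cfg$lr)
      model$w[trainable] <- upd$w[trainable]
      st <- upd$st
      lr_rows <- .loss_rows(fo, gb, lambda, cfg$include_m2,
                            cfg$include_class_decoder)
      sums <- vapply(lr_rows, sum, numeric(1))
      comp_sum <- if (is.null(comp_sum)) sums else comp_sum + sums
      n_rows <- n_rows + length(lr_rows$total)
    }
    epoch_log <- as.list(comp_sum / n_rows)
    epoch_log$epoch <- ep
    if (!is.null(X_val)) {
      epoch_log$val_loss <- .eval_loss(model, X_val, gold_val, cfg)
      if (epoch_log$val_loss < best$loss - 1e-9) {
        best <- list(loss = epoch_log$val_loss, w = model$w, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log[[ep]] <- epoch_log
    if (cfg$verbose) {
      cat(sprintf("epoch %3d  total %.3f%s\n", ep, epoch_log$total,
                  if (!is.null(epoch_log$val_loss))
                    sprintf("  val %.3f", epoch_log$val_loss) else ""))
    }
    if (!is.null(X_val) && wait >= cfg$patience) break
  }
  if (!is.null(X_val) && is.finite(best$loss)) model$w <- best$w
  attr(model, "train_log") <- do.call(rbind, lapply(log, as.data.frame))
  model
}

#' Train the full model on a labelled corpus
#'
#' Minimises the mean per-document loss by Adam over minibatches, with
#' `n_samples_train` reparameterised draws per document per step. A fraction
#' of the corpus can be held out for early stopping on the deterministic
#' validation loss.
#'
#' @param corpus Tokenised, labelled corpus data.frame (or omit and supply
#'   `X`/`y` directly).
#' @param vocab A [build_vocabulary()] result; built from the corpus when
#'   `NULL` (capped at 2000 tokens).
#' @param cfg A [train_config()].
#' @param model Optional pre-initialised `cantm_model` (for warm starts).
#' @param X,y Optional precomputed count matrix and label vector overriding
#'   `corpus`.
#' @return The trained `cantm_model`, with the per-epoch loss-component log
#'   in `attr(, "train_log")`.
#' @export
train_supervised <- function(corpus = NULL, vocab = NULL,
                             cfg = train_config(), model = NULL,
                             X = NULL, y = NULL) {
  if (is.null(X)) {
    stopifnot(is.data.frame(corpus), !is.null(corpus$tokens))
    if (is.null(vocab)) vocab <- build_vocabulary(corpus, max_size = 2000L)
    X <- corpus_bow_matrix(corpus, vocab)
    y <- corpus$label
  }
  if (is.null(y) || any(is.na(y))) stop("supervised training needs a gold label for every document")
  keep <- rowSums(X) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d documents empty after vectorisation", sum(!keep)))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (is.null(model)) {
    labels <- sort(unique(y))
    config <- cantm_config(vocab_size = ncol(X), n_classes = length(labels))
    model <- init_cantm(config, vocab, labels, seed = cfg$seed)
  }
  gold_idx <- match(y, model$labels)
  if (any(is.na(gold_idx))) stop("label outside the model's label set")
  X_val <- NULL; gold_val <- NULL
  if (cfg$val_fraction > 0 && nrow(X) >= 20L) {
    rng <- .local_rng(cfg$seed + 2L)
    n_val <- max(1L, floor(cfg$val_fraction * nrow(X)))
    vi <- rng$sample(nrow(X))[seq_len(n_val)]
    X_val <- X[vi, , drop = FALSE]; gold_val <- gold_idx[vi]
    X <- X[-vi, , drop = FALSE]; gold_idx <- gold_idx[-vi]
  }
  .train_loop(model, X, gold_idx, cfg, trainable = names(model$w),
              X_val = X_val, gold_val = gold_val)
}

#' Adapt the stacked M2 model (and class decoder) to unlabelled data
#'
#' Re-trains the classification-aware topic machinery on an unlabelled
#' corpus: every M1 parameter (encoder, posterior maps, decoder, classifier)
#' is frozen bit-identically, the frozen classifier's prediction provides the
#' label signal, and only the class-decoder path (`Rct`) and the M2 encoder /
#' decoder parameters are updated.
#'
#' @param model A trained `cantm_model`.
#' @param corpus Tokenised unlabelled corpus (or supply `X`).
#' @param cfg A [train_config()] (`lambda` is ignored: there is no gold
#'   label; `include_class_decoder = FALSE` restricts updates to M2 only).
#' @param X Optional precomputed count matrix (columns = model vocabulary).
#' @return The adapted `cantm_model` with training log attribute.
#' @export
adapt_unlabelled <- function(model, corpus = NULL, cfg = train_config(),
                             X = NULL) {
  stopifnot(inherits(model, "cantm_model"))
  if (is.null(X)) {
    stopifnot(is.data.frame(corpus), !is.null(corpus$tokens))
    X <- corpus_bow_matrix(corpus, model$vocab)
  }
  keep <- rowSums(X) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d documents empty after vectorisation", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  trainable <- setdiff(names(model$w), .m1_param_names())
  if (!cfg$include_class_decoder) trainable <- setdiff(trainable, c("Rct", "bct"))
  .train_loop(model, X, gold_idx = NULL, cfg, trainable = trainable,
              X_val = NULL, gold_val = NULL)
}
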
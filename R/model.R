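# Stacked-VAE model core.
#
# M1: q(z|x) with h = Enc(x), mu = h W1 + b1, logvar = h W2 + b2;
#     p(x_bow|z) = softmax(z R + bR) . x_bow; classifier yhat = softmax(z Wc + bc);
#     class decoder p(x_bow|yhat) = softmax(yhat Rct + bct) . x_bow.
# M2: m = LRelu([h, yhat] Wm + bm); mu_s = m W3 + b3, logvar_s = m W4 + b4;
#     t = LRelu([yhat, z_s] Wt + bt); p(x_bow|yhat, z_s) = softmax(t Rs + bs) . x_bow;
#     p(yhat|z_s) = softmax(z_s Wy2 + by2) . yhat.
# All reconstruction likelihoods are multinomial bag-of-words log-likelihoods.

.lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
.dlrelu <- function(x, slope) ifelse(x > 0, 1, slope)

.softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

.logsoftmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  L - log(rowSums(exp(L)))
}

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

#' Model configuration
#'
#' @param vocab_size Bag-of-words vocabulary size `|V|` (experiments default
#'   to 2000).
#' @param n_classes Number of target categories `|y|` (default 10).
#' @param d_h Encoder output dimension (reference bag-of-words encoder
#'   default 64).
#' @param d_z,d_zs Latent dimensions of the M1 and M2 Gaussians (default 50,
#'   matching the experimental hidden size).
#' @param d_m Dimension of the M2 merged feature `m` (default `d_h`).
#' @param leaky_slope Negative-side slope of the leaky rectifier.
#' @param logvar_clamp Log-variance is clamped to `[-c, c]` for numerical
#'   safety (the positivity-safe reading of a linear sigma map).
#' @param lambda Classifier loss weight; default `vocab_size / n_classes`.
#' @param encoder `"bow_mlp"` (self-contained reference encoder over
#'   L1-normalised counts) or a list `list(kind = "external_adapter",
#'   fn = function(text) numeric(d_h))` wrapping any pretrained text encoder.
#' @return A `cantm_config` list.
#' @export
cantm_config <- function(vocab_size, n_classes, d_h = 64L, d_z = 50L,
                         d_zs = 50L, d_m = d_h, leaky_slope = 0.01,
                         logvar_clamp = 10, lambda = NULL,
                         encoder = "bow_mlp") {
  stopifnot(vocab_size >= 1L, n_classes >= 2L, d_h >= 1L, d_z >= 1L,
            d_zs >= 1L)
  if (is.null(lambda)) lambda <- vocab_size / n_classes
  if (is.character(encoder)) encoder <- list(kind = match.arg(encoder, "bow_mlp"))
  structure(list(vocab_size = as.integer(vocab_size),
                 n_classes = as.integer(n_classes),
                 d_h = as.integer(d_h), d_z = as.integer(d_z),
                 d_zs = as.integer(d_zs), d_m = as.integer(d_m),
                 leaky_slope = leaky_slope, logvar_clamp = logvar_clamp,
                 lambda = lambda, encoder = encoder),
            class = "cantm_config")
}

.xavier <- function(nr, nc, rng) {
  lim <- sqrt(6 / (nr + nc))
  matrix(rng$runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise a model
#'
#' @param config A [cantm_config()].
#' @param vocab A [build_vocabulary()] result (length must equal
#'   `config$vocab_size`).
#' @param labels Character vector of class names (length `n_classes`).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `cantm_model`: list with `config`, `vocab`,
#'   `labels` and `w` (named list of weight matrices/vectors).
#' @export
init_cantm <- function(config, vocab, labels, seed = 1L) {
  stopifnot(inherits(config, "cantm_config"),
            length(vocab$tokens) == config$vocab_size,
            length(labels) == config$n_classes)
  rng <- .local_rng(seed)
  V <- config$vocab_size; K <- config$n_classes
  dh <- config$d_h; dz <- config$d_z; dzs <- config$d_zs; dm <- config$d_m
  w <- list(
    We = .xavier(V, dh, rng),        be = numeric(dh),
    W1 = .xavier(dh, dz, rng),       b1 = numeric(dz),
    W2 = .xavier(dh, dz, rng),       b2 = numeric(dz),
    Wc = .xavier(dz, K, rng),        bc = numeric(K),
    R  = .xavier(dz, V, rng),        bR = numeric(V),
    Rct = .xavier(K, V, rng),        bct = numeric(V),
    Wm = .xavier(dh + K, dm, rng),   bm = numeric(dm),
    W3 = .xavier(dm, dzs, rng),      b3 = numeric(dzs),
    W4 = .xavier(dm, dzs, rng),      b4 = numeric(dzs),
    Wy2 = .xavier(dzs, K, rng),      by2 = numeric(K),
    Wt = .xavier(K + dzs, dzs, rng), bt = numeric(dzs),
    Rs = .xavier(dzs, V, rng),       bs = numeric(V)
  )
  structure(list(config = config, vocab = vocab, labels = labels, w = w),
            class = "cantm_model")
}

#' @export
print.cantm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cantm_model> |V| = %d, classes = %d (%s, ...)\n",
                     "  d_h = %d, d_z = %d, d_zs = %d, lambda = %.1f\n"),
              cfg$vocab_size, cfg$n_classes,
              paste(utils::head(x$labels, 3), collapse = ", "),
              cfg$d_h, cfg$d_z, cfg$d_zs, cfg$lambda))
  invisible(x)
}

# names of parameters frozen during unlabelled adaptation (M1 stack)
.m1_param_names <- function() c("We", "be", "W1", "b1", "W2", "b2",
                                "Wc", "bc", "R", "bR")

#' Encode documents to the shared representation h
#'
#' The reference encoder (`bow_mlp`) is a one-hidden-layer leaky-rectifier
#' map over the L1-normalised bag-of-words counts; an `external_adapter`
#' encoder instead applies a user-supplied text-to-vector function.
#'
#' @param model A `cantm_model`.
#' @param x_bow Count vector (or matrix, rows = documents).
#' @param text Raw text, only used by an external-adapter encoder.
#' @return Numeric matrix of encodings, rows = documents.
#' @export
encode <- function(model, x_bow = NULL, text = NULL) {
  enc <- model$config$encoder
  if (enc$kind == "external_adapter") {
    if (is.null(text)) stop("external_adapter encoder needs `text`")
    H <- matrix(unlist(lapply(text, enc$fn)), nrow = length(text),
                ncol = model$config$d_h, byrow = TRUE)
    return(H)
  }
  if (is.null(x_bow)) stop("bow_mlp encoder needs `x_bow`")
  X <- .as_row(x_bow)
  Nd <- rowSums(X)
  if (any(Nd == 0)) stop("empty document after vectorisation")
  xn <- X / Nd
  A <- sweep(xn %*% model$w$We, 2L, model$w$be, "+")
  .lrelu(A, model$config$leaky_slope)
}

#' M1 variational posterior parameters
#'
#' `mu = h W1 + b1`, `logvar = clamp(h W2 + b2)`; sigma is recovered as
#' `exp(logvar / 2)`.
#'
#' @param model A `cantm_model`.
#' @param h Encoding vector or matrix (rows = documents).
#' @return List of class `cantm_gauss`: `mu`, `logvar` (matrices).
#' @export
m1_infer <- function(model, h) {
  H <- .as_row(h)
  if (any(!is.finite(H))) stop("non-finite encoder output")
  cl <- model$config$logvar_clamp
  mu <- sweep(H %*% model$w$W1, 2L, model$w$b1, "+")
  lv <- pmin(pmax(sweep(H %*% model$w$W2, 2L, model$w$b2, "+"), -cl), cl)
  structure(list(mu = mu, logvar = lv), class = "cantm_gauss")
}

#' Draw latent samples by reparameterisation
#'
#' `z = mu + sigma * eps`, `eps ~ N(0, I)`, so gradients flow through the
#' sampling node. Each draw is reproducible from its stored `eps`.
#'
#' @param params A `cantm_gauss` (single row used when a matrix).
#' @param n_samples Number of draws.
#' @param seed Optional integer seed.
#' @param eps Optional `n_samples x d` matrix of forced noise draws.
#' @return List with `z` (`n_samples x d`) and `eps`.
#' @export
reparameterize <- function(params, n_samples = 1L, seed = NULL, eps = NULL) {
  stopifnot(n_samples >= 1L)
  mu <- .as_row(params$mu)[1L, ]
  lv <- .as_row(params$logvar)[1L, ]
  sg <- exp(lv / 2)
  d <- length(mu)
  if (is.null(eps)) {
    eps <- if (is.null(seed)) {
      matrix(stats::rnorm(n_samples * d), n_samples, d)
    } else {
      rng <- .local_rng(seed)
      matrix(rng$rnorm(n_samples * d), n_samples, d)
    }
  }
  eps <- .as_row(eps)
  z <- sweep(sweep(eps, 2L, sg, "*"), 2L, mu, "+")
  list(z = z, eps = eps)
}

# multinomial bag-of-words log-likelihood given row logits
.bow_loglik <- function(logits, X) {
  if (any(rowSums(X) == 0)) stop("zero bag-of-words vector")
  rowSums(X * .logsoftmax_rows(logits))
}

#' M1 reconstruction log-likelihood log p(x_bow | z)
#'
#' @param model A `cantm_model`.
#' @param z Latent vector or matrix (rows = samples).
#' @param x_bow Count vector (recycled across rows of `z`) or matrix.
#' @return Numeric vector of per-row log-likelihoods (all `<= 0`).
#' @export
m1_reconstruct_logprob <- function(model, z, x_bow) {
  Z <- .as_row(z)
  X <- .as_row(x_bow)
  if (nrow(X) == 1L && nrow(Z) > 1L) X <- X[rep(1L, nrow(Z)), , drop = FALSE]
  .bow_loglik(sweep(Z %*% model$w$R, 2L, model$w$bR, "+"), X)
}

#' Classify from a latent vector
#'
#' `yhat = softmax(z Wc + bc)`.
#'
#' @param model A `cantm_model`.
#' @param z Latent vector or matrix (rows = samples).
#' @return Probability matrix, rows summing to 1, columns named by label.
#' @export
classify <- function(model, z) {
  P <- .softmax_rows(sweep(.as_row(z) %*% model$w$Wc, 2L, model$w$bc, "+"))
  colnames(P) <- model$labels
  P
}

#' Class-decoder log-likelihood log p(x_bow | yhat)
#'
#' A one-hot `yhat` selects a single row of the class-topic matrix `Rct`.
#'
#' @param model A `cantm_model`.
#' @param yhat Probability vector or matrix over classes.
#' @param x_bow Count vector or matrix.
#' @return Numeric vector of per-row log-likelihoods.
#' @export
class_decoder_logprob <- function(model, yhat, x_bow) {
  Y <- .as_row(yhat)
  X <- .as_row(x_bow)
  if (nrow(X) == 1L && nrow(Y) > 1L) X <- X[rep(1L, nrow(Y)), , drop = FALSE]
  .bow_loglik(sweep(Y %*% model$w$Rct, 2L, model$w$bct, "+"), X)
}

#' M2 variational posterior given document and predicted label
#'
#' `m = LRelu([h, yhat] Wm + bm)`; `mu_s = m W3 + b3`,
#' `logvar_s = clamp(m W4 + b4)`.
#'
#' @param model A `cantm_model`.
#' @param h Encoding vector/matrix.
#' @param yhat Class-probability vector/matrix (same number of rows).
#' @return List with `m` and `params` (a `cantm_gauss`).
#' @export
m2_infer <- function(model, h, yhat) {
  H <- .as_row(h); Y <- .as_row(yhat)
  if (nrow(H) == 1L && nrow(Y) > 1L) H <- H[rep(1L, nrow(Y)), , drop = FALSE]
  if (ncol(H) != model$config$d_h || ncol(Y) != model$config$n_classes) {
    stop("dimension mismatch in M2 encoder input")
  }
  cl <- model$config$logvar_clamp
  A <- sweep(cbind(H, Y) %*% model$w$Wm, 2L, model$w$bm, "+")
  m <- .lrelu(A, model$config$leaky_slope)
  mu <- sweep(m %*% model$w$W3, 2L, model$w$b3, "+")
  lv <- pmin(pmax(sweep(m %*% model$w$W4, 2L, model$w$b4, "+"), -cl), cl)
  list(m = m, params = structure(list(mu = mu, logvar = lv),
                                 class = "cantm_gauss"))
}

#' M2 reconstruction log-likelihood log p(x_bow | yhat, z_s)
#'
#' `t = LRelu([yhat, z_s] Wt + bt)` is the classification-aware topic vector;
#' the bag-of-words is reconstructed through `softmax(t Rs + bs)`.
#'
#' @param model A `cantm_model`.
#' @param yhat Class probabilities (vector or matrix).
#' @param z_s M2 latent samples (vector or matrix).
#' @param x_bow Count vector or matrix.
#' @return List with `logprob` (per-row) and `t` (topic-vector matrix).
#' @export
m2_reconstruct_logprob <- function(model, yhat, z_s, x_bow) {
  Y <- .as_row(yhat); Zs <- .as_row(z_s)
  if (nrow(Y) == 1L && nrow(Zs) > 1L) Y <- Y[rep(1L, nrow(Zs)), , drop = FALSE]
  X <- .as_row(x_bow)
  if (nrow(X) == 1L && nrow(Zs) > 1L) X <- X[rep(1L, nrow(Zs)), , drop = FALSE]
  A <- sweep(cbind(Y, Zs) %*% model$w$Wt, 2L, model$w$bt, "+")
  tt <- .lrelu(A, model$config$leaky_slope)
  lp <- .bow_loglik(sweep(tt %*% model$w$Rs, 2L, model$w$bs, "+"), X)
  list(logprob = lp, t = tt)
}

#' M2 label log-likelihood log p(yhat | z_s)
#'
#' Soft-label cross-entropy form: `sum_c yhat[c] * log softmax(z_s Wy2 + by2)[c]`.
#' Used only inside the training objective, never for prediction.
#'
#' @param model A `cantm_model`.
#' @param z_s M2 latent samples.
#' @param yhat Class probabilities.
#' @return Numeric vector of per-row log-likelihoods.
#' @export
m2_label_logprob <- function(model, z_s, yhat) {
  Zs <- .as_row(z_s); Y <- .as_row(yhat)
  if (nrow(Y) == 1L && nrow(Zs) > 1L) Y <- Y[rep(1L, nrow(Zs)), , drop = FALSE]
  rowSums(Y * .logsoftmax_rows(sweep(Zs %*% model$w$Wy2, 2L, model$w$by2, "+")))
}

# ---------------------------------------------------------------------------
# Vectorised batch forward/backward. Rows of the cache are document-sample
# pairs: a batch of n documents with S samples becomes N = n * S rows (eps
# drawn fresh per row), so one pass handles all samples.

.forward_batch <- function(model, X, S = 1L, sample = TRUE,
                           eps = NULL, eps_s = NULL, H = NULL) {
  w <- model$w; cfg <- model$config
  n <- nrow(X)
  rows <- rep(seq_len(n), times = S)
  Xr <- X[rows, , drop = FALSE]
  Nd <- rowSums(Xr)
  if (any(Nd == 0)) stop("empty document after vectorisation")
  N <- nrow(Xr)
  if (is.null(H)) {
    xn <- Xr / Nd
    Ae <- sweep(xn %*% w$We, 2L, w$be, "+")
    h <- .lrelu(Ae, cfg$leaky_slope)
  } else {
    xn <- NULL; Ae <- NULL
    h <- H[rows, , drop = FALSE]
  }
  cl <- cfg$logvar_clamp
  mu <- sweep(h %*% w$W1, 2L, w$b1, "+")
  lv_raw <- sweep(h %*% w$W2, 2L, w$b2, "+")
  lv <- pmin(pmax(lv_raw, -cl), cl)
  sg <- exp(lv / 2)
  if (sample) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(N * cfg$d_z), N, cfg$d_z)
    z <- mu + sg * eps
  } else {
    eps <- NULL
    z <- mu
  }
  logits_c <- sweep(z %*% w$Wc, 2L, w$bc, "+")
  yhat <- .softmax_rows(logits_c)
  lsm_r <- .logsoftmax_rows(sweep(z %*% w$R, 2L, w$bR, "+"))
  recon_m1 <- rowSums(Xr * lsm_r)
  lsm_ct <- .logsoftmax_rows(sweep(yhat %*% w$Rct, 2L, w$bct, "+"))
  recon_ct <- rowSums(Xr * lsm_ct)
  c1 <- cbind(h, yhat)
  Am <- sweep(c1 %*% w$Wm, 2L, w$bm, "+")
  m <- .lrelu(Am, cfg$leaky_slope)
  mu_s <- sweep(m %*% w$W3, 2L, w$b3, "+")
  lvs_raw <- sweep(m %*% w$W4, 2L, w$b4, "+")
  lvs <- pmin(pmax(lvs_raw, -cl), cl)
  sgs <- exp(lvs / 2)
  if (sample) {
    if (is.null(eps_s)) eps_s <- matrix(stats::rnorm(N * cfg$d_zs), N, cfg$d_zs)
    zs <- mu_s + sgs * eps_s
  } else {
    eps_s <- NULL
    zs <- mu_s
  }
  lsm_y2 <- .logsoftmax_rows(sweep(zs %*% w$Wy2, 2L, w$by2, "+"))
  label_m2 <- rowSums(yhat * lsm_y2)
  c2 <- cbind(yhat, zs)
  At <- sweep(c2 %*% w$Wt, 2L, w$bt, "+")
  tt <- .lrelu(At, cfg$leaky_slope)
  lsm_s <- .logsoftmax_rows(sweep(tt %*% w$Rs, 2L, w$bs, "+"))
  recon_m2 <- rowSums(Xr * lsm_s)
  kl_m1 <- 0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
  kl_m2 <- 0.5 * rowSums(mu_s^2 + exp(lvs) - lvs - 1)
  list(rows = rows, n_docs = n, S = S, Xr = Xr, Nd = Nd, xn = xn, Ae = Ae,
       h = h, mu = mu, lv_raw = lv_raw, lv = lv, sg = sg, eps = eps, z = z,
       logits_c = logits_c, yhat = yhat, lsm_r = lsm_r, lsm_ct = lsm_ct,
       c1 = c1, Am = Am, m = m, mu_s = mu_s, lvs_raw = lvs_raw, lvs = lvs,
       sgs = sgs, eps_s = eps_s, zs = zs, lsm_y2 = lsm_y2, c2 = c2, At = At,
       tt = tt, lsm_s = lsm_s,
       recon_m1 = recon_m1, recon_ct = recon_ct, recon_m2 = recon_m2,
       label_m2 = label_m2, kl_m1 = kl_m1, kl_m2 = kl_m2,
       external_h = !is.null(H))
}

# per-row loss components; gold_idx is a per-document integer class (1-based)
# or NULL (unsupervised). Flags zero the M2 / class-decoder terms.
.loss_rows <- function(fo, gold_idx, lambda, include_m2 = TRUE,
                       include_class_decoder = TRUE) {
  f2 <- as.numeric(include_m2); fct <- as.numeric(include_class_decoder)
  if (!is.null(gold_idx)) {
    gi <- gold_idx[fo$rows]
    l_cls <- -log(pmax(fo$yhat[cbind(seq_along(gi), gi)], 1e-12))
  } else {
    l_cls <- numeric(length(fo$rows))
    lambda <- 0
  }
  total <- lambda * l_cls - fo$recon_m1 + fo$kl_m1 -
    f2 * (fo$recon_m2 + fo$label_m2 - fo$kl_m2) - fct * fo$recon_ct
  list(l_cls = l_cls, recon_m1 = fo$recon_m1, kl_m1 = fo$kl_m1,
       recon_m2 = f2 * fo$recon_m2, label_m2 = f2 * fo$label_m2,
       kl_m2 = f2 * fo$kl_m2, recon_ct = fct * fo$recon_ct, total = total)
}

# Analytic gradients of mean(total) over the N cache rows, w.r.t. every
# weight. Verified against central finite differences in the test suite.
.backward_batch <- function(model, fo, gold_idx, lambda,
                            include_m2 = TRUE, include_class_decoder = TRUE) {
  w <- model$w; cfg <- model$config
  sl <- cfg$leaky_slope
  N <- length(fo$rows)
  K <- cfg$n_classes; dh <- cfg$d_h; nzs <- cfg$d_zs
  f2 <- as.numeric(include_m2); fct <- as.numeric(include_class_decoder)
  cl <- cfg$logvar_clamp
  mask1 <- (fo$lv_raw > -cl & fo$lv_raw < cl) * 1
  mask2 <- (fo$lvs_raw > -cl & fo$lvs_raw < cl) * 1

  sm_r <- exp(fo$lsm_r); sm_ct <- exp(fo$lsm_ct)
  sm_s <- exp(fo$lsm_s); sm_y2 <- exp(fo$lsm_y2)

  dlogits_r <- (sm_r * fo$Nd - fo$Xr) / N
  dlogits_ct <- fct * (sm_ct * fo$Nd - fo$Xr) / N
  dlogits_s <- f2 * (sm_s * fo$Nd - fo$Xr) / N
  dlogits_y2 <- f2 * (sm_y2 - fo$yhat) / N
  dyhat_lab <- f2 * (-fo$lsm_y2) / N

  g <- list()
  # M2 reconstruction path
  g$Rs <- crossprod(fo$tt, dlogits_s); g$bs <- colSums(dlogits_s)
  dtt <- tcrossprod(dlogits_s, w$Rs)
  dAt <- dtt * .dlrelu(fo$At, sl)
  g$Wt <- crossprod(fo$c2, dAt); g$bt <- colSums(dAt)
  dc2 <- tcrossprod(dAt, w$Wt)
  dyhat_t <- dc2[, seq_len(K), drop = FALSE]
  dZs <- dc2[, K + seq_len(nzs), drop = FALSE]
  # M2 label path
  g$Wy2 <- crossprod(fo$zs, dlogits_y2); g$by2 <- colSums(dlogits_y2)
  dZs <- dZs + tcrossprod(dlogits_y2, w$Wy2)
  # M2 KL + reparameterisation
  dmu_s <- dZs + f2 * fo$mu_s / N
  dlvs <- 0.5 * f2 * (exp(fo$lvs) - 1) / N
  if (!is.null(fo$eps_s)) dlvs <- dlvs + 0.5 * dZs * fo$eps_s * fo$sgs
  dlvs <- dlvs * mask2
  g$W3 <- crossprod(fo$m, dmu_s); g$b3 <- colSums(dmu_s)
  g$W4 <- crossprod(fo$m, dlvs); g$b4 <- colSums(dlvs)
  dm <- tcrossprod(dmu_s, w$W3) + tcrossprod(dlvs, w$W4)
  dAm <- dm * .dlrelu(fo$Am, sl)
  g$Wm <- crossprod(fo$c1, dAm); g$bm <- colSums(dAm)
  dc1 <- tcrossprod(dAm, w$Wm)
  dh_m <- dc1[, seq_len(dh), drop = FALSE]
  dyhat_m <- dc1[, dh + seq_len(K), drop = FALSE]
  # class decoder
  g$Rct <- crossprod(fo$yhat, dlogits_ct); g$bct <- colSums(dlogits_ct)
  dyhat <- dyhat_lab + tcrossprod(dlogits_ct, w$Rct) + dyhat_t + dyhat_m
  # through the classifier softmax
  dlogits_c <- fo$yhat * (dyhat - rowSums(dyhat * fo$yhat))
  if (!is.null(gold_idx)) {
    gi <- gold_idx[fo$rows]
    G <- fo$yhat
    G[cbind(seq_len(N), gi)] <- G[cbind(seq_len(N), gi)] - 1
    dlogits_c <- dlogits_c + lambda * G / N
  }
  g$Wc <- crossprod(fo$z, dlogits_c); g$bc <- colSums(dlogits_c)
  # M1 decoder
  g$R <- crossprod(fo$z, dlogits_r); g$bR <- colSums(dlogits_r)
  dz <- tcrossprod(dlogits_r, w$R) + tcrossprod(dlogits_c, w$Wc)
  # M1 KL + reparameterisation
  dmu <- dz + fo$mu / N
  dlv <- 0.5 * (exp(fo$lv) - 1) / N
  if (!is.null(fo$eps)) dlv <- dlv + 0.5 * dz * fo$eps * fo$sg
  dlv <- dlv * mask1
  g$W1 <- crossprod(fo$h, dmu); g$b1 <- colSums(dmu)
  g$W2 <- crossprod(fo$h, dlv); g$b2 <- colSums(dlv)
  if (!fo$external_h) {
    dh <- dh_m + tcrossprod(dmu, w$W1) + tcrossprod(dlv, w$W2)
    dAe <- dh * .dlrelu(fo$Ae, sl)
    g$We <- crossprod(fo$xn, dAe); g$be <- colSums(dAe)
  } else {
    g$We <- model$w$We * 0; g$be <- model$w$be * 0
  }
  g
}

#' Full forward pass for one document
#'
#' In train mode, `n_samples` latent draws are taken and the class posterior
#' is computed per sample from `z`; in test mode the classification path is
#' deterministic (`yhat = classify(mu)`, a single `z_s = mu_s` path), matching
#' the use of the posterior mean at test time.
#'
#' @param model A `cantm_model`.
#' @param x_bow Count vector of the document.
#' @param n_samples Latent draws in train mode (experimental defaults: 10
#'   training, 1 testing).
#' @param mode `"train"` or `"test"`.
#' @param seed Optional seed for the noise draws.
#' @return Object of class `cantm_forward`: list with `h`, `m1_params`,
#'   per-sample matrices `z`, `eps`, `yhat` (rows = samples), aggregate
#'   `yhat_mean`, M2 fields (`m`, `m2_params`, `zs`, `t`), and per-sample
#'   log-likelihood vectors `recon_m1`, `recon_ct`, `recon_m2`, `label_m2`
#'   plus scalars `kl_m1`, `kl_m2` (sample-averaged where stochastic).
#' @export
cantm_forward <- function(model, x_bow, n_samples = 10L,
                          mode = c("train", "test"), seed = NULL) {
  mode <- match.arg(mode)
  X <- .as_row(x_bow)
  stopifnot(nrow(X) == 1L)
  if (sum(X) == 0) stop("empty document after vectorisation")
  if (!is.null(seed)) {
    rng <- .local_rng(seed)
    draw <- function(n, d) matrix(rng$rnorm(n * d), n, d)
  } else {
    draw <- function(n, d) matrix(stats::rnorm(n * d), n, d)
  }
  sample <- mode == "train"
  S <- if (sample) as.integer(n_samples) else 1L
  eps <- if (sample) draw(S, model$config$d_z) else NULL
  eps_s <- if (sample) draw(S, model$config$d_zs) else NULL
  fo <- .forward_batch(model, X, S = S, sample = sample,
                       eps = eps, eps_s = eps_s)
  structure(list(
    mode = mode, n_samples = S, x_bow = drop(X),
    h = fo$h[1L, ],
    m1_params = structure(list(mu = fo$mu[1L, , drop = FALSE],
                               logvar = fo$lv[1L, , drop = FALSE]),
                          class = "cantm_gauss"),
    z = fo$z, eps = fo$eps,
    yhat = structure(fo$yhat, dimnames = list(NULL, model$labels)),
    yhat_mean = stats::setNames(colMeans(fo$yhat), model$labels),
    m = fo$m,
    m2_params = structure(list(mu = fo$mu_s, logvar = fo$lvs),
                          class = "cantm_gauss"),
    zs = fo$zs, eps_s = fo$eps_s, t = fo$tt,
    recon_m1 = fo$recon_m1, recon_ct = fo$recon_ct,
    recon_m2 = fo$recon_m2, label_m2 = fo$label_m2,
    kl_m1 = mean(fo$kl_m1), kl_m2 = mean(fo$kl_m2)
  ), class = "cantm_forward")
}

#' @export
print.cantm_forward <- function(x, ...) {
  cat(sprintf("<cantm_forward> mode = %s, samples = %d, argmax = %s (p = %.3f)\n",
              x$mode, x$n_samples, names(which.max(x$yhat_mean)),
              max(x$yhat_mean)))
  invisible(x)
}
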
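# Evaluation: variational perplexity, classification metrics, k-fold
# cross-validation harness.

#' Classify a corpus with a trained model
#'
#' Test-time classification is deterministic: the posterior mean of
#' `q(z|x)` is used, with no sampling. Documents that vectorise to the zero
#' vector are flagged (`NA` label, `NA` probabilities).
#'
#' @param model A trained `cantm_model`.
#' @param corpus Tokenised corpus data.frame (or supply `X`).
#' @param X Optional precomputed count matrix over the model vocabulary.
#' @return data.frame with `id`, `label` (argmax), `flagged`, and one
#'   probability column per class (`p_<label>`).
#' @export
predict_corpus <- function(model, corpus = NULL, X = NULL) {
  if (is.null(X)) {
    stopifnot(is.data.frame(corpus), !is.null(corpus$tokens))
    X <- corpus_bow_matrix(corpus, model$vocab)
  }
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
  ok <- rowSums(X) > 0
  P <- matrix(NA_real_, nrow(X), model$config$n_classes,
              dimnames = list(NULL, model$labels))
  if (any(ok)) {
    fo <- .forward_batch(model, X[ok, , drop = FALSE], S = 1L, sample = FALSE)
    P[ok, ] <- fo$yhat
  }
  out <- data.frame(id = ids,
                    label = ifelse(ok, model$labels[max.col(replace(P, is.na(P), -Inf))],
                                   NA_character_),
                    flagged = !ok, stringsAsFactors = FALSE)
  colnames(P) <- paste0("p_", model$labels)
  cbind(out, as.data.frame(P))
}

#' Variational perplexity of a corpus under the document model
#'
#' Uses the per-document variational lower bound on `log p(x_bow)`
#' (sample-averaged M1 reconstruction minus the closed-form KL), normalised
#' by the in-vocabulary token count inside the corpus average:
#' `exp(-(1/D) * sum_d Lhat_d / N_d)` (`average = "per_document"`), or the
#' token-weighted alternative `exp(-sum_d Lhat_d / sum_d N_d)`
#' (`average = "per_token"`). A uniform decoder with zero KL gives `|V|`.
#' Documents with no in-vocabulary tokens are excluded and counted.
#'
#' @param model A trained `cantm_model`.
#' @param corpus Tokenised corpus (or supply `X`).
#' @param X Optional count matrix.
#' @param n_samples Latent draws for the bound (default 10).
#' @param seed Seed for the draws.
#' @param average `"per_document"` (default) or `"per_token"`.
#' @return Perplexity (scalar), with attribute `n_excluded`.
#' @export
perplexity <- function(model, corpus = NULL, X = NULL, n_samples = 10L,
                       seed = 1L, average = c("per_document", "per_token")) {
  average <- match.arg(average)
  if (is.null(X)) {
    stopifnot(is.data.frame(corpus), !is.null(corpus$tokens))
    X <- corpus_bow_matrix(corpus, model$vocab)
  }
  ok <- rowSums(X) > 0
  n_excluded <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  if (nrow(X) == 0L) stop("no document has in-vocabulary tokens")
  rng <- .local_rng(seed)
  N <- nrow(X) * n_samples
  eps <- matrix(rng$rnorm(N * model$config$d_z), N, model$config$d_z)
  eps_s <- matrix(rng$rnorm(N * model$config$d_zs), N, model$config$d_zs)
  fo <- .forward_batch(model, X, S = n_samples, sample = TRUE,
                       eps = eps, eps_s = eps_s)
  # per-document sample-averaged bound: E[log p(x|z)] - KL
  recon <- rowsum(fo$recon_m1, fo$rows) / n_samples
  kl <- rowsum(fo$kl_m1, fo$rows) / n_samples
  lhat <- drop(recon - kl)
  Nd <- rowSums(X)
  pp <- if (average == "per_document") exp(-mean(lhat / Nd)) else
    exp(-sum(lhat) / sum(Nd))
  attr(pp, "n_excluded") <- n_excluded
  pp
}

#' Classification metrics from prediction and gold label lists
#'
#' Macro-F1 is the unweighted mean of per-class F1; a class with neither
#' predictions nor gold instances contributes F1 = 0 and is flagged in
#' `empty_classes`. Accuracy equals the trace of the confusion matrix over
#' its total.
#'
#' @param preds Character vector of predicted labels.
#' @param gold Character vector of gold labels (same length).
#' @param label_set Character vector of all class names.
#' @return List with `accuracy`, `macro_f1`, `per_class_f1` (named),
#'   `confusion` (gold rows x predicted columns) and `empty_classes`.
#' @export
classification_report <- function(preds, gold, label_set) {
  if (length(preds) != length(gold)) stop("preds and gold differ in length")
  if (any(!preds %in% label_set) || any(!gold %in% label_set)) {
    stop("label outside label_set")
  }
  cm <- table(factor(gold, label_set), factor(preds, label_set))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  empty <- label_set[rowSums(cm) == 0 & colSums(cm) == 0]
  list(accuracy = sum(tp) / sum(cm),
       macro_f1 = mean(f1),
       per_class_f1 = stats::setNames(as.numeric(f1), label_set),
       confusion = unclass(cm),
       empty_classes = empty)
}

#' Column-normalised confusion percentages
#'
#' Per gold class (row), the percentage of documents predicted as each class
#' — the stacked-column view of model-vs-gold agreement.
#'
#' @param confusion Count matrix, gold rows x predicted columns.
#' @return Matrix of row percentages.
#' @export
confusion_percent <- function(confusion) {
  rs <- rowSums(confusion)
  out <- 100 * confusion / ifelse(rs > 0, rs, 1)
  round(out, 1)
}

#' k-fold cross-validation of the full pipeline
#'
#' Trains one model per fold on the remaining folds and evaluates accuracy,
#' macro-F1, per-class F1 and variational perplexity on the held-out fold;
#' reports per-fold values, their mean and population standard deviation
#' (divide by k), and the aggregate confusion matrix summed over folds.
#'
#' @param corpus Tokenised labelled corpus.
#' @param k Number of folds (default 5).
#' @param cfg A [train_config()].
#' @param vocab Optional shared vocabulary; by default built per fold from
#'   the training portion only (no test leakage).
#' @param vocab_size Vocabulary cap when building per fold.
#' @return Object of class `cantm_eval`: list with `folds` (per-fold metric
#'   rows), `accuracy`, `macro_f1`, `perplexity` (each mean/sd), `per_class_f1`
#'   (mean and sd per label), `confusion`, `confusion_pct` and `models`.
#' @export
cross_validate <- function(corpus, k = 5L, cfg = train_config(),
                           vocab = NULL, vocab_size = 2000L) {
  stopifnot(is.data.frame(corpus), !is.null(corpus$tokens),
            !any(is.na(corpus$label)))
  split <- make_folds(corpus, k = k, seed = cfg$seed, stratified = TRUE)
  fold_of <- split$assignments[corpus$id]
  label_set <- sort(unique(corpus$label))
  fold_rows <- list(); models <- list()
  confusion <- matrix(0L, length(label_set), length(label_set),
                      dimnames = list(label_set, label_set))
  pcf <- matrix(NA_real_, k, length(label_set),
                dimnames = list(NULL, label_set))
  for (f in seq_len(k)) {
    tr <- corpus[fold_of != f, , drop = FALSE]
    te <- corpus[fold_of == f, , drop = FALSE]
    if (!all(label_set %in% tr$label) || !all(label_set %in% te$label)) {
      warning(sprintf("fold %d is missing a class entirely", f))
    }
    voc <- if (is.null(vocab)) build_vocabulary(tr, max_size = vocab_size) else vocab
    fit <- train_supervised(tr, vocab = voc, cfg = cfg)
    Xte <- corpus_bow_matrix(te, voc)
    ok <- rowSums(Xte) > 0
    pred <- predict_corpus(fit, X = Xte[ok, , drop = FALSE])
    rep_f <- classification_report(pred$label, te$label[ok], label_set)
    pp <- perplexity(fit, X = Xte[ok, , drop = FALSE],
                     n_samples = cfg$n_samples_test, seed = cfg$seed + f)
    fold_rows[[f]] <- data.frame(fold = f, accuracy = rep_f$accuracy,
                                 macro_f1 = rep_f$macro_f1,
                                 perplexity = as.numeric(pp),
                                 n_test = sum(ok))
    pcf[f, ] <- rep_f$per_class_f1
    confusion <- confusion + rep_f$confusion
    models[[f]] <- fit
  }
  folds <- do.call(rbind, fold_rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summ <- function(x) c(mean = mean(x), sd = pop_sd(x))
  structure(list(
    folds = folds,
    accuracy = summ(folds$accuracy),
    macro_f1 = summ(folds$macro_f1),
    perplexity = summ(folds$perplexity),
    per_class_f1 = list(mean = colMeans(pcf), sd = apply(pcf, 2L, pop_sd)),
    confusion = confusion,
    confusion_pct = confusion_percent(confusion),
    split = split, models = models
  ), class = "cantm_eval")
}

#' @export
print.cantm_eval <- function(x, ...) {
  cat(sprintf(paste0("<cantm_eval> %d-fold cross-validation\n",
                     "  accuracy   %.4f (%.4f)\n  macro-F1   %.4f (%.4f)\n",
                     "  perplexity %.1f (%.1f)\n"),
              nrow(x$folds), x$accuracy["mean"], x$accuracy["sd"],
              x$macro_f1["mean"], x$macro_f1["sd"],
              x$perplexity["mean"], x$perplexity["sd"]))
  invisible(x)
}
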
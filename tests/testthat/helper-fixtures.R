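# Shared fixtures: tiny corpora, vocabularies and models built in code.

make_vocab <- function(tokens) {
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "cantm_vocab")
}

# tiny model with every weight set to zero (useful for closed-form cases)
zero_model <- function(V = 4L, K = 2L, d_h = 3L, d_z = 2L, d_zs = 2L) {
  cfg <- cantm_config(vocab_size = V, n_classes = K, d_h = d_h,
                      d_z = d_z, d_zs = d_zs, d_m = d_h)
  m <- init_cantm(cfg, make_vocab(sprintf("w%02d", seq_len(V))),
                  sprintf("c%02d", seq_len(K)), seed = 1L)
  m$w <- lapply(m$w, function(w) w * 0)
  m
}

# small randomly initialised model, weights jittered off any kink
random_model <- function(V = 6L, K = 2L, d_h = 3L, d_z = 2L, d_zs = 2L,
                         seed = 7L, jitter = 0.1) {
  cfg <- cantm_config(vocab_size = V, n_classes = K, d_h = d_h,
                      d_z = d_z, d_zs = d_zs, d_m = d_h)
  m <- init_cantm(cfg, make_vocab(sprintf("w%02d", seq_len(V))),
                  sprintf("c%02d", seq_len(K)), seed = seed)
  set.seed(seed + 1L)
  m$w <- lapply(m$w, function(w) w + jitter * stats::rnorm(length(w)))
  m
}

# corpus data.frame directly from a list of token vectors
corpus_from_tokens <- function(tokens, labels = NA_character_) {
  df <- data.frame(id = sprintf("d%03d", seq_along(tokens)),
                   text = vapply(tokens, paste, character(1), collapse = " "),
                   label = rep_len(labels, length(tokens)),
                   stringsAsFactors = FALSE)
  df$tokens <- tokens
  df
}

# annotation table from a compact spec: list of doc -> list(annotator =
# c(category, confidence))
annotations_from <- function(spec) {
  rows <- list()
  for (doc in names(spec)) {
    for (ann in names(spec[[doc]])) {
      v <- spec[[doc]][[ann]]
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc, annotator_id = ann, category = v[[1]],
        confidence = as.integer(v[[2]]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# independent brute-force oracles -------------------------------------------

# Cohen's kappa recomputed through the full contingency table
kappa_bruteforce <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  M <- table(factor(a, cats), factor(b, cats))
  n <- sum(M)
  po <- sum(diag(M)) / n
  pe <- sum(rowSums(M) * colSums(M)) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

# pairwise agreement by explicit double loop over each document's records
agreement_bruteforce <- function(records) {
  match_n <- 0L; tot <- 0L
  for (doc in unique(records$doc_id)) {
    cats <- records$category[records$doc_id == doc]
    n <- length(cats)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      tot <- tot + 1L
      if (cats[i] == cats[j]) match_n <- match_n + 1L
    }
  }
  if (tot == 0L) stop("no pairs")
  match_n / tot
}

# random small annotation table for property tests
random_annotation_table <- function(n_docs = 8L, n_annotators = 4L,
                                    n_cats = 3L) {
  rows <- list()
  for (d in seq_len(n_docs)) {
    k <- sample(1:3, 1L)
    anns <- sample(n_annotators, min(k, n_annotators))
    rows[[d]] <- data.frame(
      doc_id = paste0("d", d),
      annotator_id = paste0("a", anns),
      category = sample(LETTERS[seq_len(n_cats)], length(anns), replace = TRUE),
      confidence = sample(0:9, length(anns), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Unsupervised variational document model (NVDM-style) negative ELBO,
# independently coded: plain per-document arithmetic with explicit loops,
# sharing only the weight values and noise draws with the model under test.
nvdm_neg_elbo <- function(w, x, eps, slope = 0.01) {
  stopifnot(is.numeric(x), is.matrix(eps))
  xn <- x / sum(x)
  pre <- as.numeric(xn %*% w$We) + w$be
  h <- ifelse(pre > 0, pre, slope * pre)
  mu <- as.numeric(h %*% w$W1) + w$b1
  lv <- as.numeric(h %*% w$W2) + w$b2
  lv <- pmin(pmax(lv, -10), 10)
  sg <- exp(lv / 2)
  kl <- 0.5 * sum(mu^2 + sg^2 - lv - 1)
  recon <- numeric(nrow(eps))
  for (s in seq_len(nrow(eps))) {
    z <- mu + sg * eps[s, ]
    logits <- as.numeric(z %*% w$R) + w$bR
    logp <- logits - (max(logits) + log(sum(exp(logits - max(logits)))))
    recon[s] <- sum(x * logp)
  }
  -(mean(recon) - kl)
}
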
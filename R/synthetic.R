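# Synthetic corpus and annotator simulators with planted ground truth, so
# the curation, model and evaluation machinery are testable fully offline.

#' Specification for a synthetic class-signature corpus
#'
#' Documents are generated by a mixture-of-signatures model: each document
#' draws a class, then each token independently comes from the class's
#' exclusive signature vocabulary with probability `separation`, else from
#' the shared background vocabulary. Defaults mirror the study corpus scale:
#' 10 categories, ~1300 documents, a 2000-token vocabulary, and short texts
#' in the 15-30 token range (claims plus debunking explanations average
#' about 23 words).
#'
#' @param n_docs Number of documents.
#' @param n_classes Number of categories.
#' @param vocab_size Total vocabulary size (signature + background).
#' @param doc_length Length-2 integer range of document lengths (uniform).
#' @param signature_size Signature tokens exclusive to each class.
#' @param separation Probability in `[0, 1]` that a token is drawn from the
#'   class signature rather than the background (0 = no class signal).
#' @param class_probs Optional class marginals (default uniform).
#' @param seed Integer seed.
#' @return A `cantm_synth_spec` list.
#' @export
synthetic_spec <- function(n_docs = 1300L, n_classes = 10L,
                           vocab_size = 2000L, doc_length = c(15L, 30L),
                           signature_size = 20L, separation = 0.7,
                           class_probs = NULL, seed = 1L) {
  if (signature_size * n_classes > vocab_size) {
    stop("signature_size * n_classes exceeds vocab_size")
  }
  if (separation < 0 || separation > 1) stop("separation must lie in [0, 1]")
  stopifnot(length(doc_length) == 2L, doc_length[1] >= 1L,
            doc_length[2] >= doc_length[1])
  if (is.null(class_probs)) class_probs <- rep(1 / n_classes, n_classes)
  stopifnot(length(class_probs) == n_classes)
  structure(list(n_docs = as.integer(n_docs), n_classes = as.integer(n_classes),
                 vocab_size = as.integer(vocab_size),
                 doc_length = as.integer(doc_length),
                 signature_size = as.integer(signature_size),
                 separation = separation,
                 class_probs = class_probs / sum(class_probs),
                 seed = as.integer(seed)),
            class = "cantm_synth_spec")
}

#' Generate a labelled corpus with planted class signatures
#'
#' Bit-reproducible given the spec's seed. Token names are chosen to survive
#' the package's text normalisation unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `corpus` (tokenised corpus data.frame with labels) and
#'   `signatures` (named list class -> exclusive signature tokens).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "cantm_synth_spec"))
  rng <- .local_rng(spec$seed)
  K <- spec$n_classes
  labels <- sprintf("cat%02d", seq_len(K))
  n_sig <- spec$signature_size * K
  sig_tokens <- sprintf("sig%02dw%03d", rep(seq_len(K), each = spec$signature_size),
                        rep(seq_len(spec$signature_size), K))
  bg_tokens <- sprintf("bg%04d", seq_len(spec$vocab_size - n_sig))
  signatures <- split(sig_tokens, rep(labels, each = spec$signature_size))
  signatures <- signatures[labels]
  cls <- labels[rng$rmultinom_draw(spec$n_docs, spec$class_probs)]
  lens <- spec$doc_length[1] +
    floor(rng$runif(spec$n_docs) * (spec$doc_length[2] - spec$doc_length[1] + 1L))
  tokens <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    L <- lens[i]
    from_sig <- rng$runif(L) < spec$separation
    tk <- character(L)
    n_s <- sum(from_sig)
    if (n_s > 0L) {
      sig <- signatures[[cls[i]]]
      tk[from_sig] <- sig[rng$rmultinom_draw(n_s, rep(1, length(sig)))]
    }
    if (n_s < L) {
      tk[!from_sig] <- bg_tokens[rng$rmultinom_draw(L - n_s, rep(1, length(bg_tokens)))]
    }
    tokens[[i]] <- tk
  }
  corpus <- data.frame(id = sprintf("doc%05d", seq_len(spec$n_docs)),
                       text = vapply(tokens, paste, character(1), collapse = " "),
                       label = cls, stringsAsFactors = FALSE)
  corpus$tokens <- tokens
  list(corpus = corpus, signatures = signatures, labels = labels)
}

#' Annotator population model
#'
#' Each annotator has a confusion row per true class (their probability of
#' assigning each category) and a confidence distribution conditional on
#' whether their assignment matched the truth. `coverage` gives the
#' distribution of the number of annotators per document.
#'
#' @param n_annotators Number of annotators (the study recruited 27).
#' @param n_classes Number of categories.
#' @param accuracy Probability an ordinary annotator assigns the true class
#'   (remaining mass uniform over the other classes).
#' @param adversarial Integer indices of annotators whose confusion rows are
#'   uniform (no signal).
#' @param conf_correct,conf_wrong Probability vectors over confidences 0..9
#'   conditional on correctness; defaults concentrate correct annotations at
#'   high confidence and wrong ones at low confidence.
#' @param coverage Probability vector over 1, 2, 3, ... annotators per
#'   document (default mostly single- with some double/triple-annotation, as
#'   in a two-round annotation campaign).
#' @return A `cantm_annotator_model` list.
#' @export
annotator_model <- function(n_annotators = 27L, n_classes = 10L,
                            accuracy = 0.85,
                            adversarial = integer(0),
                            conf_correct = c(rep(0, 6), 0.1, 0.2, 0.3, 0.4),
                            conf_wrong = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1,
                                           rep(0, 4)),
                            coverage = c(0.6, 0.3, 0.1)) {
  stopifnot(length(conf_correct) == 10L, length(conf_wrong) == 10L,
            all(adversarial >= 1L & adversarial <= n_annotators))
  confusion <- lapply(seq_len(n_annotators), function(a) {
    if (a %in% adversarial) {
      matrix(1 / n_classes, n_classes, n_classes)
    } else {
      M <- matrix((1 - accuracy) / (n_classes - 1), n_classes, n_classes)
      diag(M) <- accuracy
      M
    }
  })
  structure(list(n_annotators = as.integer(n_annotators),
                 n_classes = as.integer(n_classes),
                 confusion = confusion,
                 conf_correct = conf_correct / sum(conf_correct),
                 conf_wrong = conf_wrong / sum(conf_wrong),
                 coverage = coverage / sum(coverage),
                 adversarial = as.integer(adversarial)),
            class = "cantm_annotator_model")
}

#' Simulate a multi-annotator annotation table for a labelled corpus
#'
#' For each document, the number of annotators is drawn from the coverage
#' distribution, distinct annotators are sampled, each assigns a category
#' from their confusion row given the true label, and a 0-9 confidence from
#' the correctness-conditional distribution.
#'
#' @param corpus Labelled corpus data.frame.
#' @param am An [annotator_model()].
#' @param seed Integer seed.
#' @return Annotation data.frame `doc_id`, `annotator_id`, `category`,
#'   `confidence`.
#' @export
simulate_annotators <- function(corpus, am, seed = 1L) {
  stopifnot(inherits(am, "cantm_annotator_model"), !any(is.na(corpus$label)))
  labels <- sort(unique(corpus$label))
  if (length(labels) > am$n_classes) stop("annotator model has too few classes")
  rng <- .local_rng(seed)
  rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    k <- rng$rmultinom_draw(1L, am$coverage)
    k <- min(k, am$n_annotators)
    anns <- rng$sample(am$n_annotators)[seq_len(k)]
    true_idx <- match(corpus$label[i], labels)
    cat_idx <- vapply(anns, function(a) {
      rng$rmultinom_draw(1L, am$confusion[[a]][true_idx, seq_along(labels)])
    }, integer(1))
    correct <- cat_idx == true_idx
    conf <- vapply(correct, function(ok) {
      rng$rmultinom_draw(1L, if (ok) am$conf_correct else am$conf_wrong) - 1L
    }, integer(1))
    rows[[i]] <- data.frame(doc_id = corpus$id[i],
                            annotator_id = sprintf("ann%02d", anns),
                            category = labels[cat_idx],
                            confidence = conf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
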
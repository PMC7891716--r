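#' @keywords internal
"_PACKAGE"

# A corpus is a plain data.frame with columns:
#   id (character), text (character), label (character or NA),
# plus a list-column `tokens` added by tokenize_corpus(). Metadata fields
# (date, platform, veracity, media type) travel as extra character columns.

.default_stopwords <- function() {
  # compact English stop-list; tokens of length 1 are dropped separately
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "herself", "him", "himself", "his", "how", "if", "in",
    "into", "is", "it", "its", "itself", "just", "me", "more", "most", "my",
    "myself", "no", "nor", "not", "now", "of", "off", "on", "once", "only",
    "or", "other", "our", "ours", "ourselves", "out", "over", "own", "same",
    "she", "should", "so", "some", "such", "than", "that", "the", "their",
    "theirs", "them", "themselves", "then", "there", "these", "they", "this",
    "those", "through", "to", "too", "under", "until", "up", "very", "was",
    "we", "were", "what", "when", "where", "which", "while", "who", "whom",
    "why", "will", "with", "you", "your", "yours", "yourself", "yourselves")
}

#' Tokenise raw text
#'
#' Deterministic normalisation used throughout the package: lowercase, split
#' on non-alphanumeric characters, drop single-character tokens and (by
#' default) a standard English stop-list. The same normalisation must be used
#' when building the vocabulary and when vectorising new documents against an
#' existing checkpoint.
#'
#' @param text Character vector of raw document texts.
#' @param stopwords Character vector of tokens to drop, or `NULL` to keep all.
#' @param min_chars Minimum token length retained (default 2).
#' @return A list of character vectors, one per input text.
#' @export
tokenize_text <- function(text, stopwords = .default_stopwords(),
                          min_chars = 2L) {
  stopifnot(is.character(text))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk) & nchar(tk) >= min_chars]
    if (length(stopwords)) tk <- tk[!tk %in% stopwords]
    tk
  })
}

#' Attach a `tokens` list-column to a corpus
#'
#' @param corpus Corpus data.frame with a `text` column.
#' @param text_fields Character vector of column names concatenated (space
#'   joined) before tokenisation; classification input is typically the claim
#'   together with the fact-checker's explanation.
#' @inheritParams tokenize_text
#' @return The corpus with a `tokens` list-column.
#' @export
tokenize_corpus <- function(corpus, text_fields = "text",
                            stopwords = .default_stopwords(),
                            min_chars = 2L) {
  stopifnot(is.data.frame(corpus), all(text_fields %in% names(corpus)))
  joined <- do.call(paste, corpus[text_fields])
  corpus$tokens <- tokenize_text(joined, stopwords = stopwords,
                                 min_chars = min_chars)
  corpus
}

#' Build a capped vocabulary from a tokenised corpus
#'
#' Selects the `max_size` most frequent tokens (after normalisation and
#' stop-token removal), requiring at least `min_count` occurrences. Frequency
#' ties at the cut are broken lexicographically so the result is fully
#' deterministic.
#'
#' @param corpus Tokenised corpus (see [tokenize_corpus()]), or a list of
#'   token vectors.
#' @param max_size Maximum vocabulary size (the topic-modelling default used
#'   in the experiments is 2000).
#' @param min_count Minimum corpus frequency for a token to be eligible.
#' @return An object of class `cantm_vocab`: list with `tokens` (character,
#'   index i = token i) and `index` (named integer map token -> 1-based index).
#' @export
build_vocabulary <- function(corpus, max_size = 2000L, min_count = 1L) {
  tokens <- if (is.data.frame(corpus)) corpus$tokens else corpus
  if (is.null(tokens)) stop("corpus has no `tokens` column; run tokenize_corpus() first")
  if (length(tokens) == 0L) stop("cannot build a vocabulary from an empty corpus")
  if (max_size < 1L) stop("max_size must be >= 1")
  freq <- table(unlist(tokens, use.names = FALSE))
  if (length(freq) == 0L) stop("no tokens survive normalisation; vocabulary would be empty")
  freq <- freq[freq >= min_count]
  if (length(freq) == 0L) stop("no token reaches min_count")
  # order: frequency descending, then token lexicographic ascending
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  keep <- names(freq)[ord][seq_len(min(max_size, length(freq)))]
  structure(list(tokens = keep,
                 index = stats::setNames(seq_along(keep), keep)),
            class = "cantm_vocab")
}

#' @export
print.cantm_vocab <- function(x, ...) {
  cat(sprintf("<cantm_vocab> %d tokens: %s ...\n", length(x$tokens),
              paste(utils::head(x$tokens, 5L), collapse = ", ")))
  invisible(x)
}

#' Bag-of-words vector for one document
#'
#' Out-of-vocabulary tokens are ignored; a fully out-of-vocabulary document
#' yields the zero vector (downstream model operations reject it explicitly).
#'
#' @param tokens Character vector of document tokens.
#' @param vocab A [build_vocabulary()] result.
#' @return Integer count vector of length `|V|`, named by token.
#' @export
vectorize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "cantm_vocab"))
  v <- integer(length(vocab$tokens))
  names(v) <- vocab$tokens
  idx <- vocab$index[tokens]
  idx <- idx[!is.na(idx)]
  if (length(idx)) {
    tab <- tabulate(idx, nbins = length(vocab$tokens))
    v[] <- tab
  }
  v
}

#' Document-term count matrix for a corpus
#'
#' @param corpus Tokenised corpus.
#' @inheritParams vectorize
#' @return Integer matrix, rows = documents (named by id), cols = vocabulary.
#' @export
corpus_bow_matrix <- function(corpus, vocab) {
  stopifnot(is.data.frame(corpus), !is.null(corpus$tokens))
  V <- length(vocab$tokens)
  X <- matrix(unlist(lapply(corpus$tokens, vectorize, vocab = vocab)),
              nrow = nrow(corpus), ncol = V, byrow = TRUE)
  rownames(X) <- corpus$id
  colnames(X) <- vocab$tokens
  X
}

#' Read a corpus from JSON-lines or CSV
#'
#' JSON-lines records carry fields `id`, `text`, optional `label` and optional
#' flat `metadata`; CSV needs a header with at least a `text` column. Missing
#' ids are filled with the row number. When `label_set` is given, any record
#' with a label outside it aborts with the offending line number.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"` (default guessed from the extension).
#' @param label_set Optional character vector of admissible labels.
#' @return Corpus data.frame (not yet tokenised).
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        label_set = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$text)) {
        stop(sprintf("malformed corpus record at line %d of %s", i, path))
      }
      recs[[i]] <- rec
    }
    df <- data.frame(
      id = vapply(seq_along(recs), function(i) {
        if (!is.null(recs[[i]]$id)) as.character(recs[[i]]$id) else as.character(i)
      }, character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      label = vapply(recs, function(r) {
        if (is.null(r$label)) NA_character_ else as.character(r$label)
      }, character(1)),
      stringsAsFactors = FALSE
    )
    meta_names <- unique(unlist(lapply(recs, function(r) names(r$metadata))))
    for (mn in meta_names) {
      df[[mn]] <- vapply(recs, function(r) {
        v <- r$metadata[[mn]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8", colClasses = "character")
    if (is.null(df$text)) stop("CSV corpus needs a `text` column: ", path)
    if (is.null(df$id)) df$id <- as.character(seq_len(nrow(df)))
    if (is.null(df$label)) df$label <- NA_character_
  }
  if (!is.null(label_set)) {
    bad <- which(!is.na(df$label) & !df$label %in% label_set)
    if (length(bad)) {
      stop(sprintf("unknown label '%s' at record %d (allowed: %s)",
                   df$label[bad[1]], bad[1],
                   paste(label_set, collapse = ", ")))
    }
  }
  df
}

#' Write a corpus as JSON-lines
#'
#' @param corpus Corpus data.frame.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  core <- c("id", "text", "label", "tokens")
  meta_cols <- setdiff(names(corpus), core)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (!is.na(corpus$label[i])) rec$label <- corpus$label[i]
    if (length(meta_cols)) {
      md <- as.list(corpus[i, meta_cols, drop = FALSE])
      md <- md[!vapply(md, function(v) is.na(v[[1]]), logical(1))]
      if (length(md)) rec$metadata <- md
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Assign documents to cross-validation folds
#'
#' Deterministic given `seed`. With `stratified = TRUE` (the default) labels
#' are shuffled within class and dealt round-robin, so each fold's per-label
#' count differs from the proportional share by at most one.
#'
#' @param corpus Corpus data.frame (needs `label` when stratified).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Stratify folds by label?
#' @return Object of class `cantm_split`: list with `k`, `seed` and
#'   `assignments` (named integer vector, doc id -> fold in 1..k).
#' @export
make_folds <- function(corpus, k = 5L, seed = 1L, stratified = TRUE) {
  n <- nrow(corpus)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d exceeds corpus size %d", k, n))
  rng <- .local_rng(seed)
  fold <- integer(n)
  if (stratified && !all(is.na(corpus$label))) {
    for (lab in unique(corpus$label)) {
      idx <- which(corpus$label == lab)
      idx <- idx[rng$sample(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    idx <- rng$sample(n)
    fold[idx] <- rep_len(seq_len(k), n)
  }
  structure(list(k = k, seed = seed,
                 assignments = stats::setNames(fold, corpus$id)),
            class = "cantm_split")
}

#' @export
print.cantm_split <- function(x, ...) {
  cat(sprintf("<cantm_split> k = %d, seed = %d, sizes: %s\n", x$k, x$seed,
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

#' Write / read fold assignments as JSON
#' @param split A [make_folds()] result.
#' @param path File path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(k = split$k, seed = split$seed,
                            assignments = as.list(split$assignments)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(k = obj$k, seed = obj$seed,
                 assignments = unlist(obj$assignments)),
            class = "cantm_split")
}

# Isolated RNG helper: runs seeded draws without disturbing the global
# .Random.seed more than R semantics require; returns closures.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  use <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(sample = use(sample.int),
       rnorm = use(stats::rnorm),
       runif = use(stats::runif),
       rmultinom_draw = use(function(n, prob) sample.int(length(prob), n, replace = TRUE, prob = prob)))
}
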
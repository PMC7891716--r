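# Curation of multi-annotator category labels: agreement measurement,
# leave-one-out annotator scoring, confidence filtering and label merging.
# An annotation table is a data.frame with columns
#   doc_id, annotator_id, category, confidence (integer 0..9).

.check_annotations <- function(records) {
  need <- c("doc_id", "annotator_id", "category", "confidence")
  if (!all(need %in% names(records))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(records$confidence < 0 | records$confidence > 9, na.rm = TRUE)) {
    stop("confidence must lie in 0..9")
  }
  records
}

#' Read an annotation table from CSV
#'
#' Expects a header `doc_id,annotator_id,category,confidence`.
#'
#' @param path CSV path.
#' @param label_set Optional admissible category names; violations abort.
#' @return Annotation data.frame.
#' @export
read_annotations <- function(path, label_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$doc_id <- as.character(df$doc_id)
  df$annotator_id <- as.character(df$annotator_id)
  df$confidence <- as.integer(df$confidence)
  .check_annotations(df)
  if (!is.null(label_set)) {
    bad <- which(!df$category %in% label_set)
    if (length(bad)) {
      stop(sprintf("unknown category '%s' at record %d", df$category[bad[1]], bad[1]))
    }
  }
  df
}

# all unordered same-document annotation pairs, as a 2-column category matrix
.annotation_pairs <- function(records) {
  out <- list()
  for (d in split(records, records$doc_id)) {
    n <- nrow(d)
    if (n < 2L) next
    cmb <- utils::combn(n, 2L)
    out[[length(out) + 1L]] <-
      cbind(d$category[cmb[1L, ]], d$category[cmb[2L, ]])
  }
  if (!length(out)) return(matrix(character(0), ncol = 2L))
  do.call(rbind, out)
}

#' Pairwise inter-annotator agreement
#'
#' Over all unordered pairs of annotations of the same document (pooled
#' across documents), the fraction whose categories match. A document with
#' three annotators contributes three pairs.
#'
#' @param records Annotation data.frame.
#' @return Agreement in `[0, 1]`.
#' @export
pairwise_agreement <- function(records) {
  .check_annotations(records)
  pairs <- .annotation_pairs(records)
  if (nrow(pairs) == 0L) stop("no document has two or more annotations")
  mean(pairs[, 1L] == pairs[, 2L])
}

#' Cohen's kappa on pooled annotation pairs
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, where
#' \eqn{p_e} comes from the two rater-slots' marginal category frequencies.
#' With anonymous pooled pairs the slot convention (record order within each
#' document) is fixed and documented; see the methods vignette.
#'
#' @param pairs Two-column character matrix/data.frame of category pairs, or
#'   an annotation data.frame (pairs are then formed per document).
#' @return Kappa in `[-1, 1]`. When both raters are constant and equal
#'   (`p_e = 1`), returns 1 by convention with a message.
#' @export
cohens_kappa <- function(pairs) {
  if (is.data.frame(pairs) && all(c("doc_id", "category") %in% names(pairs))) {
    pairs <- .annotation_pairs(pairs)
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) stop("need at least one pair")
  cats <- sort(unique(c(pairs[, 1L], pairs[, 2L])))
  p1 <- table(factor(pairs[, 1L], cats)) / nrow(pairs)
  p2 <- table(factor(pairs[, 2L], cats)) / nrow(pairs)
  po <- mean(pairs[, 1L] == pairs[, 2L])
  pe <- sum(as.numeric(p1) * as.numeric(p2))
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    message("degenerate kappa: both raters constant and equal; returning 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Leave-one-out annotator quality scores
#'
#' For each annotator appearing on a multiply-annotated document, the score is
#' the change in overall pairwise agreement when that annotator's records are
#' removed: `agreement(without) - agreement(all)`. A larger score means the
#' annotator is more harmful (their removal improves agreement). Annotators
#' whose removal empties the pair set get `NA` and are flagged.
#'
#' @param records Annotation data.frame.
#' @return data.frame `annotator_id`, `score`, `defined`, sorted most harmful
#'   first (NA scores last).
#' @export
score_annotators <- function(records) {
  .check_annotations(records)
  base <- pairwise_agreement(records)
  multi_docs <- names(which(table(records$doc_id) >= 2L))
  anns <- sort(unique(records$annotator_id[records$doc_id %in% multi_docs]))
  if (length(anns) < 2L) stop("need at least two annotators on multiply-annotated documents")
  score <- vapply(anns, function(a) {
    rest <- records[records$annotator_id != a, , drop = FALSE]
    pairs <- .annotation_pairs(rest)
    if (nrow(pairs) == 0L) return(NA_real_)
    mean(pairs[, 1L] == pairs[, 2L]) - base
  }, numeric(1))
  out <- data.frame(annotator_id = anns, score = score,
                    defined = !is.na(score), stringsAsFactors = FALSE)
  out[order(-ifelse(is.na(out$score), -Inf, out$score)), , drop = FALSE]
}

#' Remove the n most harmful annotators
#'
#' @param records Annotation data.frame.
#' @param n Number of annotators to drop (the study dropped 2).
#' @return Filtered records, with attribute `removed` naming the annotators.
#' @export
remove_worst_annotators <- function(records, n = 2L) {
  if (n < 1L) return(records)
  sc <- score_annotators(records)
  drop <- utils::head(sc$annotator_id[sc$defined], n)
  out <- records[!records$annotator_id %in% drop, , drop = FALSE]
  attr(out, "removed") <- drop
  out
}

#' Filter annotations by per-annotator confidence threshold
#'
#' Keeps records with `confidence >=` the annotator's threshold; annotators
#' absent from `thresholds` use `default_threshold` (the study default is 6).
#' The operation is idempotent.
#'
#' @param records Annotation data.frame.
#' @param thresholds Named integer vector annotator_id -> threshold.
#' @param default_threshold Threshold applied when no per-annotator value set.
#' @return Filtered records.
#' @export
filter_by_confidence <- function(records, thresholds = integer(0),
                                 default_threshold = 6L) {
  .check_annotations(records)
  if (length(thresholds) && any(thresholds < 0 | thresholds > 9)) {
    stop("thresholds must lie in 0..9")
  }
  thr <- rep(default_threshold, nrow(records))
  if (length(thresholds)) {
    m <- match(records$annotator_id, names(thresholds))
    thr[!is.na(m)] <- thresholds[m[!is.na(m)]]
  }
  records[records$confidence >= thr, , drop = FALSE]
}

#' Merge multiple annotations into one label per document
#'
#' Per document: a single annotation is adopted directly (`single`); a
#' category annotated strictly more often than every other wins (`majority`);
#' otherwise the label of the highest-confidence record is adopted
#' (`confidence`); a residual confidence tie across categories is broken by
#' lexicographic category order (`tie_broken`).
#'
#' @param records Filtered annotation data.frame.
#' @return data.frame `doc_id`, `category`, `rule_used`, one row per document
#'   with at least one record; attribute `n_dropped` counts empty documents.
#' @export
merge_labels <- function(records) {
  .check_annotations(records)
  docs <- split(records, records$doc_id)
  rows <- lapply(docs, function(d) {
    if (nrow(d) == 1L) {
      return(data.frame(doc_id = d$doc_id[1], category = d$category[1],
                        rule_used = "single", stringsAsFactors = FALSE))
    }
    tab <- sort(table(d$category), decreasing = TRUE)
    if (length(tab) == 1L || (tab[1] > tab[2] && tab[1] >= 2L)) {
      return(data.frame(doc_id = d$doc_id[1], category = names(tab)[1],
                        rule_used = "majority", stringsAsFactors = FALSE))
    }
    cmax <- max(d$confidence)
    top <- sort(unique(d$category[d$confidence == cmax]))
    rule <- if (length(top) == 1L) "confidence" else "tie_broken"
    data.frame(doc_id = d$doc_id[1], category = top[1], rule_used = rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- 0L
  out
}

#' Category counts and majority-class share
#'
#' @param merged [merge_labels()] output, or any data.frame with a `category`
#'   column (a character vector also works).
#' @return List with `counts` (named integer, descending), `total`, and
#'   `majority_share_pct` (max count / total as a percent, 1 decimal).
#' @export
category_counts <- function(merged) {
  cats <- if (is.data.frame(merged)) merged$category else merged
  if (!length(cats)) stop("no merged labels")
  counts <- sort(table(cats), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       total = sum(counts),
       majority_class = names(counts)[1],
       majority_share_pct = round(100 * counts[[1]] / sum(counts), 1))
}

#' Agreement report before/after curation
#'
#' @param records Annotation data.frame.
#' @return List with `pairwise_agreement`, `kappa` and single/double/multiple
#'   annotation counts.
#' @export
agreement_report <- function(records) {
  .check_annotations(records)
  per_doc <- table(records$doc_id)
  list(pairwise_agreement = pairwise_agreement(records),
       kappa = cohens_kappa(records),
       n_single = sum(per_doc == 1L),
       n_double = sum(per_doc == 2L),
       n_multiple = sum(per_doc > 2L))
}
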
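# Topic-word extraction from the three decoder weight matrices:
#   R   (d_z  x |V|) - latent topics of the M1 document model
#   Rct (|y| x |V|)  - class-associated topics, one row per category
#   Rs  (d_zs x |V|) - classification-aware topics of the M2 model

#' Extract ranked topic-word tables from a decoder matrix
#'
#' For each row of the chosen matrix, returns the `k` highest-weight
#' vocabulary tokens in descending raw decoder weight (the token-global bias
#' is excluded from the ranking), ties broken lexicographically. Rows of the
#' class-associated source are labelled with the class names.
#'
#' @param model A `cantm_model`.
#' @param source `"R"` (latent topics), `"Rct"` (class-associated) or `"Rs"`
#'   (classification-aware). The aliases `"m1"`, `"class"`, `"m2"` are
#'   accepted.
#' @param k Number of topic words per row (default 10).
#' @return Object of class `cantm_topics`: list with `source` and `rows`, a
#'   named list mapping topic id / class name to a data.frame
#'   `token`, `weight` with non-increasing weights.
#' @export
extract_topics <- function(model, source = c("R", "Rct", "Rs",
                                             "m1", "class", "m2"), k = 10L) {
  source <- match.arg(source)
  source <- c(R = "R", Rct = "Rct", Rs = "Rs",
              m1 = "R", class = "Rct", m2 = "Rs")[[source]]
  W <- model$w[[source]]
  if (k > ncol(W)) stop("k exceeds vocabulary size")
  toks <- model$vocab$tokens
  row_names <- if (source == "Rct") model$labels else
    paste0("topic", seq_len(nrow(W)))
  rows <- lapply(seq_len(nrow(W)), function(i) {
    ord <- order(-W[i, ], toks, method = "radix")[seq_len(k)]
    data.frame(token = toks[ord], weight = W[i, ord],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(rows) <- row_names
  structure(list(source = source, k = k, rows = rows),
            class = "cantm_topics")
}

#' @export
print.cantm_topics <- function(x, n = 10L, ...) {
  cat(sprintf("<cantm_topics> source = %s, top-%d words\n", x$source, x$k))
  for (nm in utils::head(names(x$rows), n)) {
    cat(sprintf("  %-14s %s\n", nm,
                paste(x$rows[[nm]]$token, collapse = " ")))
  }
  invisible(x)
}

#' Write a topic table as TSV (one row per topic) or JSON
#'
#' @param topics An [extract_topics()] result.
#' @param path Output path; format chosen by extension (`.json` else TSV).
#' @export
write_topics <- function(topics, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(source = topics$source, k = topics$k,
                              rows = topics$rows),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(names(topics$rows), function(nm) {
      paste(c(nm, topics$rows[[nm]]$token), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
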
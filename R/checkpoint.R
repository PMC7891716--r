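# Single-file checkpoint archive: all weight arrays + config + vocabulary +
# label set, versioned. RDS keeps numeric precision exact, so a checkpoint
# round-trips to identical in-memory objects.

.CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' @param model A `cantm_model`.
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cantm_model"))
  obj <- list(version = .CHECKPOINT_VERSION,
              config = unclass(model$config),
              vocab = model$vocab$tokens,
              labels = model$labels,
              w = model$w)
  tmp <- paste0(path, ".tmp")
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `cantm_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version > .CHECKPOINT_VERSION) {
    stop("unsupported checkpoint version")
  }
  cfg <- obj$config
  config <- structure(cfg, class = "cantm_config")
  vocab <- structure(list(tokens = obj$vocab,
                          index = stats::setNames(seq_along(obj$vocab), obj$vocab)),
                     class = "cantm_vocab")
  structure(list(config = config, vocab = vocab, labels = obj$labels,
                 w = obj$w),
            class = "cantm_model")
}

#' Hash the frozen M1 parameter block
#'
#' Serialises the M1 encoder, posterior maps, decoder and classifier weights
#' and returns a digest string; used to assert that unlabelled adaptation
#' leaves them bit-identical.
#'
#' @param model A `cantm_model`.
#' @return Character digest.
#' @export
m1_parameter_hash <- function(model) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(model$w[.m1_param_names()], tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}
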
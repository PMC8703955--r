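# Checkpoint IO: a checkpoint is a single archive holding every weight
# array plus the model, encoding and normalisation metadata, so loading
# one fully determines inference.

#' Save a trained model checkpoint
#'
#' Serialises the complete model object (weights, model configuration,
#' encoding configuration, recurrence-plot normalizer, seed and, for the
#' decoder, the signal standardisation) to a single file.
#'
#' @param model An `fno_model`, `cnn_model`, `decoder_model` or
#'   `activity_classifier`.
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("fno_model", "cnn_model", "decoder_model",
                              "activity_classifier")))
  saveRDS(list(format = "rpfno_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The model object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rpfno_checkpoint"))
    stop(sprintf("%s is not a checkpoint file", path), call. = FALSE)
  obj$model
}
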
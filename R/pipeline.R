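#' Train the full predictor on a labeled window dataset
#'
#' Trains the k-mer embedding on the dataset's windows, encodes them, and
#' fits the network. The returned predictor bundles the embedding and the
#' model so new windows can be scored directly.
#'
#' @param dataset A labeled [kcr_dataset].
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param embedding_config Named list of [train_embedding()] arguments;
#'   `d` defaults to `model_config$input_channels` and the embedding seed
#'   to `train_config$seed`.
#' @param verbose Log progress?
#' @return A `kcr_predictor`: list with `model`, `embedding`, `threshold`.
#' @export
train_predictor <- function(dataset, model_config = model_config(),
                            train_config = train_config(),
                            embedding_config = list(), verbose = FALSE) {
  windows <- dataset$windows
  if (verbose) log_msg("train", "embedding on %d windows", nrow(windows))
  emb_args <- utils::modifyList(
    list(corpus = windows$residues, d = model_config$input_channels,
         seed = train_config$seed),
    embedding_config)
  emb <- do.call(train_embedding, emb_args)
  enc <- encode_dataset(windows, emb)
  if (verbose) log_msg("train", "fitting network (seed %d)", train_config$seed)
  model <- fit(enc, model_config, train_config, verbose = verbose)
  structure(
    list(model = model, embedding = emb,
         threshold = train_config$class_threshold),
    class = "kcr_predictor"
  )
}

#' @export
print.kcr_predictor <- function(x, ...) {
  cat("<kcr_predictor>\n")
  print(x$embedding)
  print(x$model)
  invisible(x)
}

#' Score peptide windows with a trained predictor
#'
#' @param object A `kcr_predictor`.
#' @param newdata A window `data.frame` (columns `id`, `residues`), a
#'   `kcr_dataset`, or a character vector of window strings.
#' @param type `"prob"` (positive-class probability, default) or
#'   `"class"` (0/1 call at the predictor's threshold).
#' @param ... Unused.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict.kcr_predictor <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  if (is.character(newdata)) {
    newdata <- data.frame(id = sprintf("w%d", seq_along(newdata)),
                          residues = newdata, label = "unlabeled",
                          stringsAsFactors = FALSE)
  }
  windows <- if (inherits(newdata, "kcr_dataset")) newdata$windows else newdata
  if (!"label" %in% names(windows)) windows$label <- "unlabeled"
  enc <- encode_dataset(windows, object$embedding)
  scores <- predict_scores(object$model, enc$x)
  if (type == "class") as.integer(scores >= object$threshold) else scores
}

#' Save / load a predictor checkpoint
#'
#' The checkpoint is an RDS file holding the predictor; a JSON sidecar
#' (`<path>.json`) carries the model configuration for reproducible reload
#' and inspection.
#'
#' @param predictor A `kcr_predictor`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `path`, invisibly (`save_checkpoint`); the predictor
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(predictor, path) {
  stopifnot(inherits(predictor, "kcr_predictor"))
  saveRDS(predictor, path)
  sidecar <- c(unclass(predictor$model$config),
               list(threshold = predictor$threshold,
                    embedding_d = predictor$embedding$d,
                    embedding_k = predictor$embedding$k,
                    package_version = as.character(utils::packageVersion("kcrnet"))))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: %s", path)
  p <- readRDS(path)
  if (!inherits(p, "kcr_predictor")) stop_data("not a kcr_predictor checkpoint: %s", path)
  p
}
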
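#' @title End-to-end staging pipeline
#' @description Ties the modules together: render records as text, pre-train
#'   embeddings, train the four One-vs-Rest CNNs with transfer selection and
#'   dynamic sampling, and predict stage / decision value / treatment for new
#'   records.
#' @name pipeline
NULL

#' Train a full staging model bundle
#'
#' Steps: (1) render every record as a token sequence; (2) pre-train
#' skip-gram embeddings on the corpus; (3) embed records into document
#' matrices; (4) compute the label co-occurrence matrix; (5) train the four
#' OvR CNN classifiers in decreasing positive-count order, initialising each
#' smaller-sample model from its co-occurrence-selected source model when
#' that source is already trained; each classifier is trained with dynamic
#' sampling.
#'
#' @param records List of labelled `patient_record`s.
#' @param ranges Marker reference ranges used for tokenization.
#' @param embed_dim Embedding dimension `n` (default 64).
#' @param window Skip-gram window `d` (default 2).
#' @param sg_epochs Skip-gram training epochs (default 5).
#' @param max_len Document matrix length (default 64).
#' @param windows CNN kernel window sizes (default 3, 4, 5).
#' @param E Dynamic-sampling iterations per label (default 10).
#' @param M Block size per iteration; `NULL` (default) uses
#'   `min(2 * Npos, N)` per label.
#' @param inner_epochs SGD epochs per drawn block.
#' @param lr,batch_size,dropout_rate CNN training hyper-parameters.
#' @param treatment_profile Rule table for recommendations.
#' @param seed Master seed for every stochastic step.
#' @return A list of class `stage_model_bundle`: `embedding`, `models`
#'   (named per stage), `cooccurrence`, `sources` (transfer provenance),
#'   `logs` (per-stage iteration logs), `map`, `ranges`, `max_len`,
#'   `treatment_profile`.
#' @export
train_staging_bundle <- function(records, ranges = normal_ranges(),
                                 embed_dim = 64L, window = 2L,
                                 sg_epochs = 5L, max_len = 64L,
                                 windows = c(3L, 4L, 5L),
                                 E = 10L, M = NULL, inner_epochs = 1L,
                                 lr = 0.05, batch_size = 32L,
                                 dropout_rate = 0.5,
                                 treatment_profile = "coarse", seed = 1L) {
  stopifnot(length(records) > 0)
  corpus <- lapply(records, render_text, ranges = ranges)
  embedding <- train_skipgram(corpus, n = embed_dim, d = window,
                              epochs = sg_epochs, seed = derive_seed(seed, "embed"))
  xs <- lapply(corpus, embed_document, model = embedding, max_len = max_len)
  S <- multilabel_dataset(xs, lapply(records, `[[`, "stages"))
  F_ <- cooccurrence(S)
  ovr <- ovr_split(S)
  sizes <- vapply(ovr, `[[`, integer(1), "Npos")
  train_order <- stage_levels[order(-sizes)]
  models <- stats::setNames(vector("list", 4), stage_levels)
  logs <- stats::setNames(vector("list", 4), stage_levels)
  sources <- stats::setNames(rep(NA_character_, 4), stage_levels)
  for (li in train_order) {
    ds <- ovr[[li]]
    if (ds$Npos == 0 || ds$Nneg == 0) next   # untrainable label: no model
    src <- select_source_label(F_, li, sizes)
    if (!is.null(models[[src]])) {
      init <- models[[src]]
      sources[li] <- src
    } else {
      init <- cnn_model(embed_dim, windows = windows, lr = lr,
                        batch_size = batch_size, dropout_rate = dropout_rate,
                        seed = derive_seed(seed, paste0("init-", li)))
    }
    M_i <- if (is.null(M)) min(2L * ds$Npos, ds$N) else M
    fit <- train_with_dynamic_sampling(ds, init, E = E, M = M_i,
                                       seed = derive_seed(seed, paste0("train-", li)),
                                       inner_epochs = inner_epochs)
    models[[li]] <- fit$model
    logs[[li]] <- fit$log
  }
  structure(list(
    embedding = embedding, models = models, cooccurrence = F_,
    sources = sources, logs = logs, map = staging_map(), ranges = ranges,
    max_len = as.integer(max_len), treatment_profile = treatment_profile,
    seed = as.integer(seed)
  ), class = "stage_model_bundle")
}

#' Predict stage, decision value and treatment for a record
#'
#' @param bundle A [train_staging_bundle()] result.
#' @param record A `patient_record`, or a pre-tokenized character vector.
#' @return A list of class `stage_prediction`: `patient_id`, `confidences`
#'   (named per stage; `NA` stages without a trained model contribute 0),
#'   `decision_value`, `stage`, `treatment`, `is_nsclc`.
#' @export
predict_stage <- function(bundle, record) {
  stopifnot(inherits(bundle, "stage_model_bundle"))
  tokens <- if (is.character(record)) record else
    render_text(record, bundle$ranges)
  X <- embed_document(tokens, bundle$embedding, bundle$max_len)
  conf <- stats::setNames(numeric(4), stage_levels)
  for (li in stage_levels) {
    if (!is.null(bundle$models[[li]])) {
      conf[li] <- cnn_forward(X, bundle$models[[li]], training = FALSE)
    }
  }
  v <- decision_value(conf, bundle$map)
  stage <- stage_from_decision_value(v, bundle$map)
  structure(list(
    patient_id = if (is.character(record)) NA_character_ else record$patient_id,
    confidences = conf, decision_value = v, stage = stage,
    treatment = recommend_treatment(stage, bundle$treatment_profile),
    is_nsclc = stage != "healthy"
  ), class = "stage_prediction")
}

#' Write predictions as JSON-lines
#'
#' One JSON object per line: `patient_id`, `confidences`, `decision_value`,
#' `stage`, `treatment`, `is_nsclc`.
#'
#' @param predictions List of `stage_prediction`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    jsonlite::toJSON(list(
      patient_id = p$patient_id, confidences = as.list(p$confidences),
      decision_value = p$decision_value, stage = p$stage,
      treatment = p$treatment, is_nsclc = p$is_nsclc
    ), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Save/load a staging model bundle as a directory of text artifacts
#'
#' Writes `embeddings.txt` (word2vec text format), one JSON checkpoint per
#' trained stage model (`model_<stage>.json`), per-stage iteration logs
#' (`log_<stage>.csv`), a co-occurrence report (`cooccurrence.csv`), and
#' `bundle.json` with the remaining metadata.
#'
#' @param bundle A `stage_model_bundle`.
#' @param dir Directory path (created if missing).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` a
#'   `stage_model_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "stage_model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_embeddings(bundle$embedding, file.path(dir, "embeddings.txt"))
  for (li in stage_levels) {
    if (!is.null(bundle$models[[li]])) {
      write_cnn_checkpoint(bundle$models[[li]],
                           file.path(dir, paste0("model_", li, ".json")))
    }
    if (!is.null(bundle$logs[[li]])) {
      utils::write.csv(bundle$logs[[li]],
                       file.path(dir, paste0("log_", li, ".csv")),
                       row.names = FALSE)
    }
  }
  cooc <- as.data.frame(unclass(bundle$cooccurrence))
  utils::write.csv(cbind(stage = rownames(cooc), cooc),
                   file.path(dir, "cooccurrence.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    format = "nsclcstager-bundle-1",
    max_len = bundle$max_len,
    map = list(breaks = bundle$map$breaks, iv_cap = bundle$map$iv_cap),
    ranges = lapply(bundle$ranges, as.numeric),
    sources = as.list(bundle$sources),
    treatment_profile = bundle$treatment_profile,
    seed = bundle$seed
  ), file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bundle.json"))
  if (!identical(meta$format, "nsclcstager-bundle-1")) {
    stop("unrecognized bundle format in ", dir)
  }
  embedding <- read_embeddings(file.path(dir, "embeddings.txt"))
  models <- stats::setNames(vector("list", 4), stage_levels)
  logs <- stats::setNames(vector("list", 4), stage_levels)
  for (li in stage_levels) {
    mp <- file.path(dir, paste0("model_", li, ".json"))
    if (file.exists(mp)) models[[li]] <- read_cnn_checkpoint(mp)
    lp <- file.path(dir, paste0("log_", li, ".csv"))
    if (file.exists(lp)) logs[[li]] <- utils::read.csv(lp)
  }
  cooc_df <- utils::read.csv(file.path(dir, "cooccurrence.csv"))
  F_ <- as.matrix(cooc_df[, stage_levels])
  rownames(F_) <- cooc_df$stage
  ranges <- do.call(normal_ranges, meta$ranges)
  sources <- stats::setNames(rep(NA_character_, 4), stage_levels)
  for (li in names(meta$sources)) {
    if (!is.null(meta$sources[[li]])) sources[li] <- meta$sources[[li]]
  }
  structure(list(
    embedding = embedding, models = models,
    cooccurrence = structure(F_, class = c("cooccurrence_matrix", class(F_))),
    sources = sources, logs = logs,
    map = staging_map(meta$map$breaks, meta$map$iv_cap),
    ranges = ranges, max_len = as.integer(meta$max_len),
    treatment_profile = meta$treatment_profile,
    seed = as.integer(meta$seed)
  ), class = "stage_model_bundle")
}
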
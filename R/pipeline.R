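#' Train the full CID extraction pipeline
#'
#' Builds labeled mention-pair instances from the corpus, applies the
#' training-time hypernym filter, then trains the intra-sentence CNN and the
#' inter-sentence maximum-entropy classifier. When the inter-level training
#' set is degenerate (one class only, e.g. on tiny corpora), the MaxEnt
#' model is replaced by an always-negative fallback and a warning is
#' emitted.
#'
#' @param corpus Training `cdr_corpus` (gold relations required).
#' @param parses Matching parse tibble.
#' @param ontology A `mesh_ontology` for hypernym filtering (use an empty
#'   ontology to disable).
#' @param hyper A [cnn_hyper()].
#' @param maxent_l2 L2 strength of the inter-sentence classifier.
#' @param seed Integer seed driving all randomness.
#' @param pretrained Optional word-vector matrix.
#' @param hypernym_filter Apply the training-time hypernym filter.
#' @param max_sentence_gap Inter-instance sentence window.
#' @return A `cdr_model`: the two fitted classifiers plus the configuration
#'   needed to reproduce prediction.
#' @export
cdr_train <- function(corpus, parses, ontology, hyper = cnn_hyper(),
                      maxent_l2 = 0.003, seed = 1L, pretrained = NULL,
                      hypernym_filter = TRUE, max_sentence_gap = 3) {
  instances <- build_instances(corpus, parses, max_sentence_gap = max_sentence_gap)
  instances <- label_instances(instances, corpus$relations)
  n_before <- nrow(instances)
  if (hypernym_filter) {
    instances <- hypernym_filter_train(instances, corpus$relations, ontology)
  }
  inform(sprintf("instances: %d intra, %d inter (%d removed by hypernym filter)",
                 sum(instances$level == "intra"), sum(instances$level == "inter"),
                 n_before - nrow(instances)))
  cnn <- cnn_train(filter(instances, .data$level == "intra"), parses,
                   hyper = hyper, seed = seed, pretrained = pretrained)
  inter <- filter(instances, .data$level == "inter")
  maxent <- if (nrow(inter) > 0 && length(unique(inter$label)) == 2) {
    feats <- extract_inter_features(inter, corpus, parses)
    train_maxent(feats, inter$label, l2 = maxent_l2)
  } else {
    warn("inter-sentence training set is degenerate; using an always-negative fallback")
    NULL
  }
  structure(list(cnn = cnn, maxent = maxent, hyper = hyper,
                 maxent_l2 = maxent_l2, seed = seed,
                 max_sentence_gap = max_sentence_gap,
                 version = 1L),
            class = "cdr_model")
}

#' @export
print.cdr_model <- function(x, ...) {
  cat("<cdr_model> CID extraction pipeline\n")
  print(x$cnn)
  if (is.null(x[["maxent"]])) cat("  inter: always-negative fallback\n") else print(x[["maxent"]])
  invisible(x)
}

#' Predict document-level CID relations
#'
#' Runs the pipeline on a corpus: instance construction, mention-level
#' classification at both levels, merging to document level, test-time
#' hypernym filtering, and post-processing of documents left empty. Set
#' `intra_classifier = "majority"` to replace the CNN by the majority-class
#' (always-negative) baseline — useful for checking how much of the
#' extraction performance is carried by the learned intra-sentence model.
#'
#' @param model A `cdr_model` from [cdr_train()].
#' @param corpus Test `cdr_corpus`.
#' @param parses Matching parse tibble.
#' @param ontology A `mesh_ontology`.
#' @param hypernym_filter Apply the test-time hypernym filter.
#' @param post_process Apply the empty-document heuristics.
#' @param intra_classifier `"cnn"` or `"majority"`.
#' @return Tibble of predicted relations (`doc_id`, `chem_id`, `dis_id`,
#'   `confidence`, `provenance`).
#' @export
cdr_predict <- function(model, corpus, parses, ontology,
                        hypernym_filter = TRUE, post_process = TRUE,
                        intra_classifier = c("cnn", "majority")) {
  intra_classifier <- match.arg(intra_classifier)
  instances <- build_instances(corpus, parses,
                               max_sentence_gap = model$max_sentence_gap)
  intra <- filter(instances, .data$level == "intra")
  inter <- filter(instances, .data$level == "inter")
  intra_pred <- if (intra_classifier == "majority") {
    mutate(intra, pred_label = "negative", confidence = 1)
  } else {
    cnn_predict(model$cnn, intra, parses)
  }
  inter_pred <- if (nrow(inter) == 0) {
    mutate(inter, pred_label = character(0), confidence = numeric(0))
  } else if (is.null(model[["maxent"]])) {
    mutate(inter, pred_label = "negative", confidence = 1)
  } else {
    p <- predict_maxent(model[["maxent"]], extract_inter_features(inter, corpus, parses))
    mutate(inter, pred_label = p$pred_label, confidence = p$confidence)
  }
  relations <- merge_mention_predictions(bind_rows(intra_pred, inter_pred))
  if (hypernym_filter) relations <- hypernym_filter_predict(relations, ontology)
  if (post_process) relations <- post_process(corpus, relations)
  relations
}

#' Save / load a pipeline checkpoint
#'
#' The checkpoint is a single RDS archive holding both fitted models, all
#' hyperparameters, the vocabulary and a format version;
#' `read_checkpoint(write_checkpoint(m, f))` is bit-identical to `m`.
#'
#' @param model A `cdr_model`.
#' @param path Checkpoint file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the `cdr_model`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cdr_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cdr_model") || is.null(model$version)) {
    abort("not a cdr_model checkpoint")
  }
  model
}

#' Write predictions as PubTator CID rows
#'
#' Appends predicted relation rows to each document's title/abstract block,
#' producing a PubTator file; optionally writes a companion TSV with
#' confidence and provenance.
#'
#' @param corpus The predicted-on `cdr_corpus`.
#' @param relations Prediction tibble from [cdr_predict()].
#' @param path Output PubTator path.
#' @param details_path Optional TSV path for confidence/provenance.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(corpus, relations, path, details_path = NULL) {
  out_corpus <- new_cdr_corpus(
    documents = corpus$documents,
    mentions = corpus$mentions,
    relations = select(relations, "doc_id", "chem_id", "dis_id")
  )
  write_pubtator(out_corpus, path)
  if (!is.null(details_path)) {
    hdr <- "doc_id\tchem_id\tdis_id\tconfidence\tprovenance"
    body <- sprintf("%s\t%s\t%s\t%s\t%s", relations$doc_id, relations$chem_id,
                    relations$dis_id,
                    ifelse(is.na(relations$confidence), "NA",
                           format(relations$confidence, digits = 15)),
                    relations$provenance)
    writeLines(c(hdr, body), details_path, useBytes = TRUE)
  }
  invisible(path)
}
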
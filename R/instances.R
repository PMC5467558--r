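#' Build chemical-disease relation instances
#'
#' Relation instances are generated from chemical and disease mentions in a
#' pairwise way and pooled into two groups: intra-sentence (both mentions in
#' one sentence) and inter-sentence (mentions in different sentences). A
#' mention carrying several concept identifiers yields one instance per
#' identifier; the unnormalized identifier `-1` never forms instances.
#'
#' Intra instances cover every (chemical mention, disease mention, chem id,
#' dis id) combination co-occurring in a sentence. Inter instances are built
#' only for concept pairs that never co-occur in any sentence of the
#' document: one instance per cross-sentence mention pair within
#' `max_sentence_gap` sentences, or — when no pair is that close — the single
#' nearest mention pair. Set `all_pairs = TRUE` to keep every cross-sentence
#' mention pair regardless of distance.
#'
#' @param corpus A `cdr_corpus`.
#' @param parses Token tibble from [read_parses()].
#' @param max_sentence_gap Maximum sentence distance for inter instances.
#' @param all_pairs Build inter instances for all cross-sentence mention
#'   pairs instead of the windowed/nearest policy.
#' @return A tibble with one row per instance: `doc_id`, `level`
#'   (`"intra"`/`"inter"`), concept ids, mention spans and texts, sentence
#'   indices, token extents and head tokens for both mentions, and `label`
#'   (`NA` until [label_instances()] is applied).
#' @export
build_instances <- function(corpus, parses, max_sentence_gap = 3, all_pairs = FALSE) {
  split <- split_sentences(corpus, parses)
  m <- split$mentions
  if (nrow(m) > 0) {
    m <- m |>
      mutate(mention_row = row_number(), concept_id = .data$concept_ids) |>
      tidyr::unnest_longer("concept_id") |>
      filter(.data$concept_id != "-1")
  }
  chem <- filter(m, .data$etype == "Chemical")
  dis <- filter(m, .data$etype == "Disease")
  if (nrow(chem) == 0 || nrow(dis) == 0) return(.empty_instances())

  pairs <- inner_join(
    chem |> select("doc_id", chem_id = "concept_id", chem_start = "start",
                   chem_end = "end", chem_text = "text", chem_sent = "sentence_index",
                   chem_tok_first = "tok_first", chem_tok_last = "tok_last",
                   chem_head_tok = "head_tok", chem_row = "mention_row"),
    dis |> select("doc_id", dis_id = "concept_id", dis_start = "start",
                  dis_end = "end", dis_text = "text", dis_sent = "sentence_index",
                  dis_tok_first = "tok_first", dis_tok_last = "tok_last",
                  dis_head_tok = "head_tok", dis_row = "mention_row"),
    by = "doc_id", relationship = "many-to-many"
  )

  intra <- pairs |>
    filter(.data$chem_sent == .data$dis_sent) |>
    mutate(level = "intra", sentence_gap = 0L)

  # concept pairs with at least one same-sentence co-occurrence are settled
  # at intra level; everything else is an inter-level candidate
  inter_cand <- pairs |>
    anti_join(distinct(intra, .data$doc_id, .data$chem_id, .data$dis_id),
              by = c("doc_id", "chem_id", "dis_id")) |>
    mutate(sentence_gap = abs(.data$chem_sent - .data$dis_sent)) |>
    group_by(.data$doc_id, .data$chem_id, .data$dis_id)
  inter <- if (all_pairs) {
    ungroup(inter_cand)
  } else {
    inter_cand |>
      filter(if (any(.data$sentence_gap <= max_sentence_gap)) {
        .data$sentence_gap <= max_sentence_gap
      } else {
        row_number() == order(.data$sentence_gap, .data$chem_sent,
                              .data$dis_sent, .data$chem_start, .data$dis_start)[1]
      }) |>
      ungroup()
  }
  inter <- mutate(inter, level = "inter")

  bind_rows(intra, inter) |>
    mutate(label = NA_character_) |>
    select("doc_id", "level", "chem_id", "dis_id", "chem_start", "chem_end",
           "chem_text", "dis_start", "dis_end", "dis_text", "chem_sent",
           "dis_sent", "sentence_gap", "chem_tok_first", "chem_tok_last",
           "chem_head_tok", "dis_tok_first", "dis_tok_last", "dis_head_tok",
           "chem_row", "dis_row", "label") |>
    arrange(.data$doc_id, .data$level, .data$chem_sent, .data$dis_sent,
            .data$chem_start, .data$dis_start, .data$chem_id, .data$dis_id)
}

.empty_instances <- function() {
  tibble(doc_id = character(), level = character(), chem_id = character(),
         dis_id = character(), chem_start = integer(), chem_end = integer(),
         chem_text = character(), dis_start = integer(), dis_end = integer(),
         dis_text = character(), chem_sent = integer(), dis_sent = integer(),
         sentence_gap = integer(), chem_tok_first = integer(),
         chem_tok_last = integer(), chem_head_tok = integer(),
         dis_tok_first = integer(), dis_tok_last = integer(),
         dis_head_tok = integer(), chem_row = integer(), dis_row = integer(),
         label = character())
}

#' Label instances by distant supervision from document-level gold pairs
#'
#' Gold CID relations are annotated per concept identifier pair, not per
#' mention pair, so every instance inherits the document-level annotation of
#' its (chem id, dis id) pair: positive when the pair is in the gold set,
#' negative otherwise.
#'
#' @param instances Instance tibble from [build_instances()].
#' @param gold_relations Tibble (`doc_id`, `chem_id`, `dis_id`).
#' @return The instances with `label` filled in.
#' @export
label_instances <- function(instances, gold_relations) {
  key <- paste(instances$doc_id, instances$chem_id, instances$dis_id)
  gold <- paste(gold_relations$doc_id, gold_relations$chem_id, gold_relations$dis_id)
  mutate(instances, label = ifelse(key %in% gold, "positive", "negative"))
}

#' Dump instances to a stable TSV for inspection
#'
#' @param instances Instance tibble.
#' @param path Output path, or `NULL` to return lines.
#' @return Lines, invisibly.
#' @export
write_instances_tsv <- function(instances, path = NULL) {
  cols <- c("doc_id", "level", "chem_id", "dis_id", "chem_start", "chem_end",
            "dis_start", "dis_end", "chem_sent", "dis_sent", "label")
  body <- do.call(paste, c(lapply(cols, function(cl) instances[[cl]]), sep = "\t"))
  out <- c(paste(cols, collapse = "\t"), body)
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}
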
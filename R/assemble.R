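#' Merge mention-level predictions into document-level relations
#'
#' A concept pair holds at document level as soon as at least one of its
#' mention-pair instances — at either level — is predicted positive. The
#' relation's confidence is the maximum confidence among its positive
#' supporters and its provenance is the level of that best supporter.
#'
#' @param predictions Instance tibble carrying `pred_label` and `confidence`
#'   columns (intra and inter rows may be mixed; bind them first).
#' @return A tibble of document-level relations: `doc_id`, `chem_id`,
#'   `dis_id`, `confidence`, `provenance`.
#' @export
merge_mention_predictions <- function(predictions) {
  if (nrow(predictions) == 0) return(.empty_doc_relations())
  predictions |>
    filter(.data$pred_label == "positive") |>
    arrange(dplyr::desc(.data$confidence)) |>
    group_by(.data$doc_id, .data$chem_id, .data$dis_id) |>
    summarise(provenance = first(.data$level),
              confidence = first(.data$confidence),
              .groups = "drop") |>
    select("doc_id", "chem_id", "dis_id", "confidence", "provenance") |>
    arrange(.data$doc_id, .data$chem_id, .data$dis_id)
}

.empty_doc_relations <- function() {
  tibble(doc_id = character(), chem_id = character(), dis_id = character(),
         confidence = numeric(), provenance = character())
}

#' Heuristic post-processing for documents with no extracted relation
#'
#' For every document of the corpus whose merged (and filtered) relation set
#' is empty, asserts likely relations: (a) every chemical mentioned in the
#' title is associated with every disease in the document; (b) when the
#' title has no chemical, the most frequently mentioned chemical (by mention
#' count, ties broken by earliest first occurrence) is associated with every
#' disease. Documents with non-empty predictions pass through unchanged, as
#' do documents lacking chemicals or diseases entirely. The unnormalized
#' concept id `-1` never participates.
#'
#' @param corpus The `cdr_corpus` being predicted on (supplies titles and
#'   mentions).
#' @param relations Document-level relation tibble from
#'   [merge_mention_predictions()] (after any hypernym filtering).
#' @return The relation tibble with rows added for previously empty
#'   documents, provenance `pp_rule_a` or `pp_rule_b`, confidence `NA`.
#' @export
post_process <- function(corpus, relations) {
  mentions <- corpus$mentions |>
    mutate(mention_order = row_number(), cid = .data$concept_ids) |>
    tidyr::unnest_longer("cid") |>
    filter(.data$cid != "-1")
  added <- map(corpus$documents$doc_id, function(d) {
    if (any(relations$doc_id == d)) return(NULL)
    m <- filter(mentions, .data$doc_id == d)
    chems <- filter(m, .data$etype == "Chemical")
    diseases <- filter(m, .data$etype == "Disease")
    if (nrow(chems) == 0 || nrow(diseases) == 0) return(NULL)
    title_len <- nchar(corpus$documents$title[corpus$documents$doc_id == d])
    in_title <- filter(chems, .data$end <= title_len)
    if (nrow(in_title) > 0) {
      chem_ids <- unique(in_title$cid)
      rule <- "pp_rule_a"
    } else {
      by_freq <- chems |>
        group_by(.data$cid) |>
        summarise(n = dplyr::n(), first_at = min(.data$start), .groups = "drop") |>
        arrange(dplyr::desc(.data$n), .data$first_at)
      chem_ids <- by_freq$cid[1]
      rule <- "pp_rule_b"
    }
    tidyr::expand_grid(chem_id = chem_ids, dis_id = unique(diseases$cid)) |>
      mutate(doc_id = d, confidence = NA_real_, provenance = rule) |>
      select("doc_id", "chem_id", "dis_id", "confidence", "provenance")
  })
  bind_rows(relations, bind_rows(added)) |>
    arrange(.data$doc_id, .data$chem_id, .data$dis_id)
}
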
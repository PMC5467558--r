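#' Test MeSH hypernymy between two concepts
#'
#' Concept `a` is a hypernym of concept `b` when some tree number of `a` is a
#' proper segment-wise prefix of some tree number of `b` (so `C01.252` is a
#' hypernym of `C01.252.400`, but `C01.25` is not — prefixes are compared at
#' dot boundaries, and a concept is never its own hypernym).
#'
#' @param ontology A `mesh_ontology` from [read_mesh_tree()].
#' @param a,b Concept identifiers. Unknown identifiers have no tree numbers,
#'   so the answer is `FALSE`.
#' @return Logical scalar.
#' @export
is_hypernym <- function(ontology, a, b) {
  ta <- ontology[[a]] %||% character()
  tb <- ontology[[b]] %||% character()
  if (length(ta) == 0 || length(tb) == 0) return(FALSE)
  any(outer(paste0(ta, "."), tb, FUN = function(p, x) startsWith(x, p)))
}

#' Remove over-general negative training instances
#'
#' The CID task asks for relations between the most specific concepts. A
#' labeled negative instance is dropped when its chemical is a hypernym of a
#' chemical participating in any gold relation of the same document, or its
#' disease is a hypernym of a disease in any gold relation of that document.
#' Positive instances are never removed.
#'
#' @param instances Labeled instance tibble from [label_instances()].
#' @param gold_relations Gold relation tibble (`doc_id`, `chem_id`, `dis_id`).
#' @param ontology A `mesh_ontology`.
#' @return The filtered instance tibble.
#' @export
hypernym_filter_train <- function(instances, gold_relations, ontology) {
  if (nrow(instances) == 0) return(instances)
  drop <- map_lgl(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    if (inst$label == "positive") return(FALSE)
    gold <- gold_relations[gold_relations$doc_id == inst$doc_id, ]
    if (nrow(gold) == 0) return(FALSE)
    any(map_lgl(unique(gold$chem_id), function(g) is_hypernym(ontology, inst$chem_id, g))) ||
      any(map_lgl(unique(gold$dis_id), function(g) is_hypernym(ontology, inst$dis_id, g)))
  })
  instances[!drop, ]
}

#' Filter over-general predicted relations
#'
#' Among the predicted document-level pairs, drop a pair whose chemical is a
#' hypernym of another predicted pair's chemical in the same document, or
#' whose disease is a hypernym of another predicted pair's disease.
#'
#' @param relations Tibble of predicted pairs (`doc_id`, `chem_id`, `dis_id`,
#'   plus any extra columns, which are preserved).
#' @param ontology A `mesh_ontology`.
#' @return A subset of `relations`.
#' @export
hypernym_filter_predict <- function(relations, ontology) {
  if (nrow(relations) == 0) return(relations)
  drop <- map_lgl(seq_len(nrow(relations)), function(i) {
    r <- relations[i, ]
    others <- relations[relations$doc_id == r$doc_id, ]
    any(map_lgl(setdiff(unique(others$chem_id), r$chem_id),
                function(c2) is_hypernym(ontology, r$chem_id, c2))) ||
      any(map_lgl(setdiff(unique(others$dis_id), r$dis_id),
                  function(d2) is_hypernym(ontology, r$dis_id, d2)))
  })
  relations[!drop, ]
}
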
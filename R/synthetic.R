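#' Configuration for the synthetic CID corpus generator
#'
#' The generator plants a learnable relation signal. Each document has two
#' "relation" chemicals that co-occur with diseases in subject-verb-object
#' sentences — a trigger verb (e.g. *induced*) marks a gold CID relation,
#' a neutral verb (e.g. *accompanied*) marks a negative co-occurrence — and
#' one "background" chemical mentioned repeatedly in administration
#' sentences without any intra-sentence disease co-occurrence. The first
#' co-occurrence sentence of every document always uses a trigger verb,
#' mirroring a curated corpus in which every abstract carries at least one
#' relation; later ones use a trigger with probability
#' `intra_positive_rate`. With probability `inter_positive_rate` a document
#' plants a cross-sentence relation: a "This drug <trigger> the <disease>"
#' anaphora sentence immediately after one of the background chemical's
#' administration sentences. Gold membership of every mentioned
#' chemical-disease pair is then flipped with probability `noise_rate`.
#' Concept identifiers carry tree numbers from a rooted toy hierarchy, and
#' with probability `hypernym_rate` a document adds a neutral co-occurrence
#' naming a hypernym of one of its relation chemicals, so hypernym filtering
#' has work to do.
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Length-2 integer range, title included (min 6:
#'   title, two co-occurrence sentences, two background sentences, one
#'   spare).
#' @param n_chem_concepts,n_dis_concepts Concept pool sizes (chemical pool
#'   at least 3).
#' @param dis_per_doc Length-2 range of distinct disease concepts per
#'   document.
#' @param trigger_verbs Verbs that mark a planted positive relation.
#' @param neutral_verbs Verbs for negative co-occurrences.
#' @param intra_positive_rate Probability that a co-occurrence sentence
#'   after the first uses a trigger verb.
#' @param inter_positive_rate Probability of planting a cross-sentence
#'   relation.
#' @param hypernym_rate Probability of adding a hypernym co-occurrence.
#' @param title_chem_rate Probability that the title names the background
#'   chemical.
#' @param hierarchy_depth Approximate depth of the toy MeSH hierarchy.
#' @param noise_rate Per-pair probability of flipping gold membership.
#' @param vocab_size Size of the filler lexicon (adverb variety).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 50, sentences_per_doc = c(6, 9),
                         n_chem_concepts = 30, n_dis_concepts = 30,
                         dis_per_doc = c(2, 2),
                         trigger_verbs = c("induced", "caused", "produced", "triggered"),
                         neutral_verbs = c("accompanied", "preceded", "followed", "predated"),
                         intra_positive_rate = 0.75, inter_positive_rate = 0.3,
                         hypernym_rate = 0.2, title_chem_rate = 0.2,
                         hierarchy_depth = 3, noise_rate = 0, vocab_size = 12,
                         seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            intra_positive_rate >= 0, intra_positive_rate <= 1,
            inter_positive_rate >= 0, inter_positive_rate <= 1,
            n_docs >= 0, length(sentences_per_doc) == 2,
            length(dis_per_doc) == 2, dis_per_doc[1] >= 1)
  if (n_docs > 0 && sentences_per_doc[1] < 6) {
    abort("documents need at least 6 sentences (title, 2 co-occurrence, 2 background, 1 spare)")
  }
  if (n_docs > 0 && (n_chem_concepts < 3 || n_dis_concepts < dis_per_doc[2])) {
    abort("concept pools too small: need >= 3 chemicals and enough diseases per document")
  }
  structure(as.list(environment()), class = "synth_config")
}

# heap-shaped tree numbers: node i's parent is floor((i-2)/k)+1
.tree_number <- function(i, k, prefix) {
  path <- integer()
  while (i >= 1) {
    path <- c(i, path)
    i <- if (i == 1) 0L else (i - 2L) %/% k + 1L
  }
  paste(c(prefix, path), collapse = ".")
}

.heap_parent <- function(i, k) if (i <= 1) NA_integer_ else (i - 2L) %/% k + 1L

.heap_ancestors <- function(i, k) {
  out <- integer()
  while (!is.na(i <- .heap_parent(i, k))) out <- c(out, i)
  out
}

# sample concepts that are pairwise hypernym-free (no element an ancestor of
# another): gold relations hold between the most specific concepts, so the
# planted relation concepts of one document must not dominate each other
.sample_free <- function(n_pool, n_pick, k, exclude = integer()) {
  pool <- setdiff(seq_len(n_pool), exclude)
  repeat {
    cand <- pool[sample.int(length(pool), n_pick)]
    related <- any(vapply(cand, function(a)
      any(cand %in% .heap_ancestors(a, k)), logical(1)))
    if (!related) return(cand)
  }
}

.tok <- function(form, lemma, pos, head, deprel) {
  tibble(form = form, lemma = lemma, pos = pos, head = head, deprel = deprel)
}

# each template returns list(tokens, chem = token index or NA, dis = ...)
.sent_templates <- function() {
  list(
    title_plain = function() list(
      tokens = .tok(c("A", "clinical", "case", "report", "."),
                    c("a", "clinical", "case", "report", "."),
                    c("DT", "JJ", "NN", "NN", "."),
                    c(4L, 4L, 4L, 0L, 4L),
                    c("det", "amod", "compound", "root", "punct")),
      chem = NA_integer_, dis = NA_integer_),
    title_chem = function(chem) list(
      tokens = .tok(c("Adverse", "reactions", "to", chem, "."),
                    c("adverse", "reaction", "to", chem, "."),
                    c("JJ", "NNS", "IN", "NN", "."),
                    c(2L, 0L, 4L, 2L, 2L),
                    c("amod", "root", "case", "nmod", "punct")),
      chem = 4L, dis = NA_integer_),
    pair = function(chem, verb, dis) list(
      tokens = .tok(c("The", chem, verb, "the", dis, "."),
                    c("the", chem, verb, "the", dis, "."),
                    c("DT", "NN", "VBD", "DT", "NN", "."),
                    c(2L, 3L, 0L, 5L, 3L, 3L),
                    c("det", "nsubj", "root", "det", "dobj", "punct")),
      chem = 2L, dis = 5L),
    chem_only = function(chem) list(
      tokens = .tok(c("The", chem, "was", "administered", "."),
                    c("the", chem, "be", "administer", "."),
                    c("DT", "NN", "VBD", "VBN", "."),
                    c(2L, 4L, 4L, 0L, 4L),
                    c("det", "nsubjpass", "auxpass", "root", "punct")),
      chem = 2L, dis = NA_integer_),
    anaphora = function(verb, dis) list(
      tokens = .tok(c("This", "drug", verb, "the", dis, "."),
                    c("this", "drug", verb, "the", dis, "."),
                    c("DT", "NN", "VBD", "DT", "NN", "."),
                    c(2L, 3L, 0L, 5L, 3L, 3L),
                    c("det", "nsubj", "root", "det", "dobj", "punct")),
      chem = NA_integer_, dis = 5L),
    dis_only = function(dis) list(
      tokens = .tok(c("The", dis, "was", "observed", "."),
                    c("the", dis, "be", "observe", "."),
                    c("DT", "NN", "VBD", "VBN", "."),
                    c(2L, 4L, 4L, 0L, 4L),
                    c("det", "nsubjpass", "auxpass", "root", "punct")),
      chem = NA_integer_, dis = 2L),
    filler = function(adv) list(
      tokens = .tok(c("The", "patient", "recovered", adv, "."),
                    c("the", "patient", "recover", adv, "."),
                    c("DT", "NN", "VBD", "RB", "."),
                    c(2L, 3L, 0L, 3L, 3L),
                    c("det", "nsubj", "root", "advmod", "punct")),
      chem = NA_integer_, dis = NA_integer_)
  )
}

.adverb_pool <- function(vocab_size) {
  base <- c("quickly", "slowly", "fully", "gradually", "markedly", "promptly",
            "steadily", "partially", "transiently", "repeatedly", "notably",
            "briefly")
  if (vocab_size <= length(base)) return(utils::head(base, max(vocab_size, 1)))
  c(base, paste0(rep(base, length.out = vocab_size - length(base)),
                 seq_len(vocab_size - length(base))))
}

#' Generate a seeded synthetic CID corpus
#'
#' Emits documents, mentions, gold relations, consistent dependency parses
#' and a toy tree-numbered ontology in exactly the shapes the corpus readers
#' produce, so synthetic and real data are interchangeable downstream. The
#' same config (including its seed) gives a byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (a `cdr_corpus`), `parses` (token tibble) and
#'   `ontology` (a `mesh_ontology`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  k <- as.integer(max(2, ceiling(max(cfg$n_chem_concepts, cfg$n_dis_concepts)^
                                   (1 / max(cfg$hierarchy_depth, 1)))))
  chem_ids <- sprintf("D%06d", 100 + seq_len(cfg$n_chem_concepts))
  dis_ids <- sprintf("D%06d", 500 + seq_len(cfg$n_dis_concepts))
  chem_names <- sprintf("chem%02d", seq_len(cfg$n_chem_concepts))
  dis_names <- sprintf("dis%02d", seq_len(cfg$n_dis_concepts))
  ontology <- new_mesh_ontology(c(
    setNames(lapply(seq_len(cfg$n_chem_concepts), .tree_number, k = k, prefix = "CH"),
             chem_ids),
    setNames(lapply(seq_len(cfg$n_dis_concepts), .tree_number, k = k, prefix = "DI"),
             dis_ids)
  ))
  if (cfg$n_docs == 0) {
    return(list(
      corpus = new_cdr_corpus(.empty_documents(), .empty_mentions(), .empty_relations()),
      parses = read_parses(character()),
      ontology = ontology
    ))
  }
  tmpl <- .sent_templates()
  advs <- .adverb_pool(cfg$vocab_size)

  assembled <- map(seq_len(cfg$n_docs), function(di) {
    doc_id <- sprintf("1%05d", di)
    n_sent <- sample(cfg$sentences_per_doc[1]:cfg$sentences_per_doc[2], 1)
    chems3 <- .sample_free(cfg$n_chem_concepts, 3, k)
    rel_chems <- chems3[1:2]
    background <- chems3[3]
    diss <- sort(.sample_free(cfg$n_dis_concepts,
                              sample(cfg$dis_per_doc[1]:cfg$dis_per_doc[2], 1), k))
    planted <- tibble(chem = integer(), dis = integer())
    sents <- list()

    add <- function(s, chem_concept = NULL, dis_concept = NULL) {
      s$chem_concept <- chem_concept
      s$dis_concept <- dis_concept
      sents[[length(sents) + 1]] <<- s
    }

    # title
    if (runif(1) < cfg$title_chem_rate) {
      add(tmpl$title_chem(chem_names[background]), chem_concept = background)
    } else add(tmpl$title_plain())
    budget <- n_sent - 1L

    # two co-occurrence sentences with distinct relation chemicals; the
    # first is always a trigger (every document carries >= 1 relation)
    for (i in 1:2) {
      d <- diss[sample.int(length(diss), 1)]
      pos <- i == 1 || runif(1) < cfg$intra_positive_rate
      verb <- sample(if (pos) cfg$trigger_verbs else cfg$neutral_verbs, 1)
      add(tmpl$pair(chem_names[rel_chems[i]], verb, dis_names[d]),
          chem_concept = rel_chems[i], dis_concept = d)
      if (pos) planted <- bind_rows(planted, tibble(chem = rel_chems[i], dis = d))
      budget <- budget - 1L
    }

    # background chemical block, optionally hosting the cross-sentence
    # signal; the anaphora names its own disease concept (not one of the
    # intra-sentence diseases) so the planted relation is attributable to
    # the cross-sentence template alone
    inter <- budget >= 3 && runif(1) < cfg$inter_positive_rate
    add(tmpl$chem_only(chem_names[background]), chem_concept = background)
    budget <- budget - 1L
    if (inter) {
      # the anaphora disease must be hierarchy-unrelated to the document's
      # other diseases (in either direction) for the same specificity reason
      unrelated <- setdiff(seq_len(cfg$n_dis_concepts),
                           unique(c(diss,
                                    unlist(lapply(diss, .heap_ancestors, k = k)),
                                    which(vapply(seq_len(cfg$n_dis_concepts),
                                                 function(x) any(diss %in% .heap_ancestors(x, k)),
                                                 logical(1))))))
      d <- if (length(unrelated) > 0) {
        unrelated[sample.int(length(unrelated), 1)]
      } else diss[sample.int(length(diss), 1)]
      add(tmpl$anaphora(sample(cfg$trigger_verbs, 1), dis_names[d]),
          dis_concept = d)
      planted <- bind_rows(planted, tibble(chem = background, dis = d))
      budget <- budget - 1L
    }
    add(tmpl$chem_only(chem_names[background]), chem_concept = background)
    budget <- budget - 1L

    # neutral co-occurrence with a hypernym of a planted relation chemical
    if (budget >= 1 && runif(1) < cfg$hypernym_rate) {
      parents <- unique(stats::na.omit(vapply(planted$chem, .heap_parent,
                                              integer(1), k = k)))
      parents <- setdiff(parents, c(rel_chems, background))
      if (length(parents) > 0) {
        pc <- parents[sample.int(length(parents), 1)]
        d <- diss[sample.int(length(diss), 1)]
        add(tmpl$pair(chem_names[pc], sample(cfg$neutral_verbs, 1), dis_names[d]),
            chem_concept = pc, dis_concept = d)
        budget <- budget - 1L
      }
    }

    # pad out with disease-only and filler sentences
    while (budget > 0) {
      if (runif(1) < 0.4) {
        d <- diss[sample.int(length(diss), 1)]
        add(tmpl$dis_only(dis_names[d]), dis_concept = d)
      } else {
        add(tmpl$filler(advs[sample.int(length(advs), 1)]))
      }
      budget <- budget - 1L
    }

    .assemble_doc(list(doc_id = doc_id, sents = sents,
                       planted = distinct(planted, .data$chem, .data$dis),
                       # label flips draw from their own per-document stream
                       # so noise overlays the same planted structure
                       noise_seed = (cfg$seed + 7919L * di) %% 2147483647L),
                  cfg, chem_ids, dis_ids)
  })

  list(
    corpus = new_cdr_corpus(
      documents = bind_rows(map(assembled, "document")),
      mentions = bind_rows(map(assembled, "mentions")),
      relations = bind_rows(map(assembled, "relations"))
    ),
    parses = bind_rows(map(assembled, "parses")),
    ontology = ontology
  )
}

.assemble_doc <- function(d, cfg, chem_ids, dis_ids) {
  offset <- 0L
  tok_rows <- list(); men_rows <- list(); sent_texts <- character()
  for (si in seq_along(d$sents)) {
    s <- d$sents[[si]]
    tk <- s$tokens
    n <- nrow(tk)
    starts <- integer(n); ends <- integer(n)
    pos <- offset
    for (j in seq_len(n)) {
      starts[j] <- pos
      ends[j] <- pos + nchar(tk$form[j])
      pos <- ends[j] + 1L # single space between tokens
    }
    sent_texts[si] <- paste(tk$form, collapse = " ")
    tok_rows[[si]] <- tibble(
      doc_id = d$doc_id, sentence_index = si - 1L, index = seq_len(n),
      form = tk$form, lemma = tk$lemma, pos = tk$pos, head = tk$head,
      deprel = tk$deprel, char_start = starts, char_end = ends
    )
    if (!is.na(s$chem) && !is.null(s$chem_concept)) {
      men_rows[[length(men_rows) + 1]] <- tibble(
        doc_id = d$doc_id, start = starts[s$chem], end = ends[s$chem],
        text = tk$form[s$chem], etype = "Chemical",
        concept_ids = list(chem_ids[s$chem_concept])
      )
    }
    if (!is.na(s$dis) && !is.null(s$dis_concept)) {
      men_rows[[length(men_rows) + 1]] <- tibble(
        doc_id = d$doc_id, start = starts[s$dis], end = ends[s$dis],
        text = tk$form[s$dis], etype = "Disease",
        concept_ids = list(dis_ids[s$dis_concept])
      )
    }
    offset <- offset + nchar(sent_texts[si]) + 1L
  }
  mentions <- if (length(men_rows) > 0) bind_rows(men_rows) else .empty_mentions()

  # gold set: planted positives, then per-candidate-pair label flips over
  # every mentioned chemical x disease combination
  mentioned_chems <- sort(unique(unlist(map(d$sents, function(s)
    if (!is.na(s$chem) && !is.null(s$chem_concept)) s$chem_concept))))
  mentioned_diss <- sort(unique(unlist(map(d$sents, function(s)
    if (!is.na(s$dis) && !is.null(s$dis_concept)) s$dis_concept))))
  gold <- d$planted
  if (cfg$noise_rate > 0 && length(mentioned_chems) > 0 && length(mentioned_diss) > 0) {
    cand <- tidyr::expand_grid(chem = mentioned_chems, dis = mentioned_diss)
    flip <- withr::with_seed(d$noise_seed, runif(nrow(cand)) < cfg$noise_rate)
    for (i in which(flip)) {
      hit <- gold$chem == cand$chem[i] & gold$dis == cand$dis[i]
      if (any(hit)) gold <- gold[!hit, ] else gold <- bind_rows(gold, cand[i, ])
    }
  }
  relations <- if (nrow(gold) > 0) {
    gold <- arrange(gold, .data$chem, .data$dis)
    tibble(doc_id = d$doc_id, chem_id = chem_ids[gold$chem], dis_id = dis_ids[gold$dis])
  } else .empty_relations()

  title <- sent_texts[1]
  abstract <- paste(sent_texts[-1], collapse = " ")
  list(
    document = tibble(doc_id = d$doc_id, title = title, abstract = abstract,
                      text = paste(title, abstract, sep = " ")),
    mentions = mentions,
    relations = relations,
    parses = bind_rows(tok_rows)
  )
}

#' Random embedding table for a generated vocabulary
#'
#' Uniform(-0.05, 0.05) entries with a zero `<PAD>` column — the fallback
#' initialization used when no pretrained vector is available for a token.
#'
#' @param vocab Character vector of tokens.
#' @param d0 Embedding dimension.
#' @param seed Integer seed.
#' @return An `embedding_table`.
#' @export
generate_embeddings <- function(vocab, d0, seed = 1L) {
  embedding_table(vocab, d0, seed = seed)
}

#' Rule-based reference labeler for the planted synthetic signal
#'
#' Predicts a document-level relation for a chemical-disease pair when (a)
#' some sentence contains both mentions with a trigger verb as the sentence
#' root, or (b) a "This drug <trigger> ..." anaphora sentence names the
#' disease and the immediately preceding sentence mentions the chemical. On
#' a corpus generated with `noise_rate = 0` this recovers the gold standard
#' exactly; it is the independent check that the planted signal is
#' recoverable by the trigger-word rule.
#'
#' @param corpus A `cdr_corpus`.
#' @param parses Matching parse tibble.
#' @param trigger_verbs Trigger lexicon (defaults to the generator's).
#' @return Tibble of predicted (`doc_id`, `chem_id`, `dis_id`) pairs.
#' @export
rule_baseline_predict <- function(corpus, parses,
                                  trigger_verbs = synth_config()$trigger_verbs) {
  split <- split_sentences(corpus, parses)
  m <- split$mentions |>
    mutate(cid = .data$concept_ids) |>
    tidyr::unnest_longer("cid") |>
    filter(.data$cid != "-1")
  roots <- parses |>
    filter(.data$head == 0) |>
    select("doc_id", "sentence_index", root_form = "form")
  anaph <- parses |>
    group_by(.data$doc_id, .data$sentence_index) |>
    summarise(is_anaph = any(.data$form == "This") && any(.data$form == "drug"),
              .groups = "drop")
  chem <- filter(m, .data$etype == "Chemical")
  dis <- filter(m, .data$etype == "Disease")
  intra <- inner_join(chem, dis, by = c("doc_id", "sentence_index"),
                      relationship = "many-to-many", suffix = c("_c", "_d")) |>
    inner_join(roots, by = c("doc_id", "sentence_index")) |>
    filter(.data$root_form %in% trigger_verbs) |>
    distinct(.data$doc_id, chem_id = .data$cid_c, dis_id = .data$cid_d)
  inter <- dis |>
    inner_join(roots, by = c("doc_id", "sentence_index")) |>
    inner_join(anaph, by = c("doc_id", "sentence_index")) |>
    filter(.data$is_anaph, .data$root_form %in% trigger_verbs) |>
    mutate(prev_sent = .data$sentence_index - 1L) |>
    inner_join(chem |> select("doc_id", prev_sent = "sentence_index",
                              chem_id = "cid"),
               by = c("doc_id", "prev_sent"), relationship = "many-to-many") |>
    distinct(.data$doc_id, .data$chem_id, dis_id = .data$cid)
  bind_rows(intra, inter) |>
    distinct(.data$doc_id, .data$chem_id, .data$dis_id) |>
    arrange(.data$doc_id, .data$chem_id, .data$dis_id)
}
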
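#' Read a PubTator-format corpus
#'
#' Parses the line-oriented PubTator dialect used by the BioCreative CDR
#' distribution: per document a `PMID|t|TITLE` line, a `PMID|a|ABSTRACT`
#' line, then tab-separated rows for entity mentions
#' (`PMID start end text type conceptID[|conceptID...]`) and document-level
#' CID relations (`PMID CID chemID disID`), with a blank line between
#' documents. Document text is reconstructed as `title + " " + abstract` and
#' every mention's character span is validated against it.
#'
#' @param input Path to a file, or a character vector of lines.
#' @param strict If `TRUE`, conditions normally reported as warnings
#'   (unnormalized `-1` concept identifiers, gold relations whose identifiers
#'   never appear on a mention) become errors.
#' @return An object of class `cdr_corpus`: a list of three tibbles —
#'   `documents` (`doc_id`, `title`, `abstract`, `text`), `mentions`
#'   (`doc_id`, `start`, `end`, `text`, `etype`, `concept_ids` list-column),
#'   and `relations` (`doc_id`, `chem_id`, `dis_id`).
#' @export
read_pubtator <- function(input, strict = FALSE) {
  lines <- .as_lines(input)
  blocks <- .split_blocks(lines)
  parsed <- map(blocks, .parse_pubtator_block)
  corpus <- if (length(parsed) == 0) {
    new_cdr_corpus(.empty_documents(), .empty_mentions(), .empty_relations())
  } else {
    new_cdr_corpus(
      documents = bind_rows(map(parsed, "document")),
      mentions  = bind_rows(map(parsed, "mentions")),
      relations = bind_rows(map(parsed, "relations"))
    )
  }
  validate_corpus(corpus, strict = strict)
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]: `read_pubtator(write_pubtator(x, f))`
#' reproduces `x` field for field, and files produced by this writer
#' round-trip byte-identically.
#'
#' @param corpus A `cdr_corpus`.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return The character vector of lines, invisibly.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "cdr_corpus"))
  out <- unlist(map(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i, ]
    m <- filter(corpus$mentions, .data$doc_id == d$doc_id)
    r <- filter(corpus$relations, .data$doc_id == d$doc_id)
    c(
      paste0(d$doc_id, "|t|", d$title),
      paste0(d$doc_id, "|a|", d$abstract),
      if (nrow(m) > 0) {
        paste(m$doc_id, m$start, m$end, m$text, m$etype,
              map_chr(m$concept_ids, paste, collapse = "|"),
              sep = "\t")
      },
      if (nrow(r) > 0) paste(r$doc_id, "CID", r$chem_id, r$dis_id, sep = "\t"),
      ""
    )
  }))
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Construct a corpus object from its component tables
#'
#' @param documents,mentions,relations Tibbles as produced by
#'   [read_pubtator()].
#' @return A `cdr_corpus`.
#' @export
new_cdr_corpus <- function(documents, mentions, relations) {
  structure(
    list(documents = as_tibble(documents),
         mentions = as_tibble(mentions),
         relations = as_tibble(relations)),
    class = "cdr_corpus"
  )
}

#' @export
print.cdr_corpus <- function(x, ...) {
  cat(sprintf("<cdr_corpus> %d documents, %d mentions, %d gold relations\n",
              nrow(x$documents), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' Validate corpus invariants
#'
#' Checks that every mention span matches the document text slice, that
#' entity types are `Chemical`/`Disease`, that no span crosses the
#' title/abstract boundary, and (as warnings) that gold relation identifiers
#' are grounded in at least one mention of the matching type.
#'
#' @inheritParams write_pubtator
#' @param strict Upgrade warnings to errors.
#' @return The corpus, invisibly validated.
#' @export
validate_corpus <- function(corpus, strict = FALSE) {
  complain <- if (strict) abort else warn
  docs <- corpus$documents
  if (nrow(corpus$mentions) > 0) {
    m <- left_join(corpus$mentions, docs, by = "doc_id")
    bad <- which(substr(m$text.y, m$start + 1, m$end) != m$text.x)
    if (length(bad) > 0) {
      b <- m[bad[1], ]
      abort(sprintf(
        "mention offset mismatch in doc %s [%d,%d): annotation %s, text slice %s",
        b$doc_id, b$start, b$end, dQuote(b$text.x),
        dQuote(substr(b$text.y, b$start + 1, b$end))))
    }
    bad_type <- setdiff(unique(m$etype), c("Chemical", "Disease"))
    if (length(bad_type) > 0) {
      abort(paste0("unknown entity type: ", paste(bad_type, collapse = ", ")))
    }
    straddle <- which(m$start < nchar(m$title) & m$end > nchar(m$title))
    if (length(straddle) > 0) {
      abort(sprintf("mention crosses title/abstract boundary in doc %s",
                    m$doc_id[straddle[1]]))
    }
    unnorm <- map_lgl(m$concept_ids, function(x) any(x == "-1"))
    if (any(unnorm)) {
      complain(sprintf("%d mention(s) carry the unnormalized concept id -1",
                       sum(unnorm)))
    }
  }
  if (nrow(corpus$relations) > 0) {
    known <- corpus$mentions |>
      mutate(cid = .data$concept_ids) |>
      tidyr::unnest_longer("cid") |>
      distinct(.data$doc_id, .data$etype, .data$cid)
    rel <- corpus$relations
    chem_ok <- paste(rel$doc_id, rel$chem_id) %in%
      paste(known$doc_id[known$etype == "Chemical"], known$cid[known$etype == "Chemical"])
    dis_ok <- paste(rel$doc_id, rel$dis_id) %in%
      paste(known$doc_id[known$etype == "Disease"], known$cid[known$etype == "Disease"])
    if (!all(chem_ok & dis_ok)) {
      complain(sprintf("%d gold relation(s) reference concept ids with no mention",
                       sum(!(chem_ok & dis_ok))))
    }
  }
  invisible(corpus)
}

#' Read dependency parses
#'
#' Reads per-sentence dependency parses in an 8-column tabular dialect:
#' blocks headed by `#doc_id<TAB>sentence_index`, then one token per line
#' with fields `index form lemma pos head deprel char_start char_end`
#' (1-based token index, 0 head = root, character offsets into the document
#' text). Each block must form a single rooted tree.
#'
#' @param input Path or character vector of lines.
#' @return A tibble of tokens with columns `doc_id`, `sentence_index`,
#'   `index`, `form`, `lemma`, `pos`, `head`, `deprel`, `char_start`,
#'   `char_end`.
#' @export
read_parses <- function(input) {
  lines <- .as_lines(input)
  lines <- lines[nzchar(lines)]
  heads <- grepl("^#", lines)
  if (length(lines) > 0 && !heads[1]) abort("parse stream must start with a #doc_id header")
  block_id <- cumsum(heads)
  out <- map(split(lines, block_id), function(bl) {
    hd <- strsplit(sub("^#", "", bl[1]), "\t", fixed = TRUE)[[1]]
    if (length(hd) != 2) abort(paste0("malformed parse header: ", bl[1]))
    tok <- strsplit(bl[-1], "\t", fixed = TRUE)
    if (any(lengths(tok) != 8)) {
      abort(sprintf("parse block %s/%s: token rows must have 8 fields", hd[1], hd[2]))
    }
    tok <- do.call(rbind, tok)
    tibble(
      doc_id = hd[1],
      sentence_index = as.integer(hd[2]),
      index = as.integer(tok[, 1]),
      form = tok[, 2], lemma = tok[, 3], pos = tok[, 4],
      head = as.integer(tok[, 5]), deprel = tok[, 6],
      char_start = as.integer(tok[, 7]), char_end = as.integer(tok[, 8])
    )
  })
  parses <- bind_rows(out)
  if (nrow(parses) == 0) {
    return(tibble(doc_id = character(), sentence_index = integer(),
                  index = integer(), form = character(), lemma = character(),
                  pos = character(), head = integer(), deprel = character(),
                  char_start = integer(), char_end = integer()))
  }
  .validate_trees(parses)
  parses
}

#' Write dependency parses in the block dialect read by [read_parses()]
#'
#' @param parses Token tibble as returned by [read_parses()].
#' @param path Output path, or `NULL` to return lines.
#' @return Lines, invisibly.
#' @export
write_parses <- function(parses, path = NULL) {
  key <- paste(parses$doc_id, parses$sentence_index, sep = "\r")
  out <- unlist(map(split(seq_len(nrow(parses)), factor(key, levels = unique(key))),
                    function(idx) {
    p <- parses[idx, ]
    c(paste0("#", p$doc_id[1], "\t", p$sentence_index[1]),
      paste(p$index, p$form, p$lemma, p$pos, p$head, p$deprel,
            p$char_start, p$char_end, sep = "\t"))
  }))
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

.validate_trees <- function(parses) {
  key <- paste(parses$doc_id, parses$sentence_index)
  for (idx in split(seq_len(nrow(parses)), key)) {
    p <- parses[idx, ]
    n <- nrow(p)
    where <- sprintf("doc %s sentence %d", p$doc_id[1], p$sentence_index[1])
    if (!identical(sort(p$index), seq_len(n))) {
      abort(paste0("token indices must be 1..n in ", where))
    }
    p <- p[order(p$index), ]
    if (sum(p$head == 0) != 1) {
      abort(paste0("parse tree must have exactly one root in ", where))
    }
    if (any(p$head < 0 | p$head > n)) {
      abort(paste0("head index out of range in ", where))
    }
    # cycle check: walk to root from every node, bounded by n steps
    for (i in seq_len(n)) {
      cur <- i; steps <- 0L
      while (cur != 0L) {
        cur <- p$head[cur]; steps <- steps + 1L
        if (steps > n) abort(paste0("cyclic head links in ", where))
      }
    }
    if (any(diff(p$char_start) <= 0) || any(p$char_end <= p$char_start) ||
        any(utils::head(p$char_end, -1) > utils::tail(p$char_start, -1))) {
      abort(paste0("token char spans must be increasing and non-overlapping in ", where))
    }
  }
  invisible(parses)
}

#' Read a MeSH tree-number table
#'
#' Reads tab-separated rows `conceptID<TAB>treeNumber`; a concept may repeat
#' across rows and accumulates all its tree numbers. Tree numbers are
#' dot-separated alphanumeric segments (e.g. `C14.280.067`).
#'
#' @param input Path or character vector of lines.
#' @return A `mesh_ontology`: a named list mapping concept id to a character
#'   vector of tree numbers. Concepts absent from the table have an empty
#'   set, so every hypernymy query on them is `FALSE`.
#' @export
read_mesh_tree <- function(input) {
  lines <- .as_lines(input)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_mesh_ontology(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) abort("MeSH tree rows must have 2 tab-separated fields")
  tab <- do.call(rbind, parts)
  bad <- !grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", tab[, 2])
  if (any(bad)) {
    abort(paste0("malformed tree number: ", tab[which(bad)[1], 2]))
  }
  new_mesh_ontology(lapply(split(tab[, 2], tab[, 1]), unique))
}

#' Write a MeSH tree-number table
#'
#' @param ontology A `mesh_ontology`.
#' @param path Output path, or `NULL`.
#' @return Lines, invisibly.
#' @export
write_mesh_tree <- function(ontology, path = NULL) {
  out <- unlist(imap(unclass(ontology), function(nums, id) paste(id, nums, sep = "\t")),
                use.names = FALSE)
  out <- out %||% character()
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' @rdname read_mesh_tree
#' @param tree_numbers Named list of character vectors of tree numbers.
#' @export
new_mesh_ontology <- function(tree_numbers) {
  structure(tree_numbers, class = "mesh_ontology")
}

#' @export
print.mesh_ontology <- function(x, ...) {
  cat(sprintf("<mesh_ontology> %d concepts, %d tree numbers\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Read word vectors in the whitespace text format
#'
#' One line per token: `token v1 v2 ... vd`. Only tokens in `vocab_filter`
#' are retained (mirroring the practice of keeping only corpus vocabulary
#' from a large pretrained table); absent tokens are simply missing from the
#' result and callers substitute random vectors.
#'
#' @param input Path or lines.
#' @param vocab_filter Character vector of tokens to keep; `NULL` keeps all.
#' @return A `d0 x n` numeric matrix with token colnames.
#' @export
read_word_vectors <- function(input, vocab_filter = NULL) {
  lines <- .as_lines(input)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(matrix(numeric(), nrow = 0, ncol = 0))
  parts <- strsplit(lines, "[ \t]+")
  toks <- map_chr(parts, 1)
  keep <- if (is.null(vocab_filter)) rep(TRUE, length(toks)) else toks %in% vocab_filter
  parts <- parts[keep]; toks <- toks[keep]
  if (length(parts) == 0) return(matrix(numeric(), nrow = 0, ncol = 0))
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1) {
    abort(sprintf("inconsistent vector dimension: %s",
                  paste(unique(dims), collapse = " vs ")))
  }
  vec <- vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1]))
  vec <- matrix(vec, nrow = dims[1])
  colnames(vec) <- toks
  vec
}

#' Assign mentions to sentences
#'
#' Sentence extents are defined by the parse file: each sentence spans from
#' its first token's `char_start` to its last token's `char_end`. Every
#' mention is assigned to the sentence containing its start offset; a mention
#' overlapping a sentence boundary is assigned to the sentence containing its
#' start and a warning is emitted. Each mention also gets its token extent
#' and a head token — the unique mention token whose governor lies outside
#' the mention (falling back to the last mention token).
#'
#' @param corpus A `cdr_corpus`.
#' @param parses Token tibble from [read_parses()].
#' @return A list with `sentences` (tibble `doc_id`, `sentence_index`,
#'   `char_start`, `char_end`) and `mentions` (the corpus mentions augmented
#'   with `sentence_index`, `tok_first`, `tok_last`, `head_tok`).
#' @export
split_sentences <- function(corpus, parses) {
  sentences <- parses |>
    group_by(.data$doc_id, .data$sentence_index) |>
    summarise(char_start = min(.data$char_start),
              char_end = max(.data$char_end), .groups = "drop") |>
    arrange(.data$doc_id, .data$sentence_index)

  m <- corpus$mentions
  if (nrow(m) == 0) {
    return(list(sentences = sentences,
                mentions = mutate(m, sentence_index = integer(),
                                  tok_first = integer(), tok_last = integer(),
                                  head_tok = integer())))
  }
  assigned <- pmap(list(m$doc_id, m$start, m$end), function(d, s, e) {
    sen <- sentences[sentences$doc_id == d &
                       sentences$char_start <= s & s < sentences$char_end, ]
    if (nrow(sen) != 1) {
      abort(sprintf("mention at [%d,%d) in doc %s lies in %d sentences",
                    s, e, d, nrow(sen)))
    }
    if (e > sen$char_end) {
      warn(sprintf("mention at [%d,%d) in doc %s overlaps a sentence boundary; assigned to sentence %d",
                   s, e, d, sen$sentence_index))
    }
    tok <- parses[parses$doc_id == d & parses$sentence_index == sen$sentence_index, ]
    tok <- tok[order(tok$index), ]
    inside <- which(tok$char_start < e & tok$char_end > s)
    if (length(inside) == 0) {
      abort(sprintf("mention at [%d,%d) in doc %s covers no token", s, e, d))
    }
    heads_out <- inside[!(tok$head[inside] %in% tok$index[inside])]
    head_tok <- if (length(heads_out) == 1) tok$index[heads_out] else tok$index[max(inside)]
    list(sentence_index = sen$sentence_index,
         tok_first = tok$index[min(inside)],
         tok_last = tok$index[max(inside)],
         head_tok = head_tok)
  })
  m$sentence_index <- map_int(assigned, "sentence_index")
  m$tok_first <- map_int(assigned, "tok_first")
  m$tok_last <- map_int(assigned, "tok_last")
  m$head_tok <- map_int(assigned, "head_tok")
  list(sentences = sentences, mentions = m)
}

# ---- internal helpers -------------------------------------------------------

.as_lines <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (length(input) == 1 && grepl("\n", input)) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(input)
  }
}

.split_blocks <- function(lines) {
  lines <- c(lines, "")
  blank <- !nzchar(trimws(lines))
  id <- cumsum(c(TRUE, utils::head(blank, -1)))
  blocks <- split(lines[!blank], id[!blank])
  unname(blocks[lengths(blocks) > 0])
}

.parse_pubtator_block <- function(block) {
  tline <- grepl("^[^\t|]+\\|t\\|", block)
  aline <- grepl("^[^\t|]+\\|a\\|", block)
  if (sum(tline) != 1 || sum(aline) != 1) {
    abort(paste0("PubTator block must have one |t| and one |a| line; got: ",
                 block[1]))
  }
  doc_id <- sub("\\|.*$", "", block[which(tline)])
  title <- sub("^[^|]+\\|t\\|", "", block[which(tline)])
  abstract <- sub("^[^|]+\\|a\\|", "", block[which(aline)])
  text <- paste(title, abstract, sep = " ")
  rows <- strsplit(block[!tline & !aline], "\t", fixed = TRUE)
  is_rel <- map_lgl(rows, function(r) length(r) == 4 && r[2] == "CID")
  is_men <- map_lgl(rows, function(r) length(r) == 6)
  if (any(!is_rel & !is_men)) {
    abort(sprintf("malformed annotation row in doc %s: %s", doc_id,
                  paste(rows[[which(!is_rel & !is_men)[1]]], collapse = "\\t")))
  }
  mrows <- rows[is_men]
  mentions <- if (length(mrows) > 0) {
    tab <- do.call(rbind, mrows)
    if (any(tab[, 1] != doc_id)) abort(paste0("row PMID mismatch in doc ", doc_id))
    tibble(
      doc_id = doc_id,
      start = as.integer(tab[, 2]), end = as.integer(tab[, 3]),
      text = tab[, 4], etype = tab[, 5],
      concept_ids = strsplit(tab[, 6], "|", fixed = TRUE)
    )
  } else .empty_mentions()
  rrows <- rows[is_rel]
  relations <- if (length(rrows) > 0) {
    tab <- do.call(rbind, rrows)
    if (any(tab[, 1] != doc_id)) abort(paste0("row PMID mismatch in doc ", doc_id))
    tibble(doc_id = doc_id, chem_id = tab[, 3], dis_id = tab[, 4])
  } else .empty_relations()
  list(
    document = tibble(doc_id = doc_id, title = title, abstract = abstract, text = text),
    mentions = mentions,
    relations = relations
  )
}

.empty_documents <- function() {
  tibble(doc_id = character(), title = character(),
         abstract = character(), text = character())
}
.empty_mentions <- function() {
  tibble(doc_id = character(), start = integer(), end = integer(),
         text = character(), etype = character(), concept_ids = list())
}
.empty_relations <- function() {
  tibble(doc_id = character(), chem_id = character(), dis_id = character())
}
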
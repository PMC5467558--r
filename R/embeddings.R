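#' Build an embedding look-up table
#'
#' The vocabulary always contains the padding token `<PAD>` (a frozen all-zero
#' column), the out-of-vocabulary token `<UNK>`, the synthetic `ROOT` node and
#' the traversal arrows used in dependency-path tokens, followed by the
#' caller's tokens. Entries are initialized uniform(-0.05, 0.05); columns for
#' tokens present in `pretrained` are copied from it instead.
#'
#' @param tokens Character vector of vocabulary tokens (deduplicated; special
#'   tokens are added automatically).
#' @param d0 Embedding dimension.
#' @param seed Integer seed driving the random initialization.
#' @param pretrained Optional `d0 x n` matrix with token colnames, as from
#'   [read_word_vectors()].
#' @return An `embedding_table`: list with `vocab` (named integer index) and
#'   `T` (`d0 x |V|` matrix).
#' @export
embedding_table <- function(tokens, d0, seed = 1L, pretrained = NULL) {
  vocab_tokens <- unique(c(.PAD, .UNK, .ROOT, .ARROW_UP, .ARROW_DOWN, tokens))
  vocab <- setNames(seq_along(vocab_tokens), vocab_tokens)
  T_ <- withr::with_seed(seed, {
    matrix(runif(d0 * length(vocab), -0.05, 0.05), nrow = d0)
  })
  if (!is.null(pretrained) && ncol(pretrained) > 0) {
    if (nrow(pretrained) != d0) {
      abort(sprintf("pretrained vectors have dimension %d, expected %d",
                    nrow(pretrained), d0))
    }
    hit <- intersect(colnames(pretrained), vocab_tokens)
    T_[, vocab[hit]] <- pretrained[, hit]
  }
  T_[, vocab[[.PAD]]] <- 0
  structure(list(vocab = vocab, T = T_), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> d0 = %d, |V| = %d\n", nrow(x$T), length(x$vocab)))
  invisible(x)
}

.token_index <- function(table, tokens) {
  idx <- table$vocab[tokens]
  idx[is.na(idx)] <- table$vocab[[.UNK]]
  unname(idx)
}

#' Embed a token sequence
#'
#' Column `i` of the result is the embedding of token `i` — the matrix-vector
#' product of the look-up table with the token's one-hot indicator. `<PAD>`
#' maps to the zero vector; tokens absent from the vocabulary map to the
#' `<UNK>` column.
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector of tokens.
#' @return A `d0 x length(tokens)` matrix.
#' @export
cnn_lookup <- function(table, tokens) {
  stopifnot(length(tokens) >= 1)
  table$T[, .token_index(table, tokens), drop = FALSE]
}

#' Mention embedding as the mean of its token embeddings
#'
#' @param table An `embedding_table`.
#' @param tokens The mention's tokens (at least one).
#' @return A length-`d0` vector.
#' @export
mention_embedding <- function(table, tokens) {
  rowMeans(cnn_lookup(table, tokens))
}
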
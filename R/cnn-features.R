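#' CNN hyperparameters
#'
#' Bundles the intra-sentence network's hyperparameters with their defaults:
#' contextual window `w = 5`, dependency-path window `v = 9`, convolution
#' output size `n1 = 300`, hidden size `n2 = 1500`, `n3 = 2` relation labels,
#' L2 coefficient `lambda = 1e-4`, dropout probability `p_drop = 0.3`,
#' AdaGrad learning rate `lr = 0.002`, mini-batch size 64, embedding
#' dimension `d0 = 300`, `V_max = 5` verb slots, padded path length
#' `L_max = 40`, 15 training epochs.
#'
#' @param w,v Odd context/path window sizes.
#' @param n1,n2,n3 Convolution, hidden and output sizes.
#' @param lambda L2 regularization coefficient.
#' @param p_drop Dropout probability in `[0, 1)`.
#' @param lr AdaGrad learning rate.
#' @param batch Mini-batch size.
#' @param d0 Word-embedding dimension.
#' @param V_max Number of between-mention verb slots.
#' @param L_max Padded length of each dependency path.
#' @param epochs Training epochs.
#' @param pool_include_pad Pool over padding columns too (default masks
#'   columns whose center token is `<PAD>`).
#' @param pool_per_path Pool each of the three path blocks separately and
#'   take the elementwise max (default pools jointly over all columns of Z).
#' @return A `cnn_hyper` list.
#' @export
cnn_hyper <- function(w = 5, v = 9, n1 = 300, n2 = 1500, n3 = 2,
                      lambda = 1e-4, p_drop = 0.3, lr = 0.002, batch = 64,
                      d0 = 300, V_max = 5, L_max = 40, epochs = 15,
                      pool_include_pad = FALSE, pool_per_path = FALSE) {
  stopifnot(w %% 2 == 1, w >= 1, v %% 2 == 1, v >= 1,
            p_drop >= 0, p_drop < 1, n1 >= 1, n2 >= 1, n3 >= 2, L_max >= 1)
  structure(list(w = w, v = v, n1 = n1, n2 = n2, n3 = n3, lambda = lambda,
                 p_drop = p_drop, lr = lr, batch = batch, d0 = d0,
                 V_max = V_max, L_max = L_max, epochs = epochs,
                 pool_include_pad = pool_include_pad,
                 pool_per_path = pool_per_path),
            class = "cnn_hyper")
}

# size of the contextual feature vector in embedding units
.n_ctx_slots <- function(hyper) 2 + 2 * (hyper$w - 1) + hyper$V_max

#' Extract the three dependency paths of a mention pair
#'
#' Returns the root-to-chemical (R2C), root-to-disease (R2D) and
#' chemical-to-disease (C2D) paths through the sentence's dependency tree as
#' token sequences interleaving surface forms, dependency labels and
#' traversal arrows: a head-to-dependent step contributes
#' `"↓", label, "↓", word` and a dependent-to-head step contributes
#' `"↑", label, "↑", word`. R2C/R2D start at the synthetic `ROOT` node; C2D
#' runs through the unique tree path between the two mention head tokens (a
#' shared head token gives the single word token).
#'
#' @param tree Token tibble for one sentence (columns `index`, `form`,
#'   `head`, `deprel`).
#' @param chem_head,dis_head 1-based token indices of the mention heads.
#' @return A list with character vectors `r2c`, `r2d`, `c2d`.
#' @export
extract_dependency_paths <- function(tree, chem_head, dis_head) {
  tree <- tree[order(tree$index), ]
  n <- nrow(tree)
  stopifnot(chem_head >= 1, chem_head <= n, dis_head >= 1, dis_head <= n)
  chain <- function(i) { # node indices from root token down to i
    out <- integer()
    while (i != 0L) { out <- c(i, out); i <- tree$head[i] }
    out
  }
  root_path <- function(i) {
    steps <- chain(i)
    out <- .ROOT
    for (s in steps) out <- c(out, .ARROW_DOWN, tree$deprel[s], .ARROW_DOWN, tree$form[s])
    out
  }
  ch <- chain(chem_head); dh <- chain(dis_head)
  k <- min(length(ch), length(dh))
  common <- max(which(ch[seq_len(k)] == dh[seq_len(k)]))
  # chem-side nodes strictly below the lowest common ancestor, nearest first
  up_nodes <- if (common < length(ch)) rev(ch[(common + 1):length(ch)]) else integer()
  down_nodes <- if (common < length(dh)) dh[(common + 1):length(dh)] else integer()
  c2d <- tree$form[chem_head]
  cur <- chem_head
  for (s in up_nodes) {
    parent <- tree$head[s]
    parent_form <- if (parent == 0L) .ROOT else tree$form[parent]
    c2d <- c(c2d, .ARROW_UP, tree$deprel[s], .ARROW_UP, parent_form)
  }
  for (s in down_nodes) {
    c2d <- c(c2d, .ARROW_DOWN, tree$deprel[s], .ARROW_DOWN, tree$form[s])
  }
  list(r2c = root_path(chem_head), r2d = root_path(dis_head), c2d = c2d)
}

# pad to L tokens; over-long paths are truncated keeping the mention end
# (R2C/R2D: keep the tail; C2D: keep both mention ends, drop the middle)
.fit_path <- function(path, L, keep = c("tail", "ends")) {
  keep <- match.arg(keep)
  n <- length(path)
  if (n > L) {
    path <- if (keep == "tail") {
      path[(n - L + 1):n]
    } else {
      c(path[seq_len(ceiling(L / 2))], path[(n - floor(L / 2) + 1):n])
    }
    n <- L
  }
  c(path, rep(.PAD, L - n))
}

# window index matrix for one padded path: v x L token strings
.path_windows <- function(padded, v) {
  L <- length(padded)
  half <- (v - 1) / 2
  vapply(seq_len(L), function(i) {
    pos <- (i - half):(i + half)
    ifelse(pos >= 1 & pos <= L, padded[pmax(pmin(pos, L), 1)], .PAD)
  }, character(v))
}

#' Window and embed the three dependency paths
#'
#' Each path is right-padded with `<PAD>` to `L_max` tokens (over-long paths
#' are truncated keeping the mention end). For every position the window of
#' `v` tokens centered there (out-of-range positions give `<PAD>`) is
#' embedded and the `v` embeddings are stacked into one column, producing the
#' matrix `X0` of shape `v*d0 x 3*L_max` with the R2C, R2D and C2D blocks
#' concatenated column-wise in that order.
#'
#' @param paths List from [extract_dependency_paths()].
#' @param table An `embedding_table`.
#' @param hyper A `cnn_hyper` (uses `v` and `L_max`).
#' @return The `X0` matrix, with attributes `mask` (logical, `TRUE` where the
#'   window's center token is padding) and `windows` (the `v x 3*L_max`
#'   matrix of window tokens).
#' @export
path_to_windows <- function(paths, table, hyper) {
  win <- .path_window_tokens(paths, hyper)
  idx <- matrix(.token_index(table, win), nrow = nrow(win))
  X0 <- table$T[, as.vector(idx), drop = FALSE]
  dim(X0) <- c(hyper$v * nrow(table$T), ncol(win))
  attr(X0, "mask") <- win[(hyper$v + 1) / 2, ] == .PAD
  attr(X0, "windows") <- win
  X0
}

.path_window_tokens <- function(paths, hyper) {
  padded <- list(
    .fit_path(paths$r2c, hyper$L_max, "tail"),
    .fit_path(paths$r2d, hyper$L_max, "tail"),
    .fit_path(paths$c2d, hyper$L_max, "ends")
  )
  do.call(cbind, lapply(padded, .path_windows, v = hyper$v))
}

# contextual feature slots as token strings, in fixed order:
# chem mention tokens (mean) | dis mention tokens (mean) |
# (w-1)/2 left + (w-1)/2 right of chem | same for dis | V_max verb slots
.ctx_tokens <- function(sent, chem_first, chem_last, dis_first, dis_last, hyper) {
  forms <- sent$form
  n <- length(forms)
  half <- (hyper$w - 1) / 2
  at <- function(pos) ifelse(pos >= 1 & pos <= n, forms[pmax(pmin(pos, n), 1)], .PAD)
  around <- function(first, last) {
    c(at(seq(first - half, length.out = half)), at(seq(last + 1, length.out = half)))
  }
  lo <- min(chem_last, dis_last); hi <- max(chem_first, dis_first)
  between <- if (hi - lo > 1) (lo + 1):(hi - 1) else integer()
  verbs <- between[startsWith(sent$pos[between], "VB")]
  verbs <- utils::head(forms[verbs], hyper$V_max)
  list(
    chem = forms[chem_first:chem_last],
    dis = forms[dis_first:dis_last],
    slots = c(around(chem_first, chem_last), around(dis_first, dis_last),
              c(verbs, rep(.PAD, hyper$V_max - length(verbs))))
  )
}

#' Assemble the contextual feature vector of an intra-sentence instance
#'
#' Concatenates, in fixed order: the chemical mention embedding (mean of its
#' token embeddings), the disease mention embedding, the `(w-1)/2` tokens to
#' the left and right of each mention, and the embeddings of up to `V_max`
#' verbs (POS tag `VB*`) strictly between the mentions, with padding
#' (all-zero) vectors filling positions beyond the sentence bounds and empty
#' verb slots.
#'
#' @param sent Token tibble for the instance's sentence (ordered by `index`).
#' @param chem_first,chem_last,dis_first,dis_last Token extents of the two
#'   mentions.
#' @param table An `embedding_table`.
#' @param hyper A `cnn_hyper` (uses `w` and `V_max`).
#' @return A numeric vector of length `d0 * (2 + 2*(w-1) + V_max)`.
#' @export
contextual_features <- function(sent, chem_first, chem_last, dis_first, dis_last,
                                table, hyper) {
  sent <- sent[order(sent$index), ]
  ctx <- .ctx_tokens(sent, chem_first, chem_last, dis_first, dis_last, hyper)
  c(mention_embedding(table, ctx$chem),
    mention_embedding(table, ctx$dis),
    as.vector(cnn_lookup(table, ctx$slots)))
}
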
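#' Convolution and max-over-time pooling of a windowed path matrix
#'
#' Applies the linear filter bank `Z = W1 %*% X0 + b1` (bias broadcast over
#' columns), takes the per-row maximum over window positions, and passes the
#' pooled vector through `tanh`. The pooled dimension no longer depends on
#' the path length. By default, columns whose window center is the padding
#' token are excluded from the maximum; if every column is masked the pool
#' falls back to the unmasked maximum with a warning.
#'
#' @param X0 Matrix from [path_to_windows()] (`v*d0 x 3*L_max`).
#' @param W1 `n1 x v*d0` filter matrix.
#' @param b1 Length-`n1` bias.
#' @param mask Logical vector marking padded columns; defaults to the `mask`
#'   attribute of `X0`. Use `mask = NULL` (or `rep(FALSE, ncol(X0))`) to pool
#'   over padding too.
#' @return The length-`n1` dependency feature vector `d = tanh(max_j Z[, j])`,
#'   with the pre-activation pooled vector in attribute `pooled` and the
#'   argmax column per row in attribute `argmax`.
#' @export
conv_pool <- function(X0, W1, b1, mask = attr(X0, "mask")) {
  Z <- W1 %*% X0 + b1
  if (is.null(mask)) mask <- rep(FALSE, ncol(Z))
  if (all(mask)) {
    warn("all path columns are padding; pooling over padded columns")
    mask <- rep(FALSE, ncol(Z))
  }
  Zm <- Z
  if (any(mask)) Zm[, mask] <- -Inf
  j <- max.col(Zm, ties.method = "first")
  pooled <- Zm[cbind(seq_len(nrow(Z)), j)]
  d <- tanh(pooled)
  attr(d, "pooled") <- pooled
  attr(d, "argmax") <- j
  d
}

#' Forward pass of the intra-sentence network head
#'
#' Concatenates the contextual feature vector `cvec` and dependency feature
#' vector `dvec` into `k = [c, d]`, applies the hidden layer
#' `r = tanh(W2 k + b2)`, optionally drops out `r` (inverted dropout: the
#' kept units are scaled by `1/(1-p_drop)` so the test-time pass needs no
#' rescaling and equals the undropped network), and scores
#' `o = W3 h + b3`, with class probabilities by softmax.
#'
#' @param cvec,dvec Feature vectors (contextual, dependency).
#' @param params Parameter list with `W2`, `b2`, `W3`, `b3`.
#' @param p_drop Dropout probability (used only when `train = TRUE`).
#' @param train Logical; dropout is applied only during training.
#' @return List with `scores` (length `n3`), `probs` (softmax, sums to 1) and
#'   `hidden` (the post-dropout hidden vector).
#' @export
cnn_forward <- function(cvec, dvec, params, p_drop = 0, train = FALSE) {
  k <- c(cvec, dvec)
  r <- tanh(as.vector(params$W2 %*% k + params$b2))
  h <- if (train && p_drop > 0) {
    r * (rbinom(length(r), 1, 1 - p_drop) / (1 - p_drop))
  } else r
  o <- as.vector(params$W3 %*% h + params$b3)
  list(scores = o, probs = .softmax(o), hidden = h)
}

.softmax <- function(o) {
  e <- exp(o - max(o))
  e / sum(e)
}

.softmax_cols <- function(O) {
  E <- exp(sweep(O, 2, apply(O, 2, max)))
  sweep(E, 2, colSums(E), "/")
}

#' Initialize CNN parameters
#'
#' All weight matrices are initialized uniform(-0.05, 0.05); biases start at
#' zero; the embedding table is taken as-is (its `<PAD>` column is zero and
#' stays frozen throughout training).
#'
#' @param table An `embedding_table` whose `d0` matches `hyper$d0`.
#' @param hyper A `cnn_hyper`.
#' @param seed Integer seed for the random initialization.
#' @return Parameter list `T`, `W1`, `b1`, `W2`, `b2`, `W3`, `b3` with a
#'   `vocab` attribute.
#' @export
cnn_init <- function(table, hyper, seed = 1L) {
  stopifnot(nrow(table$T) == hyper$d0)
  d0 <- hyper$d0
  n_pool <- if (hyper$pool_per_path) 3 * hyper$n1 else hyper$n1
  nf <- d0 * .n_ctx_slots(hyper) + n_pool
  withr::with_seed(seed, {
    params <- list(
      T = table$T,
      W1 = matrix(runif(hyper$n1 * hyper$v * d0, -0.05, 0.05), hyper$n1),
      b1 = numeric(hyper$n1),
      W2 = matrix(runif(hyper$n2 * nf, -0.05, 0.05), hyper$n2),
      b2 = numeric(hyper$n2),
      W3 = matrix(runif(hyper$n3 * hyper$n2, -0.05, 0.05), hyper$n3),
      b3 = numeric(hyper$n3)
    )
  })
  attr(params, "vocab") <- table$vocab
  params
}

#' Precompute CNN input indices for intra-sentence instances
#'
#' Maps every instance to the vocabulary-index structures the network
#' consumes: mention token indices (averaged into the mention embeddings),
#' context/verb slot indices, and the `v x 3*L_max` window index matrix over
#' the three dependency paths, with the padding mask. Out-of-vocabulary
#' tokens map to `<UNK>`.
#'
#' @param instances Intra-level instance tibble (labeled or not).
#' @param parses Token tibble from [read_parses()].
#' @param vocab Named integer vocabulary index (or an `embedding_table`).
#' @param hyper A `cnn_hyper`.
#' @return A list of per-instance feature structures (fields `chem_idx`,
#'   `dis_idx`, `slot_idx`, `win_idx`, `mask`, `y` where `y` is 1 for
#'   negative, 2 for positive, `NA` if unlabeled).
#' @export
cnn_featurise <- function(instances, parses, vocab, hyper) {
  if (inherits(vocab, "embedding_table")) vocab <- vocab$vocab
  stopifnot(all(instances$level == "intra"))
  lookup <- function(tokens) {
    idx <- vocab[tokens]
    idx[is.na(idx)] <- vocab[[.UNK]]
    unname(idx)
  }
  sent_split <- split(parses, paste(parses$doc_id, parses$sentence_index, sep = "\r"))
  sent_split <- lapply(sent_split, function(p) p[order(p$index), ])
  map(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    sent <- sent_split[[paste(inst$doc_id, inst$chem_sent, sep = "\r")]]
    if (is.null(sent)) {
      abort(sprintf("no parse for doc %s sentence %d", inst$doc_id, inst$chem_sent))
    }
    ctx <- .ctx_tokens(sent, inst$chem_tok_first, inst$chem_tok_last,
                       inst$dis_tok_first, inst$dis_tok_last, hyper)
    paths <- extract_dependency_paths(sent, inst$chem_head_tok, inst$dis_head_tok)
    win <- .path_window_tokens(paths, hyper)
    list(
      chem_idx = lookup(ctx$chem),
      dis_idx = lookup(ctx$dis),
      slot_idx = lookup(ctx$slots),
      win_idx = matrix(lookup(win), nrow = nrow(win)),
      mask = win[(hyper$v + 1) / 2, ] == .PAD,
      y = if (is.na(inst$label)) NA_integer_ else if (inst$label == "positive") 2L else 1L
    )
  })
}

# ---- batched forward/backward ----------------------------------------------

# contextual feature matrix (nc x B) for a batch of featurised instances
.ctx_matrix <- function(feats, T_, hyper) {
  nc <- hyper$d0 * .n_ctx_slots(hyper)
  vapply(feats, function(f) {
    c(rowMeans(T_[, f$chem_idx, drop = FALSE]),
      rowMeans(T_[, f$dis_idx, drop = FALSE]),
      as.vector(T_[, f$slot_idx, drop = FALSE]))
  }, numeric(nc))
}

# pooled dependency features for a batch; returns pre-activation matrix and
# argmax bookkeeping for the backward pass
.pool_batch <- function(Z, feats, hyper) {
  n1 <- hyper$n1
  L3 <- 3 * hyper$L_max
  B <- length(feats)
  n_pool <- if (hyper$pool_per_path) 3 * n1 else n1
  P <- matrix(0, n_pool, B)
  argmax <- matrix(0L, n_pool, B) # column index within the instance block
  blocks <- if (hyper$pool_per_path) {
    split(seq_len(L3), rep(1:3, each = hyper$L_max))
  } else list(seq_len(L3))
  for (b in seq_len(B)) {
    Zb <- Z[, (b - 1L) * L3 + seq_len(L3), drop = FALSE]
    if (!hyper$pool_include_pad) {
      msk <- feats[[b]]$mask
      if (!all(msk)) Zb[, msk] <- -Inf
    }
    for (g in seq_along(blocks)) {
      cols <- blocks[[g]]
      Zg <- Zb[, cols, drop = FALSE]
      j <- max.col(Zg, ties.method = "first")
      rows <- (g - 1L) * n1 + seq_len(n1)
      P[rows, b] <- Zg[cbind(seq_len(n1), j)]
      argmax[rows, b] <- cols[j]
    }
  }
  list(P = P, argmax = argmax)
}

#' Objective and analytic gradients for a batch of instances
#'
#' Computes the regularized negative log-likelihood
#' `J = -(1/m) * sum(log p(y_i | x_i)) + lambda * ||theta||^2` over a batch,
#' together with gradients for every parameter in
#' `theta = {T, W1, b1, W2, b2, W3, b3}` by backpropagation. The `<PAD>`
#' embedding column is excluded from both the penalty and the gradient. With
#' `lazy_reg = TRUE` (the training configuration) the embedding penalty is
#' restricted to columns touched by the batch, which keeps the update sparse.
#'
#' @param feats Featurised batch from [cnn_featurise()] (labels required).
#' @param params Parameter list from [cnn_init()].
#' @param hyper A `cnn_hyper`.
#' @param dropout_mask Optional fixed `n2 x B` dropout mask (already scaled);
#'   by default a mask is drawn from the current RNG when `p_drop > 0`, and
#'   no dropout is applied when `p_drop == 0`.
#' @param lazy_reg Restrict the embedding L2 term to touched columns.
#' @return List with `loss` and `grads` (same shapes as `params`).
#' @export
cnn_loss_gradients <- function(feats, params, hyper, dropout_mask = NULL,
                               lazy_reg = FALSE) {
  B <- length(feats)
  stopifnot(B > 0)
  y <- map_int(feats, "y")
  stopifnot(!anyNA(y))
  T_ <- params$T
  L3 <- 3 * hyper$L_max
  v <- hyper$v; d0 <- hyper$d0; n1 <- hyper$n1
  pad_col <- 1L # <PAD> is always the first vocabulary entry

  C <- .ctx_matrix(feats, T_, hyper)
  big_win <- do.call(cbind, map(feats, "win_idx")) # v x (3L*B)
  X0 <- T_[, as.vector(big_win), drop = FALSE]
  dim(X0) <- c(v * d0, L3 * B)
  Z <- params$W1 %*% X0 + params$b1
  pool <- .pool_batch(Z, feats, hyper)
  D <- tanh(pool$P)
  K <- rbind(C, D)
  R <- tanh(params$W2 %*% K + params$b2)
  M <- dropout_mask
  if (is.null(M) && hyper$p_drop > 0) {
    M <- matrix(rbinom(hyper$n2 * B, 1, 1 - hyper$p_drop) / (1 - hyper$p_drop),
                hyper$n2, B)
  }
  H <- if (is.null(M)) R else R * M
  O <- params$W3 %*% H + params$b3
  P <- .softmax_cols(O)
  if (!all(is.finite(P))) abort("non-finite network activations; training diverged")

  nll <- -mean(log(pmax(P[cbind(y, seq_len(B))], .Machine$double.xmin)))
  touched <- sort(unique(c(as.vector(big_win),
                           unlist(map(feats, "chem_idx")),
                           unlist(map(feats, "dis_idx")),
                           unlist(map(feats, "slot_idx")))))
  touched <- setdiff(touched, pad_col)
  reg_cols <- if (lazy_reg) touched else setdiff(seq_len(ncol(T_)), pad_col)
  lam <- hyper$lambda
  reg <- lam * (sum(params$W1^2) + sum(params$b1^2) + sum(params$W2^2) +
                  sum(params$b2^2) + sum(params$W3^2) + sum(params$b3^2) +
                  sum(T_[, reg_cols]^2))
  loss <- nll + reg

  # backward
  dO <- P
  dO[cbind(y, seq_len(B))] <- dO[cbind(y, seq_len(B))] - 1
  dO <- dO / B
  dW3 <- dO %*% t(H) + 2 * lam * params$W3
  db3 <- rowSums(dO) + 2 * lam * params$b3
  dH <- crossprod(params$W3, dO)
  dR <- if (is.null(M)) dH else dH * M
  dA2 <- dR * (1 - R^2)
  dW2 <- dA2 %*% t(K) + 2 * lam * params$W2
  db2 <- rowSums(dA2) + 2 * lam * params$b2
  dK <- crossprod(params$W2, dA2)
  nc <- nrow(C)
  dC <- dK[seq_len(nc), , drop = FALSE]
  dD <- dK[-seq_len(nc), , drop = FALSE]
  dPpool <- dD * (1 - D^2)

  # scatter pooled gradients back to the argmax columns of Z
  dZ <- matrix(0, n1, L3 * B)
  n_pool <- nrow(dPpool)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * L3 + pool$argmax[, b]
    rows <- rep_len(seq_len(n1), n_pool)
    # accumulate (with per-path pooling a row can be hit up to 3 times)
    for (g in seq_len(n_pool / n1)) {
      sel <- (g - 1L) * n1 + seq_len(n1)
      idx <- cbind(rows[sel], cols[sel])
      dZ[idx] <- dZ[idx] + dPpool[sel, b]
    }
  }
  nz <- which(colSums(dZ != 0) > 0)
  dZs <- dZ[, nz, drop = FALSE]
  dW1 <- dZs %*% t(X0[, nz, drop = FALSE]) + 2 * lam * params$W1
  db1 <- rowSums(dZ) + 2 * lam * params$b1
  dX0 <- crossprod(params$W1, dZs) # (v*d0) x |nz|

  # embedding gradients: window contributions + contextual contributions
  ids <- as.vector(big_win[, nz, drop = FALSE])
  G <- dX0
  dim(G) <- c(d0, v * length(nz))
  for (b in seq_len(B)) {
    f <- feats[[b]]
    g <- dC[, b]
    ids <- c(ids, f$chem_idx, f$dis_idx, f$slot_idx)
    gc_ <- matrix(g[seq_len(d0)] / length(f$chem_idx), d0, length(f$chem_idx))
    gd_ <- matrix(g[d0 + seq_len(d0)] / length(f$dis_idx), d0, length(f$dis_idx))
    gs_ <- matrix(g[-seq_len(2 * d0)], d0)
    G <- cbind(G, gc_, gd_, gs_)
  }
  acc <- rowsum(t(G), ids)
  dT <- matrix(0, d0, ncol(T_))
  dT[, as.integer(rownames(acc))] <- t(acc)
  dT[, reg_cols] <- dT[, reg_cols] + 2 * lam * T_[, reg_cols]
  dT[, pad_col] <- 0

  list(loss = loss,
       grads = list(T = dT, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3))
}

#' Train the intra-sentence CNN
#'
#' Mini-batch AdaGrad on the regularized negative log-likelihood: instances
#' are shuffled each epoch, gradients accumulate per-coordinate squared sums
#' `G`, and each coordinate is updated by `lr * g / sqrt(G + 1e-8)`. The
#' vocabulary is built from the training parses (surface forms, lemmas and
#' dependency labels) plus the special tokens; embeddings are initialized
#' from `pretrained` where available and uniform(-0.05, 0.05) otherwise. All
#' randomness (initialization, shuffling, dropout) is driven by `seed`, so a
#' repeated run is bit-identical.
#'
#' @param instances Labeled intra-level instance tibble (at least one
#'   positive and one negative).
#' @param parses Token tibble covering the instances' sentences.
#' @param hyper A `cnn_hyper`.
#' @param seed Integer seed.
#' @param pretrained Optional word-vector matrix from [read_word_vectors()].
#' @return A fitted `cdr_cnn` object: parameters, vocabulary, hyperparameters
#'   and the per-epoch mean training loss trace.
#' @export
cnn_train <- function(instances, parses, hyper = cnn_hyper(), seed = 1L,
                      pretrained = NULL) {
  instances <- filter(instances, .data$level == "intra")
  if (!all(c("positive", "negative") %in% instances$label)) {
    abort("training needs at least one positive and one negative intra instance")
  }
  tokens <- unique(c(parses$form, parses$lemma, parses$deprel))
  table <- embedding_table(tokens, hyper$d0, seed = seed, pretrained = pretrained)
  feats <- cnn_featurise(instances, parses, table$vocab, hyper)
  params <- cnn_init(table, hyper, seed = seed)
  fit <- withr::with_seed(seed + 1L, {
    .adagrad(feats, params, hyper)
  })
  structure(list(params = fit$params, vocab = table$vocab, hyper = hyper,
                 trace = fit$trace, n_train = length(feats), seed = seed),
            class = "cdr_cnn")
}

.adagrad <- function(feats, params, hyper, eps = 1e-8) {
  acc <- lapply(params, function(p) p * 0)
  n <- length(feats)
  trace <- numeric(hyper$epochs)
  pad_col <- 1L
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = hyper$batch)
    losses <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + hyper$batch - 1, n)]
      lg <- cnn_loss_gradients(feats[idx], params, hyper, lazy_reg = TRUE)
      losses[s] <- lg$loss
      if (!is.finite(lg$loss)) abort("training loss diverged (non-finite)")
      for (nm in names(params)) {
        g <- lg$grads[[nm]]
        acc[[nm]] <- acc[[nm]] + g^2
        params[[nm]] <- params[[nm]] - hyper$lr * g / sqrt(acc[[nm]] + eps)
      }
      params$T[, pad_col] <- 0
    }
    trace[ep] <- mean(losses)
  }
  list(params = params, trace = tibble(epoch = seq_len(hyper$epochs), loss = trace))
}

#' Predict labels and confidences for intra-sentence instances
#'
#' Deterministic forward pass (no dropout): the predicted label is the
#' argmax of the softmax scores and the confidence is that probability. With
#' zero scores the tie breaks toward negative.
#'
#' @param model A fitted `cdr_cnn`.
#' @param instances Intra-level instance tibble.
#' @param parses Token tibble covering the instances' sentences.
#' @return The instances with `pred_label` (`"positive"`/`"negative"`) and
#'   `confidence` columns appended.
#' @export
cnn_predict <- function(model, instances, parses) {
  instances <- filter(instances, .data$level == "intra")
  if (nrow(instances) == 0) {
    return(mutate(instances, pred_label = character(), confidence = numeric()))
  }
  hyper <- model$hyper
  feats <- cnn_featurise(instances, parses, model$vocab, hyper)
  L3 <- 3 * hyper$L_max
  probs <- matrix(0, hyper$n3, length(feats))
  chunk <- split(seq_along(feats), ceiling(seq_along(feats) / 256))
  for (idx in chunk) {
    fb <- feats[idx]
    C <- .ctx_matrix(fb, model$params$T, hyper)
    big_win <- do.call(cbind, map(fb, "win_idx"))
    X0 <- model$params$T[, as.vector(big_win), drop = FALSE]
    dim(X0) <- c(hyper$v * hyper$d0, L3 * length(fb))
    Z <- model$params$W1 %*% X0 + model$params$b1
    D <- tanh(.pool_batch(Z, fb, hyper)$P)
    R <- tanh(model$params$W2 %*% rbind(C, D) + model$params$b2)
    probs[, idx] <- .softmax_cols(model$params$W3 %*% R + model$params$b3)
  }
  pos <- probs[2, ]
  mutate(instances,
         pred_label = ifelse(pos > 0.5, "positive", "negative"),
         confidence = ifelse(pos > 0.5, pos, 1 - pos))
}

#' @export
print.cdr_cnn <- function(x, ...) {
  cat(sprintf(
    "<cdr_cnn> d0=%d n1=%d n2=%d |V|=%d; %d instances, %d epochs, final loss %.4f\n",
    x$hyper$d0, x$hyper$n1, x$hyper$n2, length(x$vocab), x$n_train,
    x$hyper$epochs, tail(x$trace$loss, 1)))
  invisible(x)
}

#' @describeIn cnn_train Per-epoch training loss as a tibble.
#' @param x A `cdr_cnn`.
#' @param ... Unused.
#' @method tidy cdr_cnn
#' @export
tidy.cdr_cnn <- function(x, ...) x$trace

#' @describeIn cnn_train One-row model summary.
#' @method glance cdr_cnn
#' @export
glance.cdr_cnn <- function(x, ...) {
  tibble(n_train = x$n_train, epochs = x$hyper$epochs,
         vocab_size = length(x$vocab), d0 = x$hyper$d0, n1 = x$hyper$n1,
         n2 = x$hyper$n2, lambda = x$hyper$lambda, p_drop = x$hyper$p_drop,
         final_loss = tail(x$trace$loss, 1))
}

#' @describeIn cnn_train Training-loss trace plot.
#' @param object A `cdr_cnn`.
#' @method autoplot cdr_cnn
#' @export
autoplot.cdr_cnn <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "Intra-sentence CNN training trace")
}
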
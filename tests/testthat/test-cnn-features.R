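test_that("embedding lookup equals the explicit one-hot matrix product", {
  tab <- embedding_table(c("alpha", "beta", "gamma", "delta", "eps"), d0 = 6,
                         seed = 3)
  tokens <- c("beta", "eps", "alpha", "beta", "delta")
  E <- cnn_lookup(tab, tokens)
  # brute force: build each one-hot indicator and multiply
  for (i in seq_along(tokens)) {
    u <- numeric(length(tab$vocab))
    u[tab$vocab[[tokens[i]]]] <- 1
    expect_equal(E[, i], as.vector(tab$T %*% u))
  }
  # padding embeds to the zero vector
  expect_equal(cnn_lookup(tab, "<PAD>"), matrix(0, 6, 1))
  # repeated tokens give identical columns
  expect_equal(E[, 1], E[, 4])
  # out-of-vocabulary tokens map to the <UNK> column
  expect_equal(cnn_lookup(tab, "missing"), cnn_lookup(tab, "<UNK>"))
})

test_that("pretrained vectors override random initialization where available", {
  pre <- matrix(c(1, 2, 3, 4), 2)
  colnames(pre) <- c("alpha", "zeta")
  tab <- embedding_table(c("alpha", "beta"), d0 = 2, seed = 1, pretrained = pre)
  expect_equal(cnn_lookup(tab, "alpha")[, 1], c(1, 2))
  expect_true(all(abs(cnn_lookup(tab, "beta")) <= 0.05))
  expect_error(embedding_table("a", d0 = 3, pretrained = pre), "dimension")
})

test_that("mention embeddings are token means", {
  tab <- embedding_table(c("a", "b", "c"), d0 = 5, seed = 9)
  expect_equal(mention_embedding(tab, "b"), cnn_lookup(tab, "b")[, 1])
  threetok <- mention_embedding(tab, c("a", "b", "c"))
  expect_equal(threetok, (cnn_lookup(tab, "a") + cnn_lookup(tab, "b") +
                            cnn_lookup(tab, "c"))[, 1] / 3)
  # antisymmetric embeddings cancel
  tab$T[, tab$vocab[["b"]]] <- -tab$T[, tab$vocab[["a"]]]
  expect_equal(mention_embedding(tab, c("a", "b")), rep(0, 5))
})

test_that("dependency paths reproduce the printed R2C/R2D/C2D sequences", {
  paths <- extract_dependency_paths(fig_tree(), chem_head = 2L, dis_head = 5L)
  expect_identical(paths$r2c,
                   c("ROOT", "↓", "root", "↓", "induced", "↓", "nsubj", "↓",
                     "dipyridamole"))
  expect_identical(paths$r2d,
                   c("ROOT", "↓", "root", "↓", "induced", "↓", "dobj", "↓",
                     "hyperemia"))
  expect_identical(paths$c2d,
                   c("dipyridamole", "↑", "nsubj", "↑", "induced", "↓", "dobj",
                     "↓", "hyperemia"))
})

test_that("reversing the C2D endpoints reverses the sequence and flips arrows", {
  fwd <- extract_dependency_paths(fig_tree(), 2L, 5L)$c2d
  rev_ <- extract_dependency_paths(fig_tree(), 5L, 2L)$c2d
  flip <- c("↑" = "↓", "↓" = "↑")
  expect_identical(rev_, unname(ifelse(rev(fwd) %in% names(flip),
                                       flip[rev(fwd)], rev(fwd))))
})

test_that("degenerate paths are handled: shared head and ancestor chains", {
  tr <- fig_tree()
  p <- extract_dependency_paths(tr, 3L, 3L)
  expect_identical(p$c2d, "induced")
  # chem head is an ancestor of the disease head: no upward steps
  p2 <- extract_dependency_paths(tr, 3L, 5L)
  expect_identical(p2$c2d, c("induced", "↓", "dobj", "↓", "hyperemia"))
  # disease head above the chemical head: only upward steps
  p3 <- extract_dependency_paths(tr, 1L, 2L)
  expect_identical(p3$c2d, c("The", "↑", "det", "↑", "dipyridamole"))
})

test_that("path windows match the printed v=3 window list", {
  hyper <- cnn_hyper(v = 3, d0 = 4, w = 3, V_max = 2, L_max = 9, n1 = 2,
                     n2 = 3)
  tab <- embedding_table(unique(c(fig_tree()$form, fig_tree()$deprel)), 4,
                         seed = 2)
  paths <- extract_dependency_paths(fig_tree(), 2L, 5L)
  X0 <- path_to_windows(paths, tab, hyper)
  expect_equal(dim(X0), c(3 * 4, 3 * 9))
  win <- attr(X0, "windows")
  c2d <- win[, 19:27] # third block
  expect_identical(c2d[, 1], c("<PAD>", "dipyridamole", "↑"))
  expect_identical(c2d[, 2], c("dipyridamole", "↑", "nsubj"))
  # the last non-pad window
  expect_identical(c2d[, 9], c("↓", "hyperemia", "<PAD>"))
  # mask marks pad-centered columns; the 9-token path fills L_max exactly
  expect_false(any(attr(X0, "mask")[19:27]))

  # columns whose window is entirely padding are zero
  short <- list(r2c = "ROOT", r2d = "ROOT", c2d = "x")
  tabx <- embedding_table("x", 4, seed = 2)
  X0s <- path_to_windows(short, tabx, hyper)
  all_pad <- colSums(attr(X0s, "windows") == "<PAD>") == hyper$v
  expect_true(any(all_pad))
  expect_true(all(X0s[, all_pad] == 0))
  expect_equal(sum(!attr(X0s, "mask")), 3)
})

test_that("X0 equals hand-stacked embeddings for a random path", {
  hyper <- cnn_hyper(v = 3, d0 = 5, L_max = 6, n1 = 2, n2 = 3, w = 3, V_max = 1)
  toks <- c("t1", "t2", "t3", "t4")
  tab <- embedding_table(toks, 5, seed = 77)
  paths <- list(r2c = "ROOT", r2d = "ROOT", c2d = toks)
  X0 <- path_to_windows(paths, tab, hyper)
  padded <- c(toks, "<PAD>", "<PAD>")
  for (j in seq_len(6)) {
    window <- sapply(j + (-1:1), function(p) {
      if (p < 1 || p > 6) "<PAD>" else padded[p]
    })
    expect_equal(X0[, 12 + j], as.vector(cnn_lookup(tab, window)),
                 info = paste("column", j))
  }
})

test_that("long paths are truncated keeping the mention ends", {
  hyper <- cnn_hyper(v = 3, d0 = 2, L_max = 5, n1 = 2, n2 = 2, w = 3, V_max = 1)
  long <- paste0("w", 1:9)
  tab <- embedding_table(long, 2, seed = 1)
  paths <- list(r2c = long, r2d = long, c2d = long)
  win <- attr(path_to_windows(paths, tab, hyper), "windows")
  centers <- win[2, ]
  # root-anchored paths keep the tail (the mention end)
  expect_identical(centers[1:5], paste0("w", 5:9))
  # the mention-to-mention path keeps both ends, dropping the middle
  expect_identical(centers[11:15], c("w1", "w2", "w3", "w8", "w9"))
})

test_that("contextual features assemble mention, window and verb slots in order", {
  # 7-token sentence: chem at 2, dis at 6, verb at 4
  sent <- tibble::tibble(
    index = 1:7,
    form = c("The", "chemx", "boosted", "hurt", "the", "disz", "."),
    lemma = tolower(c("the", "chemx", "boost", "hurt", "the", "disz", ".")),
    pos = c("DT", "NN", "VBD", "VBD", "DT", "NN", "."),
    head = c(2L, 3L, 0L, 3L, 6L, 4L, 3L),
    deprel = c("det", "nsubj", "root", "xcomp", "det", "dobj", "punct")
  )
  hyper <- cnn_hyper(w = 3, v = 3, V_max = 2, d0 = 3, L_max = 6, n1 = 2, n2 = 2)
  tab <- embedding_table(sent$form, d0 = 3, seed = 5)
  cvec <- contextual_features(sent, 2L, 2L, 6L, 6L, tab, hyper)
  emb <- function(tok) as.vector(cnn_lookup(tab, tok))
  expect_equal(cvec, c(
    emb("chemx"), emb("disz"),                     # mention embeddings
    emb("The"), emb("boosted"),                    # chem left/right context
    emb("the"), emb("."),                          # dis left/right context
    emb("boosted"), emb("hurt")                    # verbs in between
  ))
  expect_length(cvec, 3 * (2 + 2 * (3 - 1) + 2))
})

test_that("contextual features pad at sentence bounds and with no verbs", {
  sent <- tibble::tibble(
    index = 1:3,
    form = c("chemx", "and", "disz"),
    lemma = c("chemx", "and", "disz"),
    pos = c("NN", "CC", "NN"),
    head = c(0L, 3L, 1L),
    deprel = c("root", "cc", "conj")
  )
  hyper <- cnn_hyper(w = 3, v = 3, V_max = 2, d0 = 4, L_max = 6, n1 = 2, n2 = 2)
  tab <- embedding_table(sent$form, d0 = 4, seed = 6)
  cvec <- contextual_features(sent, 1L, 1L, 3L, 3L, tab, hyper)
  emb <- function(tok) as.vector(cnn_lookup(tab, tok))
  zero <- rep(0, 4)
  expect_equal(cvec, c(
    emb("chemx"), emb("disz"),
    zero, emb("and"),     # chem: no left context
    emb("and"), zero,     # dis: no right context
    zero, zero            # no verbs between mentions
  ))
})
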
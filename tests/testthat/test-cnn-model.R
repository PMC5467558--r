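test_that("conv_pool agrees with the naive loop oracle on random instances", {
  withr::with_seed(123, {
    for (trial in 1:200) {
      n1 <- sample(1:4, 1)
      vd0 <- sample(2:5, 1)
      ncols <- sample(2:8, 1)
      X0 <- matrix(rnorm(vd0 * ncols), vd0, ncols)
      W1 <- matrix(rnorm(n1 * vd0), n1, vd0)
      b1 <- rnorm(n1)
      mask <- as.logical(rbinom(ncols, 1, 0.3))
      if (all(mask)) mask[1] <- FALSE
      d <- conv_pool(X0, W1, b1, mask = mask)
      expect_equal(as.vector(d), naive_conv_pool(X0, W1, b1, mask),
                   tolerance = 1e-12)
    }
  })
})

test_that("conv_pool handles degenerate inputs", {
  X0 <- matrix(0, 4, 5)
  d <- conv_pool(X0, matrix(1, 2, 4), c(0, 0), mask = rep(FALSE, 5))
  expect_equal(as.vector(d), c(0, 0)) # tanh(0) = 0
  # all columns masked: falls back to the unmasked max with a warning
  expect_warning(d2 <- conv_pool(X0, matrix(1, 2, 4), c(1, -1),
                                 mask = rep(TRUE, 5)), "padding")
  expect_equal(as.vector(d2), tanh(c(1, -1)))
})

test_that("pooling is invariant to unmasked column permutations and extra padding", {
  withr::with_seed(9, {
    X0 <- matrix(rnorm(6 * 8), 6, 8)
    W1 <- matrix(rnorm(3 * 6), 3, 6)
    b1 <- rnorm(3)
    mask <- c(rep(FALSE, 5), rep(TRUE, 3))
    base <- as.vector(conv_pool(X0, W1, b1, mask = mask))
    perm <- c(sample(1:5), 6:8)
    expect_equal(as.vector(conv_pool(X0[, perm], W1, b1, mask = mask[perm])), base)
    # appending fully padded (zero, masked) columns changes nothing
    X0big <- cbind(X0, matrix(0, 6, 4))
    expect_equal(as.vector(conv_pool(X0big, W1, b1, mask = c(mask, rep(TRUE, 4)))),
                 base)
  })
})

test_that("forward pass: zero parameters give uniform probabilities; dropout off at test", {
  hyper <- tiny_hyper()
  params <- list(W2 = matrix(0, 5, 9), b2 = numeric(5),
                 W3 = matrix(0, 2, 5), b3 = numeric(2))
  out <- cnn_forward(rnorm(6), rnorm(3), params)
  expect_equal(out$probs, c(0.5, 0.5))
  # with p_drop = 0, train and test passes agree
  withr::with_seed(4, {
    params2 <- list(W2 = matrix(rnorm(45), 5, 9), b2 = rnorm(5),
                    W3 = matrix(rnorm(10), 2, 5), b3 = rnorm(2))
    cvec <- rnorm(6); dvec <- rnorm(3)
  })
  expect_equal(cnn_forward(cvec, dvec, params2, p_drop = 0, train = TRUE),
               cnn_forward(cvec, dvec, params2, train = FALSE))
})

test_that("forward pass matches hand-computed probabilities on a tiny model", {
  # nf = 4, n2 = 3, n3 = 2 with simple weights
  params <- list(W2 = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1)),
                 b2 = c(0, 0.5, 0),
                 W3 = rbind(c(1, 1, 0), c(0, 0, 1)),
                 b3 = c(0.1, -0.1))
  cvec <- c(0.2, -0.3)
  dvec <- c(0.4, 0.5)
  r <- tanh(c(0.2, -0.3 + 0.5, 0.4 + 0.5))
  o <- c(r[1] + r[2] + 0.1, r[3] - 0.1)
  expect_equal(cnn_forward(cvec, dvec, params)$scores, o)
  expect_equal(cnn_forward(cvec, dvec, params)$probs, exp(o) / sum(exp(o)))
})

test_that("softmax columns always sum to one", {
  withr::with_seed(2, {
    O <- matrix(rnorm(3 * 50, sd = 20), 3, 50)
    P <- cidrex:::.softmax_cols(O)
    expect_true(all(abs(colSums(P) - 1) < 1e-9))
    expect_true(all(P >= 0))
  })
})

test_that("loss at zero parameters is ln(2) and batches average", {
  gen <- small_world(n_docs = 4, seed = 3)
  hyper <- tiny_hyper()
  intra <- dplyr::filter(gen$instances, level == "intra")
  tab <- embedding_table(unique(c(gen$parses$form, gen$parses$deprel)),
                         hyper$d0, seed = 1)
  feats <- cnn_featurise(intra, gen$parses, tab$vocab, hyper)
  zero_params <- cnn_init(tab, hyper, seed = 1)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    zero_params[[nm]][] <- 0
  }
  zero_params$T[] <- 0
  hyper0 <- tiny_hyper(lambda = 0)
  lg <- cnn_loss_gradients(feats[1], zero_params, hyper0)
  expect_equal(lg$loss, log(2))
  # duplicating an instance leaves the mean loss unchanged
  withr::with_seed(1, {
    params <- cnn_init(tab, hyper0, seed = 5)
    l1 <- cnn_loss_gradients(feats[2], params, hyper0)$loss
    l2 <- cnn_loss_gradients(feats[c(2, 2)], params, hyper0)$loss
  })
  expect_equal(l1, l2)
})

test_that("analytic gradients match central finite differences", {
  gen <- small_world(n_docs = 3, seed = 3)
  hyper <- tiny_hyper(lambda = 1e-3)
  intra <- dplyr::filter(gen$instances, level == "intra")
  tab <- embedding_table(unique(c(gen$parses$form, gen$parses$deprel)),
                         hyper$d0, seed = 4)
  feats <- cnn_featurise(intra, gen$parses, tab$vocab, hyper)
  params <- cnn_init(tab, hyper, seed = 6)
  lg <- cnn_loss_gradients(feats, params, hyper)
  eps <- 1e-5
  withr::with_seed(8, {
    for (nm in names(params)) {
      idx <- seq_along(params[[nm]])
      if (nm == "T") idx <- setdiff(idx, seq_len(hyper$d0)) # frozen <PAD> col
      idx <- sample(idx, min(25, length(idx)))
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (cnn_loss_gradients(feats, p1, hyper)$loss -
                  cnn_loss_gradients(feats, p2, hyper)$loss) / (2 * eps)
        ana <- lg$grads[[nm]][i]
        if (abs(num) < 1e-10 && abs(ana) < 1e-10) next
        expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4)
      }
    }
  })
})

test_that("dropout masks zero roughly p_drop of the hidden units", {
  withr::with_seed(31, {
    draws <- rbinom(1e5, 1, 1 - 0.3)
    frac <- mean(draws == 0)
  })
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(frac - 0.3), 3 * se)
  # the training loss actually consumes a dropout mask (stochastic loss)
  gen <- small_world(n_docs = 3, seed = 3)
  hyper <- tiny_hyper(p_drop = 0.5)
  intra <- dplyr::filter(gen$instances, level == "intra")
  tab <- embedding_table(unique(c(gen$parses$form, gen$parses$deprel)),
                         hyper$d0, seed = 4)
  feats <- cnn_featurise(intra, gen$parses, tab$vocab, hyper)
  params <- cnn_init(tab, hyper, seed = 6)
  l <- withr::with_seed(1, cnn_loss_gradients(feats, params, hyper)$loss)
  l2 <- withr::with_seed(2, cnn_loss_gradients(feats, params, hyper)$loss)
  expect_false(identical(l, l2))
})

test_that("training is deterministic given the seed and 0 epochs returns the init", {
  gen <- small_world(n_docs = 6, seed = 17)
  hyper <- tiny_hyper(epochs = 2, p_drop = 0.3)
  intra <- dplyr::filter(gen$instances, level == "intra")
  m1 <- cnn_train(intra, gen$parses, hyper, seed = 11)
  m2 <- cnn_train(intra, gen$parses, hyper, seed = 11)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$trace, m2$trace)
  m3 <- cnn_train(intra, gen$parses, hyper, seed = 12)
  expect_false(identical(m1$params, m3$params))

  h0 <- tiny_hyper(epochs = 0)
  m0 <- cnn_train(intra, gen$parses, h0, seed = 11)
  tab <- embedding_table(unique(c(gen$parses$form, gen$parses$lemma,
                                  gen$parses$deprel)), h0$d0, seed = 11)
  expect_identical(m0$params[-1], cnn_init(tab, h0, seed = 11)[-1])
  expect_identical(m0$params$T, tab$T)
})

test_that("training requires both classes and flags divergence-free traces", {
  gen <- small_world(n_docs = 4, seed = 5)
  intra <- dplyr::filter(gen$instances, level == "intra")
  only_pos <- dplyr::mutate(intra, label = "positive")
  expect_error(cnn_train(only_pos, gen$parses, tiny_hyper(), seed = 1),
               "positive and.*negative")
  m <- cnn_train(intra, gen$parses, tiny_hyper(epochs = 3), seed = 1)
  expect_true(all(is.finite(m$trace$loss)))
})

test_that("mean epoch loss is non-increasing early in training on the planted corpus", {
  gen <- small_world(n_docs = 30, seed = 29)
  intra <- dplyr::filter(gen$instances, level == "intra")
  hyper <- cnn_hyper(d0 = 16, n1 = 10, n2 = 20, L_max = 12, epochs = 5)
  m <- cnn_train(intra, gen$parses, hyper, seed = 7)
  expect_true(all(diff(m$trace$loss) <= 1e-8))
})

test_that("prediction is deterministic, duplicates agree, and ties break negative", {
  gen <- small_world(n_docs = 6, seed = 19)
  intra <- dplyr::filter(gen$instances, level == "intra")
  m <- cnn_train(intra, gen$parses, tiny_hyper(epochs = 2), seed = 3)
  p1 <- cnn_predict(m, intra, gen$parses)
  p2 <- cnn_predict(m, intra[c(1, 1), ], gen$parses)
  expect_identical(p2$pred_label[1], p2$pred_label[2])
  expect_identical(p1[1, ], p2[1, ])
  # zeroed-out model scores 0.5/0.5: tie goes to negative
  m0 <- m
  for (nm in names(m0$params)) m0$params[[nm]][] <- 0
  p0 <- cnn_predict(m0, intra, gen$parses)
  expect_true(all(p0$pred_label == "negative"))
  expect_true(all(p0$confidence == 0.5))
})

test_that("a linearly separable trigger rule is learned to high accuracy", {
  gen <- small_world(n_docs = 60, seed = 47)
  test <- small_world(n_docs = 25, seed = 48)
  # small corpora see few mini-batches per epoch, so the AdaGrad schedule
  # needs more epochs here than at full corpus scale
  hyper <- cnn_hyper(d0 = 24, n1 = 16, n2 = 32, L_max = 12, epochs = 100)
  intra <- dplyr::filter(gen$instances, level == "intra")
  m <- cnn_train(intra, gen$parses, hyper, seed = 9)
  train_pred <- cnn_predict(m, intra, gen$parses)
  expect_gte(mean(train_pred$pred_label == train_pred$label), 0.98)
  te <- dplyr::filter(test$instances, level == "intra")
  te_pred <- cnn_predict(m, te, test$parses)
  tp <- sum(te_pred$pred_label == "positive" & te_pred$label == "positive")
  prec <- tp / sum(te_pred$pred_label == "positive")
  rec <- tp / sum(te_pred$label == "positive")
  expect_gte(2 * prec * rec / (prec + rec), 0.95)
})

test_that("per-path pooling changes the feature dimension consistently", {
  gen <- small_world(n_docs = 4, seed = 3)
  hyper <- tiny_hyper(pool_per_path = TRUE)
  intra <- dplyr::filter(gen$instances, level == "intra")
  m <- cnn_train(intra, gen$parses, hyper, seed = 2)
  expect_equal(nrow(m$params$W2),
               hyper$n2)
  expect_equal(ncol(m$params$W2),
               hyper$d0 * (2 + 2 * (hyper$w - 1) + hyper$V_max) + 3 * hyper$n1)
  p <- cnn_predict(m, intra, gen$parses)
  expect_equal(nrow(p), nrow(intra))
})
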
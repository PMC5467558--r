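# Shared fixtures, built in code.

# Dependency tree of "The dipyridamole induced his hyperemia ." with
# dipyridamole <- nsubj <- induced -> dobj -> hyperemia.
fig_tree <- function() {
  tibble::tibble(
    index = 1:6,
    form = c("The", "dipyridamole", "induced", "his", "hyperemia", "."),
    lemma = c("the", "dipyridamole", "induce", "his", "hyperemia", "."),
    pos = c("DT", "NN", "VBD", "PRP$", "NN", "."),
    head = c(2L, 3L, 0L, 5L, 3L, 3L),
    deprel = c("det", "nsubj", "root", "poss", "dobj", "punct")
  )
}

# One-document PubTator block with an intra pair, an extra disease in a later
# sentence, and one gold relation.
tiny_pubtator <- function() {
  c(
    "900|t|The aspirin induced the headache .",
    "900|a|The aspirin was administered . The nausea was observed .",
    "900\t4\t11\taspirin\tChemical\tD001241",
    "900\t24\t32\theadache\tDisease\tD006261",
    "900\t39\t46\taspirin\tChemical\tD001241",
    "900\t70\t76\tnausea\tDisease\tD009325",
    "900\tCID\tD001241\tD006261",
    ""
  )
}

tiny_parses <- function() {
  c(
    "#900\t0",
    "1\tThe\tthe\tDT\t2\tdet\t0\t3",
    "2\taspirin\taspirin\tNN\t3\tnsubj\t4\t11",
    "3\tinduced\tinduce\tVBD\t0\troot\t12\t19",
    "4\tthe\tthe\tDT\t5\tdet\t20\t23",
    "5\theadache\theadache\tNN\t3\tdobj\t24\t32",
    "6\t.\t.\t.\t3\tpunct\t33\t34",
    "#900\t1",
    "1\tThe\tthe\tDT\t2\tdet\t35\t38",
    "2\taspirin\taspirin\tNN\t4\tnsubjpass\t39\t46",
    "3\twas\tbe\tVBD\t4\tauxpass\t47\t50",
    "4\tadministered\tadminister\tVBN\t0\troot\t51\t63",
    "5\t.\t.\t.\t4\tpunct\t64\t65",
    "#900\t2",
    "1\tThe\tthe\tDT\t2\tdet\t66\t69",
    "2\tnausea\tnausea\tNN\t4\tnsubjpass\t70\t76",
    "3\twas\tbe\tVBD\t4\tauxpass\t77\t80",
    "4\tobserved\tobserve\tVBN\t0\troot\t81\t89",
    "5\t.\t.\t.\t4\tpunct\t90\t91"
  )
}

# Random toy ontology: n concepts with 1-2 tree numbers drawn from a random
# rooted hierarchy.
random_toy_ontology <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    numbers <- character(n)
    for (i in seq_len(n)) {
      if (i <= 3) {
        numbers[i] <- paste0("C", sprintf("%02d", i))
      } else {
        parent <- sample.int(i - 1, 1)
        numbers[i] <- paste0(numbers[parent], ".", sprintf("%03d", i))
      }
    }
    ids <- sprintf("D%03d", seq_len(n))
    extra <- sample.int(n, n %/% 3)
    tn <- lapply(seq_len(n), function(i) {
      out <- numbers[i]
      if (i %in% extra) out <- c(out, paste0("Z01.", sprintf("%03d", i)))
      out
    })
    new_mesh_ontology(stats::setNames(tn, ids))
  })
}

# Brute-force hypernymy: enumerate all tree-number pairs and test the
# proper segment-prefix relation by splitting on dots.
brute_hypernym <- function(ontology, a, b) {
  ta <- ontology[[a]]
  tb <- ontology[[b]]
  if (is.null(ta) || is.null(tb)) return(FALSE)
  for (x in ta) {
    sx <- strsplit(x, ".", fixed = TRUE)[[1]]
    for (y in tb) {
      sy <- strsplit(y, ".", fixed = TRUE)[[1]]
      if (length(sx) < length(sy) && identical(sy[seq_along(sx)], sx)) return(TRUE)
    }
  }
  FALSE
}

# Tiny hyperparameter set for fast CNN tests.
tiny_hyper <- function(...) {
  args <- list(d0 = 4, n1 = 3, n2 = 5, n3 = 2, w = 3, v = 3, V_max = 2,
               L_max = 6, lambda = 1e-3, p_drop = 0, batch = 8, epochs = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cnn_hyper, args)
}

# Small labeled synthetic world for model tests.
small_world <- function(n_docs = 10, noise_rate = 0, seed = 42, ...) {
  gen <- generate_corpus(synth_config(n_docs = n_docs, noise_rate = noise_rate,
                                      seed = seed, ...))
  gen$instances <- label_instances(build_instances(gen$corpus, gen$parses),
                                   gen$corpus$relations)
  gen
}

# naive loop implementation of convolution + masked max pooling + tanh,
# used as the independent oracle for conv_pool
naive_conv_pool <- function(X0, W1, b1, mask) {
  n1 <- nrow(W1)
  Z <- matrix(0, n1, ncol(X0))
  for (i in seq_len(n1)) {
    for (j in seq_len(ncol(X0))) {
      Z[i, j] <- sum(W1[i, ] * X0[, j]) + b1[i]
    }
  }
  d <- numeric(n1)
  for (i in seq_len(n1)) {
    d[i] <- tanh(max(Z[i, !mask]))
  }
  d
}
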
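#' Extract sparse features for inter-sentence instances
#'
#' Deterministic template expansion over an inter-level instance's two host
#' sentences: chemical/disease surface form and head lemma; side-prefixed
#' bags of lemmas of the chemical and disease sentences; the sentence
#' distance bucket (`1`, `2`, `3+`); chemical-in-title and disease-in-title
#' flags (a mention is "in the title" when its character span lies inside
#' the title segment, i.e. sentence 0 of the parse); per-document mention
#' count buckets for each concept (`1`, `2`, `3+`); whether either mention
#' sits in the title sentence; and a bag of verbs (POS `VB*`) from both
#' sentences.
#'
#' @param instances Inter-level instance tibble from [build_instances()].
#' @param corpus The `cdr_corpus` the instances came from.
#' @param parses Token tibble from [read_parses()].
#' @return A list of character vectors, one per instance, each the set of
#'   active feature names.
#' @export
extract_inter_features <- function(instances, corpus, parses) {
  stopifnot(all(instances$level == "inter"))
  sent_split <- split(parses, paste(parses$doc_id, parses$sentence_index, sep = "\r"))
  sent_split <- lapply(sent_split, function(p) p[order(p$index), ])
  # mention counts per (doc, concept id): a mention with several ids counts
  # once toward each
  counts <- corpus$mentions |>
    mutate(cid = .data$concept_ids) |>
    tidyr::unnest_longer("cid") |>
    count(.data$doc_id, .data$cid, name = "n_mentions")
  count_of <- setNames(counts$n_mentions, paste(counts$doc_id, counts$cid))
  bucket <- function(n) if (n >= 3) "3+" else as.character(n)

  map(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    cs <- sent_split[[paste(inst$doc_id, inst$chem_sent, sep = "\r")]]
    ds <- sent_split[[paste(inst$doc_id, inst$dis_sent, sep = "\r")]]
    if (is.null(cs) || is.null(ds)) {
      abort(sprintf("no parse for a sentence of doc %s", inst$doc_id))
    }
    head_lemma <- function(sent, tok) sent$lemma[match(tok, sent$index)]
    title_end <- nchar(corpus$documents$title[
      match(inst$doc_id, corpus$documents$doc_id)])
    feats <- c(
      paste0("chem_surf=", tolower(inst$chem_text)),
      paste0("dis_surf=", tolower(inst$dis_text)),
      paste0("chem_lemma=", head_lemma(cs, inst$chem_head_tok)),
      paste0("dis_lemma=", head_lemma(ds, inst$dis_head_tok)),
      paste0("cs_lemma=", unique(cs$lemma)),
      paste0("ds_lemma=", unique(ds$lemma)),
      paste0("dist=", bucket(inst$sentence_gap)),
      paste0("chem_count=", bucket(count_of[[paste(inst$doc_id, inst$chem_id)]] %||% 1L)),
      paste0("dis_count=", bucket(count_of[[paste(inst$doc_id, inst$dis_id)]] %||% 1L)),
      paste0("verb=", unique(c(cs$lemma[startsWith(cs$pos, "VB")],
                               ds$lemma[startsWith(ds$pos, "VB")])))
    )
    if (inst$chem_end <= title_end) feats <- c(feats, "chem_in_title")
    if (inst$dis_end <= title_end) feats <- c(feats, "dis_in_title")
    if (inst$chem_sent == 0L || inst$dis_sent == 0L) feats <- c(feats, "pair_in_title")
    sort(unique(feats))
  })
}

#' Train the inter-sentence maximum-entropy classifier
#'
#' Binary L2-penalized logistic regression over the sparse feature sets:
#' minimizes the mean negative log-likelihood plus `l2 * ||w||^2` (the bias
#' is unpenalized) with BFGS and an analytic gradient. The problem is
#' convex, so the fit is deterministic given the data. The feature
#' dictionary is grown on the training set and frozen afterwards; unseen
#' test features are dropped.
#'
#' @param features List of per-instance feature-name vectors from
#'   [extract_inter_features()].
#' @param labels Character vector (`"positive"`/`"negative"`) aligned with
#'   `features`.
#' @param l2 L2 penalty strength.
#' @param tol Gradient-norm convergence target.
#' @return A `cdr_maxent` object: feature dictionary, weights, bias.
#' @export
train_maxent <- function(features, labels, l2 = 0.003, tol = 1e-6) {
  y <- labels == "positive"
  if (length(unique(y)) < 2) {
    abort("maxent training needs both a positive and a negative instance")
  }
  dict <- sort(unique(unlist(features)))
  X <- .feature_matrix(features, dict)
  n <- length(y); p <- length(dict)
  log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  objective <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    eta <- as.vector(X %*% w) + b
    -mean(y * eta - log1pexp(eta)) + l2 * sum(w^2)
  }
  gradient <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    mu <- plogis(as.vector(X %*% w) + b)
    resid <- mu - y
    c(as.vector(crossprod(X, resid)) / n + 2 * l2 * w, mean(resid))
  }
  fit <- optim(numeric(p + 1), objective, gradient, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  # BFGS can stall short of the target; polish with a few more restarts
  for (k in seq_len(5)) {
    if (sqrt(sum(gradient(fit$par)^2)) <= tol) break
    fit <- optim(fit$par, objective, gradient, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
  }
  structure(list(dict = dict, w = fit$par[seq_len(p)], b = fit$par[p + 1],
                 l2 = l2, n_train = n,
                 grad_norm = sqrt(sum(gradient(fit$par)^2)),
                 loglik = -objective(fit$par) * n + l2 * sum(fit$par[seq_len(p)]^2) * n),
            class = "cdr_maxent")
}

.feature_matrix <- function(features, dict) {
  ij <- imap(features, function(f, i) {
    j <- match(intersect(f, dict), dict)
    cbind(rep(as.integer(i), length(j)), j)
  })
  ij <- do.call(rbind, ij)
  X <- matrix(0, length(features), length(dict))
  if (!is.null(ij) && nrow(ij) > 0) X[ij] <- 1
  X
}

#' Predict with the maximum-entropy classifier
#'
#' Sigmoid of the linear score over the frozen dictionary; features unseen
#' in training are dropped. The label is positive iff the probability
#' exceeds 0.5 (a tie goes to negative).
#'
#' @param model A `cdr_maxent`.
#' @param features List of per-instance feature-name vectors.
#' @return A tibble with `pred_label` and `confidence` (probability of the
#'   predicted label), one row per instance.
#' @export
predict_maxent <- function(model, features) {
  if (length(features) == 0) {
    return(tibble(pred_label = character(), confidence = numeric()))
  }
  X <- .feature_matrix(features, model$dict)
  prob <- plogis(as.vector(X %*% model$w) + model$b)
  tibble(pred_label = ifelse(prob > 0.5, "positive", "negative"),
         confidence = ifelse(prob > 0.5, prob, 1 - prob))
}

#' @export
print.cdr_maxent <- function(x, ...) {
  cat(sprintf("<cdr_maxent> %d features, l2=%g, trained on %d instances (|grad|=%.2g)\n",
              length(x$dict), x$l2, x$n_train, x$grad_norm))
  invisible(x)
}

#' @describeIn train_maxent Feature weights as a tibble, sorted by magnitude.
#' @param x A `cdr_maxent`.
#' @param ... Unused.
#' @method tidy cdr_maxent
#' @export
tidy.cdr_maxent <- function(x, ...) {
  tibble(feature = c(x$dict, "(bias)"), weight = c(x$w, x$b)) |>
    arrange(dplyr::desc(abs(.data$weight)))
}

#' @describeIn train_maxent One-row fit summary.
#' @method glance cdr_maxent
#' @export
glance.cdr_maxent <- function(x, ...) {
  tibble(n_features = length(x$dict), l2 = x$l2, n_train = x$n_train,
         grad_norm = x$grad_norm, loglik = x$loglik)
}
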
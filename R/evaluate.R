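#' Micro-averaged precision, recall and F-score over document-level pairs
#'
#' Counts true/false positives and false negatives over
#' `(doc_id, chem_id, dis_id)` triples, micro-averaged across the whole
#' prediction and gold sets (documents present in only one side simply
#' contribute false positives or negatives). Undefined ratios (no
#' predictions, or no gold) are reported as 0 with the `undefined` flag set,
#' never as `NaN`.
#'
#' @param predictions Tibble (`doc_id`, `chem_id`, `dis_id`); duplicates are
#'   collapsed.
#' @param gold Tibble of gold pairs in the same shape.
#' @return A `cdr_eval` object: counts, metrics, an `undefined` flag and a
#'   per-document breakdown tibble.
#' @export
evaluate_relations <- function(predictions, gold) {
  pred <- distinct(predictions, .data$doc_id, .data$chem_id, .data$dis_id)
  gold <- distinct(gold, .data$doc_id, .data$chem_id, .data$dis_id)
  tp_rows <- semi_join(pred, gold, by = c("doc_id", "chem_id", "dis_id"))
  tp <- nrow(tp_rows)
  fp <- nrow(pred) - tp
  fn <- nrow(gold) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  per_doc <- dplyr::full_join(
    count(pred, .data$doc_id, name = "n_pred"),
    count(gold, .data$doc_id, name = "n_gold"),
    by = "doc_id"
  ) |>
    left_join(count(tp_rows, .data$doc_id, name = "tp"), by = "doc_id") |>
    mutate(across(c("n_pred", "n_gold", "tp"), ~ tidyr::replace_na(.x, 0L)),
           fp = .data$n_pred - .data$tp, fn = .data$n_gold - .data$tp) |>
    arrange(.data$doc_id)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1,
                 undefined = (tp + fp == 0) || (tp + fn == 0),
                 per_doc = per_doc),
            class = "cdr_eval")
}

#' @export
print.cdr_eval <- function(x, ...) {
  cat("Document-level CID evaluation (micro-averaged)\n")
  cat(sprintf("  tp %d  fp %d  fn %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  P %.4f  R %.4f  F %.4f%s\n", x$precision, x$recall, x$f1,
              if (x$undefined) "  (undefined ratios reported as 0)" else ""))
  invisible(x)
}

#' @describeIn evaluate_relations Per-document breakdown tibble.
#' @param x A `cdr_eval`.
#' @param ... Unused.
#' @method tidy cdr_eval
#' @export
tidy.cdr_eval <- function(x, ...) x$per_doc

#' @describeIn evaluate_relations One-row summary of counts and metrics.
#' @method glance cdr_eval
#' @export
glance.cdr_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
         recall = x$recall, f1 = x$f1, undefined = x$undefined)
}

#' Write an evaluation report as a machine-readable key-value file
#'
#' @param report A `cdr_eval`.
#' @param path Output path, or `NULL` to return lines.
#' @return Lines, invisibly.
#' @export
write_eval_report <- function(report, path = NULL) {
  g <- glance(report)
  out <- sprintf("%s\t%s", names(g), unlist(lapply(g, format, digits = 15)))
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' @describeIn evaluate_relations Bar chart of precision, recall and F.
#' @param object A `cdr_eval`.
#' @method autoplot cdr_eval
#' @export
autoplot.cdr_eval <- function(object, ...) {
  df <- tibble(metric = factor(c("precision", "recall", "F1"),
                               levels = c("precision", "recall", "F1")),
               value = c(object$precision, object$recall, object$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL, title = "Document-level CID extraction")
}
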
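# Evaluation module: top-k metrics, confusion matrix, ranking
# distribution, query-size sensitivity.

#' Top-k diagnostic metrics
#'
#' Each evaluated record is exactly one of: a true positive when the model
#' made a prediction and the true disease appears among the k
#' highest-ranked candidates; a false positive when the model predicted
#' but the truth is absent from the top k; a false negative when the model
#' abstained (no candidate received a positive combined score).
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 is their
#' harmonic mean (0 when both are 0).
#'
#' @param results list of `phenodx_ranking`
#' @param truths character vector of true disease ids, one per result
#' @param k ranking cutoff (>= 1)
#' @return object of class `phenodx_topk`: list with `k`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`
#' @export
evaluate_topk <- function(results, truths, k = 10L) {
  if (!length(results)) stop_input("no results to evaluate")
  if (length(results) != length(truths)) {
    stop_input("results and truths must have the same length")
  }
  if (k < 1L) stop_input("k must be >= 1")
  tp <- fp <- fn <- 0L
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (abstained(r)) { fn <- fn + 1L; next }
    topk <- utils::head(r$items$disease_id, k)
    if (truths[i] %in% topk) tp <- tp + 1L else fp <- fp + 1L
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(k = as.integer(k), tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1),
            class = "phenodx_topk")
}

# a model abstains when no candidate carries a positive score
abstained <- function(result) {
  nrow(result$items) == 0L || max(result$items$score) <= 0
}

#' @export
print.phenodx_topk <- function(x, ...) {
  cat(sprintf("top-%d: TP=%d FP=%d FN=%d  precision=%.4f recall=%.4f f1=%.4f\n",
              x$k, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Top-k confusion matrix
#'
#' A record whose truth appears in the top k counts on the diagonal
#' (truth, truth); otherwise it counts at (truth, top-1 prediction).
#' Abstentions are tallied in a dedicated `<abstain>` column. The grand
#' total always equals the number of evaluated records.
#'
#' @inheritParams evaluate_topk
#' @return object of class `phenodx_confusion`: integer matrix (rows =
#'   true disease, columns = predicted disease plus `<abstain>`)
#' @export
confusion_topk <- function(results, truths, k = 10L) {
  if (!length(results)) stop_input("no results to evaluate")
  preds <- character(length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    preds[i] <- if (abstained(r)) "<abstain>"
      else if (truths[i] %in% utils::head(r$items$disease_id, k)) truths[i]
      else r$items$disease_id[1]
  }
  rows <- sort_c(unique(truths))
  cols <- c(sort_c(unique(c(truths, setdiff(preds, "<abstain>")))), "<abstain>")
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(results)) {
    m[truths[i], preds[i]] <- m[truths[i], preds[i]] + 1L
  }
  structure(m, class = c("phenodx_confusion", "matrix", "array"))
}

#' Ranking distribution of the true disease
#'
#' Bins the rank of the true disease per record. `top10` is cumulative
#' (it includes `top1`), matching the convention "ranked as top 10"; the
#' exclusive partition `top10 + other + unranked` sums to 1. Records
#' whose truth is absent from the candidate list, or where the model
#' abstained, count as `unranked`.
#'
#' @inheritParams evaluate_topk
#' @return list with fractions `top1`, `top10`, `other`, `unranked`
#' @export
ranking_distribution <- function(results, truths) {
  if (!length(results)) stop_input("no results to evaluate")
  ranks <- vapply(seq_along(results), function(i) {
    if (abstained(results[[i]])) NA_integer_
    else truth_rank(results[[i]], truths[i])
  }, 0L)
  n <- length(ranks)
  list(top1 = sum(!is.na(ranks) & ranks == 1L) / n,
       top10 = sum(!is.na(ranks) & ranks <= 10L) / n,
       other = sum(!is.na(ranks) & ranks > 10L) / n,
       unranked = sum(is.na(ranks)) / n)
}

#' Metric sensitivity to the number of query terms
#'
#' For each requested query size s, every record's phenotype list is
#' subsampled without replacement to `min(s, available)` terms (seeded),
#' re-ranked through the supplied model function and scored at k.
#'
#' @param model_fn function(character term vector) -> `phenodx_ranking`;
#'   with `batch = TRUE`, function(list of term vectors) -> list of
#'   rankings (lets ensemble models predict a whole cohort in one pass)
#' @param cohort list of `phenodx_patient` with `true_disease` labels
#' @param sizes positive integer query sizes
#' @param k ranking cutoff
#' @param seed integer seed for the subsampling
#' @param batch does `model_fn` take a list of queries at once?
#' @return named list size -> `phenodx_topk`
#' @export
sensitivity_by_query_size <- function(model_fn, cohort, sizes, k = 10L,
                                      seed = 1L, batch = FALSE) {
  if (any(sizes < 1L)) stop_input("sizes must be positive")
  truths <- vapply(cohort, function(p) p$true_disease, "")
  out <- vector("list", length(sizes))
  names(out) <- as.character(sizes)
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    queries <- with_seed(derive_seed(seed, c("qsize", s)), {
      lapply(cohort, function(p) {
        ph <- p$phenotypes
        if (length(ph) <= s) ph else sample(ph, s)
      })
    })
    results <- if (batch) model_fn(queries) else lapply(queries, model_fn)
    out[[si]] <- evaluate_topk(results, truths, k)
  }
  out
}

#' Write evaluation artifacts
#'
#' Metrics and ranking distributions serialize as JSON; the confusion
#' matrix as a TSV grid with the true disease in the first column.
#' @param x a `phenodx_topk`, `phenodx_confusion`, or ranking distribution
#' @param path output file
#' @export
write_metrics <- function(x, path) {
  if (inherits(x, "phenodx_confusion")) {
    df <- data.frame(true_disease = rownames(x),
                     unclass(as.data.frame.matrix(unclass(x))),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
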
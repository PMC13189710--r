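# Evaluation metrics: Pearson r over test records, mean within-list
# Spearman over test response lists, and NDCG@k.

#' Normalized discounted cumulative gain at rank k
#'
#' Relevance grades are the within-list min-max-normalized true values with
#' the DCG-style exponential gain `2^g - 1`; discount `1/log2(rank + 1)`.
#'
#' @param s_true true values of one list.
#' @param s_pred predicted values (define the ranking).
#' @param k cutoff (truncated to the list length).
#' @return NDCG in \[0, 1\], or `NA` for a fully tied truth list.
#' @export
ndcg_at_k <- function(s_true, s_pred, k = 10) {
  n <- length(s_true)
  k <- min(k, n)
  g <- 2^normalize_list_scores(s_true) - 1
  disc <- 1 / log2(seq_len(k) + 1)
  ord <- order(-s_pred)
  dcg <- sum(g[ord[seq_len(k)]] * disc)
  idcg <- sum(sort(g, decreasing = TRUE)[seq_len(k)] * disc)
  if (idcg == 0) NA_real_ else dcg / idcg
}

#' Evaluate a model on the test side of a scenario split
#'
#' Pearson r is computed between predicted and true responses over all test
#' records (on the raw response scale); the within-list Spearman is averaged
#' over test lists with at least two entries and a non-constant truth, and
#' NDCG@k likewise. A constant prediction vector makes the correlation
#' undefined; it is reported as 0 with the `degenerate` flag set.
#'
#' @param model a `synergy_model` or [oracle_model()].
#' @param dataset a `synergy_dataset`.
#' @param split a `scenario_split`; metrics use `split$test_idx` only.
#' @param k NDCG cutoff (default 10).
#' @param md optional precomputed [prepare_model_data()] result.
#' @return an `eval_report`: `pearson_r`, `within_list_spearman`,
#'   `ndcg_at_k`, `n_test`, `n_lists`, `n_degenerate_lists`, `degenerate`.
#' @export
evaluate_model <- function(model, dataset, split, k = 10, md = NULL) {
  rows <- split$test_idx
  assert_that(length(rows) > 0, "test set is empty", "data_error")
  pred <- predict_responses(model, dataset, rows = rows, md = md)
  truth <- dataset$measurements$response[rows]
  degenerate <- stats::sd(pred) == 0 || stats::sd(truth) == 0
  pearson <- if (degenerate) 0 else stats::cor(pred, truth)
  test_m <- dataset$measurements[rows, , drop = FALSE]
  lists <- group_into_lists(test_m)
  sp <- nd <- numeric(0)
  n_degenerate_lists <- 0L
  for (rl in lists) {
    if (rl$n < 2) next
    st <- truth[rl$idx]
    sp_pred <- pred[rl$idx]
    if (length(unique(st)) < 2) next
    if (stats::sd(sp_pred) == 0) {
      sp <- c(sp, 0)
      n_degenerate_lists <- n_degenerate_lists + 1L
    } else {
      sp <- c(sp, stats::cor(st, sp_pred, method = "spearman"))
    }
    nd <- c(nd, ndcg_at_k(st, sp_pred, k))
  }
  structure(list(
    pearson_r = pearson,
    within_list_spearman = if (length(sp)) mean(sp) else NA_real_,
    ndcg_at_k = if (length(nd)) mean(nd, na.rm = TRUE) else NA_real_,
    k = k,
    n_test = length(rows),
    n_lists = length(sp),
    n_degenerate_lists = n_degenerate_lists,
    degenerate = degenerate
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n_test=%d lists=%d\n",
                     "  pearson_r            %.4f%s\n",
                     "  within-list spearman %.4f\n",
                     "  ndcg@%-2d              %.4f\n"),
              x$n_test, x$n_lists, x$pearson_r,
              if (x$degenerate) " (degenerate: constant vector)" else "",
              x$within_list_spearman, x$k, x$ndcg_at_k))
  invisible(x)
}

#' Aggregate per-fold evaluation reports into mean +/- sd rows
#'
#' @param reports list of `eval_report` objects (one per fold).
#' @return data.frame with one row per metric: mean, sd, per-fold values.
#' @export
aggregate_eval <- function(reports) {
  metrics <- c("pearson_r", "within_list_spearman", "ndcg_at_k")
  vals <- sapply(reports, function(r) unlist(r[metrics]))
  data.frame(
    metric = metrics,
    mean = rowMeans(vals),
    sd = apply(vals, 1, stats::sd),
    row.names = NULL
  )
}

#' Ground-truth oracle pseudo-model
#'
#' Wraps a record-id to noise-free-response lookup (the generator's ground
#' truth sidecar) as a model, so evaluation plumbing can be verified: the
#' oracle recovers the generator's within-list ordering exactly.
#'
#' @param truth data.frame with columns `record_id`, `true_response`.
#' @return an `oracle_model`.
#' @export
oracle_model <- function(truth) {
  assert_that(all(c("record_id", "true_response") %in% names(truth)),
              "truth must have record_id and true_response columns")
  structure(list(lookup = stats::setNames(truth$true_response,
                                          truth$record_id)),
            class = "oracle_model")
}

#' @export
predict_responses.oracle_model <- function(model, dataset, rows = NULL,
                                           md = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(dataset$measurements))
  ids <- dataset$measurements$record_id[rows]
  out <- unname(model$lookup[ids])
  assert_that(!anyNA(out), "oracle is missing record ids", "data_error")
  out
}
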
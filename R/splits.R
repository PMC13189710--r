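# Leakage-controlled train/test scenarios over five-fold cross-validation.
#
# S1: within every combination dose-response matrix, entries are randomly
#     assigned to the 5 folds, so each matrix contributes to both sides.
# S2: unordered drug pairs are partitioned into 5 groups; all matrices of a
#     held-out pair, across all cell lines, are test.
# S3: S2's partition, with every monotherapy record additionally dropped
#     from the training side.
# Fold assignments depend only on (dataset, scenario family, seed), so the
# five folds' test sets partition the eligible combination records.

#' Build one fold of a scenario split
#'
#' @param dataset a `synergy_dataset`.
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param fold fold index in `0:(n_folds-1)`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the same seed yields the same fold assignment
#'   for every fold so the test sets are disjoint and covering.
#' @return a `scenario_split` with integer `train_idx`/`test_idx` into
#'   `dataset$measurements`.
#' @export
make_split <- function(dataset, scenario, fold, n_folds = 5, seed = 1) {
  assert_that(scenario %in% c("S1", "S2", "S3"),
              paste0("unknown scenario '", scenario, "' (use S1, S2 or S3)"))
  assert_that(fold >= 0 && fold < n_folds, "fold must lie in [0, n_folds)")
  m <- dataset$measurements
  mono <- is.na(m$drug2_id)
  combo_rows <- which(!mono)
  assert_that(length(combo_rows) > 0, "dataset has no combination records",
              "data_error")
  if (scenario == "S1") {
    lists <- group_into_lists(m[combo_rows, , drop = FALSE])
    set.seed(derive_seed(seed, "S1"))
    labels <- integer(length(combo_rows))
    for (rl in lists) { # stratified within each matrix
      labels[rl$idx] <- sample(rep_len(seq_len(n_folds) - 1L, rl$n))
    }
    test <- combo_rows[labels == fold]
    train <- setdiff(seq_len(nrow(m)), test)
  } else {
    pk <- pair_key(m)
    pairs <- sort(unique(pk[combo_rows]))
    set.seed(derive_seed(seed, "S2"))
    grp <- sample(rep_len(seq_len(n_folds) - 1L, length(pairs)))
    held <- pairs[grp == fold]
    test <- combo_rows[pk[combo_rows] %in% held]
    train <- setdiff(seq_len(nrow(m)), test)
    if (scenario == "S3") train <- train[!mono[train]]
  }
  structure(list(scenario = scenario, fold = as.integer(fold),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 train_idx = train, test_idx = test),
            class = "scenario_split")
}

#' Check the contracts of a scenario split
#'
#' Verifies disjointness, pair exclusion for S2/S3, stratified coverage for
#' S1, and the absence of monotherapy training records for S3. Errors on
#' violation, otherwise returns `TRUE` invisibly.
#'
#' @param split a `scenario_split`.
#' @param dataset the dataset it was built from.
#' @export
validate_split <- function(split, dataset) {
  m <- dataset$measurements
  assert_that(length(intersect(split$train_idx, split$test_idx)) == 0,
              "train and test overlap", "validation_error")
  mono <- is.na(m$drug2_id)
  if (split$scenario %in% c("S2", "S3")) {
    pk <- pair_key(m)
    shared <- intersect(pk[split$train_idx][!mono[split$train_idx]],
                        pk[split$test_idx])
    assert_that(length(shared) == 0,
                "a drug pair appears on both sides of an S2/S3 split",
                "validation_error")
  }
  if (split$scenario == "S3") {
    assert_that(sum(mono[split$train_idx]) == 0,
                "S3 training set contains monotherapy records",
                "validation_error")
  }
  assert_that(all(!mono[split$test_idx]),
              "test set contains monotherapy records", "validation_error")
  invisible(TRUE)
}

#' Write a fold manifest (record id, fold, side) as delimited text
#' @param split a `scenario_split`.
#' @param dataset the dataset.
#' @param path output path.
#' @export
write_fold_manifest <- function(split, dataset, path) {
  ids <- dataset$measurements$record_id
  df <- rbind(
    data.frame(record_id = ids[split$train_idx], fold = split$fold,
               side = "train"),
    data.frame(record_id = ids[split$test_idx], fold = split$fold,
               side = "test")
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
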
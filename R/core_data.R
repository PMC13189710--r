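# Domain types and IO for combination-response tables, drug tables and
# expression matrices.
#
# Measurements are plain data.frames with the canonical columns
#   record_id, drug1_id, drug2_id, dose1, dose2, cell_id, response
# where drug2_id is NA and dose2 is 0 for monotherapy rows. Doses are molar
# concentrations; responses are on the percent-growth scale (100 = untreated
# growth, 0 = full inhibition, negative = killing).

MEASUREMENT_COLS <- c("drug1_id", "drug2_id", "dose1", "dose2", "cell_id", "response")

#' Column-name dialect for measurement files
#'
#' Maps the canonical column names onto the names used in a particular
#' delimited export, so that differently-labelled files (e.g. ALMANAC-style
#' exports) load without code changes.
#'
#' @param drug1_id,drug2_id,dose1,dose2,cell_id,response file column names.
#' @param record_id optional file column holding a stable row identifier;
#'   when `NULL` identifiers are generated from row numbers.
#' @param sep field separator (default comma).
#' @return a named list of class `measurement_dialect`.
#' @export
measurement_dialect <- function(drug1_id = "drug1_id", drug2_id = "drug2_id",
                                dose1 = "dose1", dose2 = "dose2",
                                cell_id = "cell_id", response = "response",
                                record_id = NULL, sep = ",") {
  structure(list(drug1_id = drug1_id, drug2_id = drug2_id, dose1 = dose1,
                 dose2 = dose2, cell_id = cell_id, response = response,
                 record_id = record_id, sep = sep),
            class = "measurement_dialect")
}

#' Read a combination-response measurement table
#'
#' One [MeasurementRecord] per row. Monotherapy rows are normalized: an
#' empty/missing second drug or a zero second dose yields `drug2_id = NA`
#' and `dose2 = 0`. Rows with a non-positive first dose, a missing cell or
#' drug id, or a non-finite response are rejected; the returned data.frame
#' carries the rejected rows (with file line numbers and reasons) in its
#' `"rejected"` attribute and a warning summarises them.
#'
#' @param path path to a delimited text file.
#' @param dialect a [measurement_dialect()].
#' @return data.frame with canonical measurement columns; attribute
#'   `"rejected"` holds a data.frame (line, reason) of dropped rows.
#' @export
read_measurements <- function(path, dialect = measurement_dialect()) {
  assert_that(file.exists(path), paste0("measurement file not found: ", path),
              "io_error")
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  for (col in MEASUREMENT_COLS) {
    file_col <- dialect[[col]]
    assert_that(file_col %in% names(raw),
                paste0("measurement file is missing mapped column '", file_col,
                       "' (canonical: ", col, ")"),
                "configuration_error")
  }
  df <- data.frame(
    drug1_id = as.character(raw[[dialect$drug1_id]]),
    drug2_id = as.character(raw[[dialect$drug2_id]]),
    dose1 = as.numeric(raw[[dialect$dose1]]),
    dose2 = as.numeric(raw[[dialect$dose2]]),
    cell_id = as.character(raw[[dialect$cell_id]]),
    response = as.numeric(raw[[dialect$response]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(dialect$record_id) && dialect$record_id %in% names(raw)) {
    df$record_id <- as.character(raw[[dialect$record_id]])
  } else {
    df$record_id <- sprintf("R%06d", seq_len(nrow(df)))
  }
  df <- df[, c("record_id", MEASUREMENT_COLS)]
  normalize_measurements(df, line_offset = 1L)
}

#' Normalize and validate canonical measurement rows
#' @noRd
normalize_measurements <- function(df, line_offset = 0L) {
  mono <- is.na(df$drug2_id) | (!is.na(df$dose2) & df$dose2 == 0)
  df$drug2_id[mono] <- NA_character_
  df$dose2[mono] <- 0
  bad_dose1 <- !is.finite(df$dose1) | df$dose1 <= 0
  bad_dose2 <- !is.finite(df$dose2) | df$dose2 < 0 |
    (!mono & df$dose2 == 0)
  bad_ids <- is.na(df$drug1_id) | is.na(df$cell_id)
  bad_resp <- !is.finite(df$response)
  bad <- bad_dose1 | bad_dose2 | bad_ids | bad_resp
  rejected <- data.frame(
    line = which(bad) + line_offset,
    reason = ifelse(bad_dose1[bad], "dose1 must be > 0",
                    ifelse(bad_ids[bad], "missing drug or cell id",
                           ifelse(bad_resp[bad], "non-finite response",
                                  "invalid dose2"))),
    stringsAsFactors = FALSE
  )
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  if (nrow(rejected) > 0) {
    warning(sprintf("%d measurement row(s) rejected (first: line %d, %s)",
                    nrow(rejected), rejected$line[1], rejected$reason[1]),
            call. = FALSE)
  }
  out
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()] under the same dialect: the round trip
#' is lossless on all canonical fields.
#'
#' @param measurements canonical measurement data.frame.
#' @param path output path.
#' @param dialect a [measurement_dialect()].
#' @export
write_measurements <- function(measurements, path,
                               dialect = measurement_dialect()) {
  out <- data.frame(
    record_id = measurements$record_id,
    measurements[, MEASUREMENT_COLS],
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- c(dialect$record_id %||% "record_id",
                  vapply(MEASUREMENT_COLS, function(c) dialect[[c]], ""))
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a drug table (drug id to SMILES)
#'
#' @param path delimited file with columns `drug_id` and `smiles`.
#' @param sep field separator.
#' @return data.frame with unique `drug_id` and non-empty `smiles`.
#' @export
read_drugs <- function(path, sep = ",") {
  assert_that(file.exists(path), paste0("drug table not found: ", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  assert_that(all(c("drug_id", "smiles") %in% names(df)),
              "drug table must have columns drug_id and smiles",
              "configuration_error")
  df$drug_id <- as.character(df$drug_id)
  df$smiles <- as.character(df$smiles)
  assert_that(!anyDuplicated(df$drug_id), "duplicate drug_id in drug table",
              "validation_error")
  assert_that(all(nzchar(df$smiles) & !is.na(df$smiles)),
              "empty SMILES in drug table", "validation_error")
  df[, c("drug_id", "smiles")]
}

#' Write a drug table
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_drugs <- function(drugs, path, sep = ",") {
  utils::write.table(drugs[, c("drug_id", "smiles")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-expression matrix (genes x cell lines)
#'
#' First column = gene id, remaining columns = cell lines. Any missing
#' value is an error: expression must be complete after loading.
#'
#' @param path delimited file.
#' @param sep field separator.
#' @return numeric matrix, genes in rows (rownames = gene ids), cell lines
#'   in columns.
#' @export
read_expression <- function(path, sep = ",") {
  assert_that(file.exists(path), paste0("expression file not found: ", path),
              "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  assert_that(!anyNA(m), "expression matrix contains missing values",
              "validation_error")
  m
}

#' Write a gene-expression matrix
#' @param expr numeric matrix, genes x cells, with dimnames.
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(expr, path, sep = ",") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a dataset
#'
#' Checks that every measurement's drug ids and cell id resolve against the
#' drug table and the expression matrix.
#'
#' @param drugs drug table data.frame.
#' @param measurements canonical measurement data.frame.
#' @param expression genes x cells matrix.
#' @return list of class `synergy_dataset`.
#' @export
synergy_dataset <- function(drugs, measurements, expression) {
  ids <- unique(c(measurements$drug1_id,
                  measurements$drug2_id[!is.na(measurements$drug2_id)]))
  missing_drugs <- setdiff(ids, drugs$drug_id)
  assert_that(length(missing_drugs) == 0,
              paste0("measurements reference unknown drug id(s): ",
                     paste(utils::head(missing_drugs, 5), collapse = ", ")),
              "validation_error")
  missing_cells <- setdiff(unique(measurements$cell_id), colnames(expression))
  assert_that(length(missing_cells) == 0,
              paste0("measurements reference unknown cell id(s): ",
                     paste(utils::head(missing_cells, 5), collapse = ", ")),
              "validation_error")
  structure(list(drugs = drugs, measurements = measurements,
                 expression = expression),
            class = "synergy_dataset")
}

#' @export
print.synergy_dataset <- function(x, ...) {
  mono <- sum(is.na(x$measurements$drug2_id))
  cat("<synergy_dataset>\n",
      "  drugs:        ", nrow(x$drugs), "\n",
      "  cell lines:   ", ncol(x$expression), "\n",
      "  genes:        ", nrow(x$expression), "\n",
      "  measurements: ", nrow(x$measurements),
      " (", nrow(x$measurements) - mono, " combination, ", mono,
      " monotherapy)\n", sep = "")
  invisible(x)
}

#' Read a dataset directory written by [write_dataset()] or [cmd_simulate()]
#' @param dir directory containing drugs.csv, measurements.csv, expression.csv.
#' @return a `synergy_dataset`.
#' @export
read_dataset <- function(dir) {
  synergy_dataset(
    drugs = read_drugs(file.path(dir, "drugs.csv")),
    measurements = read_measurements(file.path(dir, "measurements.csv")),
    expression = read_expression(file.path(dir, "expression.csv"))
  )
}

#' Write a dataset as delimited text files
#' @param dataset a `synergy_dataset`.
#' @param dir output directory (created if absent).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_drugs(dataset$drugs, file.path(dir, "drugs.csv"))
  write_measurements(dataset$measurements, file.path(dir, "measurements.csv"))
  write_expression(dataset$expression, file.path(dir, "expression.csv"))
  invisible(dir)
}

# ---------------------------------------------------------------------------

#' Canonical (unordered pair, cell line) key for measurements
#'
#' The drug-pair key is unordered: pair (A, B) and pair (B, A) share a key,
#' which is what the leakage-controlled scenarios require. Monotherapy rows
#' key on (drug, <mono>, cell).
#' @noRd
list_key <- function(measurements) {
  d1 <- measurements$drug1_id
  d2 <- measurements$drug2_id
  lo <- ifelse(is.na(d2), d1, pmin(d1, d2))
  hi <- ifelse(is.na(d2), "<mono>", pmax(d1, d2))
  paste(lo, hi, measurements$cell_id, sep = "\r")
}

#' Unordered drug-pair key (ignoring cell line)
#' @noRd
pair_key <- function(measurements) {
  d1 <- measurements$drug1_id
  d2 <- measurements$drug2_id
  ifelse(is.na(d2), paste0(d1, "\r<mono>"),
         paste(pmin(d1, d2), pmax(d1, d2), sep = "\r"))
}

#' Group measurements into response lists
#'
#' A response list holds all measurements sharing one (unordered drug pair,
#' cell line) combination -- the unit over which the listwise ranking loss
#' operates. Monotherapy records form their own lists keyed by
#' (drug, NA, cell). Entries of records stored with the pair in swapped
#' order are reoriented (doses swapped along with the drugs) so that
#' duplicate dose coordinates are detected regardless of storage order.
#'
#' @param measurements canonical measurement data.frame.
#' @return list of `response_list` objects, each with fields `drug1_id`,
#'   `drug2_id` (NA for monotherapy), `cell_id`, `entries` (data.frame
#'   dose1, dose2, response), `idx` (row indices into `measurements`), `n`.
#' @export
group_into_lists <- function(measurements) {
  if (nrow(measurements) == 0) return(list())
  keys <- list_key(measurements)
  groups <- split(seq_len(nrow(measurements)), keys)
  groups <- groups[order(vapply(groups, min, integer(1)))] # first-seen order
  lapply(groups, function(idx) {
    sub <- measurements[idx, , drop = FALSE]
    mono <- is.na(sub$drug2_id[1]) || all(is.na(sub$drug2_id))
    if (mono) {
      d1 <- sub$drug1_id[1]; d2 <- NA_character_
      e1 <- sub$dose1; e2 <- sub$dose2
    } else {
      d1 <- min(sub$drug1_id[1], sub$drug2_id[1])
      d2 <- max(sub$drug1_id[1], sub$drug2_id[1])
      swap <- sub$drug1_id != d1
      e1 <- ifelse(swap, sub$dose2, sub$dose1)
      e2 <- ifelse(swap, sub$dose1, sub$dose2)
    }
    if (anyDuplicated(paste(e1, e2))) {
      sr_abort(paste0("duplicate (dose1, dose2) measurement within list (",
                      d1, ", ", ifelse(is.na(d2), "mono", d2), ", ",
                      sub$cell_id[1], ")"),
               "duplicate_measurement_error")
    }
    structure(list(drug1_id = d1, drug2_id = d2, cell_id = sub$cell_id[1],
                   entries = data.frame(dose1 = e1, dose2 = e2,
                                        response = sub$response),
                   idx = idx, n = length(idx)),
              class = "response_list")
  })
}

#' Select the most variable genes
#'
#' Keeps the `k` genes with the largest population variance (divide by N)
#' across cell lines, ordered by descending variance; ties are broken by
#' input row order so the selection is deterministic.
#'
#' @param expr genes x cells numeric matrix.
#' @param k number of genes to keep; must not exceed `nrow(expr)`.
#' @return the k x cells submatrix, rows in descending-variance order.
#' @export
select_variable_genes <- function(expr, k) {
  assert_that(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  assert_that(length(k) == 1 && k >= 1 && k == floor(k), "k must be a positive integer")
  assert_that(k <= nrow(expr),
              sprintf("k (%d) exceeds the number of genes (%d)", k, nrow(expr)))
  mu <- rowMeans(expr)
  v <- rowMeans(expr * expr) - mu * mu # population variance
  ord <- order(-v) # stable: ties keep input order
  expr[ord[seq_len(k)], , drop = FALSE]
}
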
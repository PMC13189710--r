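test_that("reader normalizes monotherapy rows and preserves row count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug1_id,drug2_id,dose1,dose2,cell_id,response",
               "A,B,1e-6,1e-6,X,50",
               "A,,1e-6,0,X,80",
               "B,A,1e-7,1e-6,X,42"), path)
  m <- read_measurements(path)
  expect_equal(nrow(m), 3)
  expect_equal(sum(is.na(m$drug2_id)), 1)
  expect_equal(m$dose2[is.na(m$drug2_id)], 0)
})

test_that("rows with non-positive dose1 are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug1_id,drug2_id,dose1,dose2,cell_id,response",
               "A,B,1e-6,1e-6,X,50",
               "A,B,0,1e-6,X,55",
               "A,B,1e-7,1e-6,X,60"), path)
  expect_warning(m <- read_measurements(path), "rejected")
  expect_equal(nrow(m), 2)
  rej <- attr(m, "rejected")
  expect_equal(rej$line, 3) # header is line 1
  expect_match(rej$reason, "dose1")
})

test_that("missing mapped columns raise a configuration error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug1_id,drug2_id,dose1,cell_id,response",
               "A,B,1e-6,X,50"), path)
  expect_error(read_measurements(path), "dose2",
               class = "configuration_error")
})

test_that("a custom column dialect loads ALMANAC-style headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("NSC1\tNSC2\tCONC1\tCONC2\tCELL\tPERCENTGROWTH",
               "123\t456\t1e-6\t1e-7\tMCF7\t37.5"), path)
  dia <- measurement_dialect(drug1_id = "NSC1", drug2_id = "NSC2",
                             dose1 = "CONC1", dose2 = "CONC2",
                             cell_id = "CELL", response = "PERCENTGROWTH",
                             sep = "\t")
  m <- read_measurements(path, dia)
  expect_equal(m$drug1_id, "123")
  expect_equal(m$response, 37.5)
})

test_that("write/read round trip is lossless on all fields", {
  set.seed(42)
  for (seed in c(1, 2)) {
    m <- random_measurements(seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_measurements(m, path)
    m2 <- read_measurements(path)
    expect_equal(m2$drug1_id, m$drug1_id)
    expect_equal(m2$drug2_id, m$drug2_id)
    expect_equal(m2$dose1, m$dose1)
    expect_equal(m2$dose2, m$dose2)
    expect_equal(m2$cell_id, m$cell_id)
    expect_equal(m2$response, m$response)
  }
})

test_that("grouping keys on the unordered pair and conserves records", {
  # one 3x3 matrix for pair (A, B) in one cell -> one list with n = 9
  gg <- expand.grid(dose1 = 10^c(-7, -6, -5), dose2 = 10^c(-7, -6, -5))
  m <- make_measurements(rep("A", 9), rep("B", 9), gg$dose1, gg$dose2,
                         rep("X", 9), rnorm(9))
  ll <- group_into_lists(m)
  expect_length(ll, 1)
  expect_equal(ll[[1]]$n, 9)
  # same pair in two cells -> two lists
  m2 <- m
  m2$cell_id <- rep(c("X", "Y"), length.out = 9)
  expect_length(group_into_lists(m2), 2)
  # swapped storage order joins the same list
  m3 <- m
  m3$drug1_id[5] <- "B"; m3$drug2_id[5] <- "A"
  m3$dose1[5] <- m$dose2[5]; m3$dose2[5] <- m$dose1[5]
  expect_length(group_into_lists(m3), 1)
})

test_that("grouping conserves records on random inputs", {
  for (seed in 1:5) {
    m <- random_measurements(seed)
    ll <- group_into_lists(m)
    expect_equal(sum(vapply(ll, function(x) x$n, integer(1))), nrow(m))
    expect_setequal(unlist(lapply(ll, function(x) x$idx)), seq_len(nrow(m)))
  }
})

test_that("duplicate dose coordinates within a list raise an error naming the key", {
  m <- make_measurements(c("A", "B"), c("B", "A"), c(1e-6, 1e-7),
                         c(1e-7, 1e-6), c("X", "X"), c(10, 20))
  # the two rows are the same (pair, cell) measurement after reorientation
  expect_error(group_into_lists(m), "duplicate",
               class = "duplicate_measurement_error")
})

test_that("variance gene filter matches a brute-force oracle and is idempotent", {
  # hand-built variances
  expr <- rbind(matrix(rep(c(0, 1, 2, 3, 4), each = 4) *
                         rep(c(-1, 1), 10), 5, 4, byrow = TRUE))
  expr <- outer(sqrt(0:4), c(-1, 1, -1, 1))
  rownames(expr) <- paste0("g", 1:5)
  colnames(expr) <- paste0("c", 1:4)
  top2 <- select_variable_genes(expr, 2)
  expect_equal(rownames(top2), c("g5", "g4"))
  # random oracle
  set.seed(9)
  expr <- matrix(rnorm(500), 50, 10,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
  k <- 12
  v <- apply(expr, 1, function(x) mean((x - mean(x))^2))
  oracle <- rownames(expr)[order(-v)][1:k]
  got <- select_variable_genes(expr, k)
  expect_equal(rownames(got), oracle)
  # idempotent
  expect_equal(select_variable_genes(got, k), got)
  # k = all genes is a row permutation of the input
  all_g <- select_variable_genes(expr, nrow(expr))
  expect_setequal(rownames(all_g), rownames(expr))
  expect_equal(all_g[rownames(expr), ], expr)
  # errors
  expect_error(select_variable_genes(expr, 51), "exceeds")
})

test_that("variance ties are broken by input row order", {
  expr <- matrix(c(1, -1, 1, -1, 2, -2), 3, 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("x", "y")))
  expect_equal(rownames(select_variable_genes(expr, 2)), c("c", "a"))
})

test_that("dataset assembly validates id resolution", {
  fx <- tiny_filtered_dataset()
  ds <- fx$dataset
  expect_s3_class(ds, "synergy_dataset")
  bad <- ds$measurements
  bad$drug1_id[1] <- "NOPE"
  expect_error(synergy_dataset(ds$drugs, bad, ds$expression),
               "unknown drug", class = "validation_error")
  bad2 <- ds$measurements
  bad2$cell_id[1] <- "NOPE"
  expect_error(synergy_dataset(ds$drugs, bad2, ds$expression),
               "unknown cell", class = "validation_error")
})

test_that("dataset directory round trip preserves content", {
  fx <- tiny_filtered_dataset()
  dir <- withr::local_tempdir()
  write_dataset(fx$dataset, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$drugs, fx$dataset$drugs)
  expect_equal(ds2$measurements$response, fx$dataset$measurements$response)
  expect_equal(dim(ds2$expression), dim(fx$dataset$expression))
  expect_equal(unname(ds2$expression), unname(fx$dataset$expression),
               tolerance = 1e-12)
})
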
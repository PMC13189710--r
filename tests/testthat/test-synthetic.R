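test_that("the generator is deterministic given its seed", {
  a <- generate_dataset(generator_config(n_drugs = 5, n_cells = 3,
                                         n_pairs = 4, n_genes = 40, seed = 5))
  b <- generate_dataset(generator_config(n_drugs = 5, n_cells = 3,
                                         n_pairs = 4, n_genes = 40, seed = 5))
  expect_identical(a$dataset$measurements, b$dataset$measurements)
  expect_identical(a$dataset$expression, b$dataset$expression)
  expect_identical(a$truth$gamma, b$truth$gamma)
  # and bitwise identical on the serialized form
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in c("measurements.csv", "expression.csv", "truth_gamma.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c2 <- generate_dataset(generator_config(n_drugs = 5, n_cells = 3,
                                          n_pairs = 4, n_genes = 40, seed = 6))
  expect_false(identical(a$dataset$measurements$response,
                         c2$dataset$measurements$response))
})

test_that("record counts follow the construction formula", {
  # n_pairs * n_cells * grid^2 combination records,
  # n_drugs * n_cells * grid monotherapy records
  cfg <- generator_config(n_drugs = 8, n_cells = 4, n_pairs = 10,
                          n_genes = 30, seed = 2)
  sim <- generate_dataset(cfg)
  m <- sim$dataset$measurements
  expect_equal(sum(!is.na(m$drug2_id)), 10 * 4 * 16)
  expect_equal(sum(is.na(m$drug2_id)), 8 * 4 * 4)
  expect_equal(nrow(sim$truth$responses), nrow(m))
  expect_equal(nrow(sim$truth$gamma), 10 * 4)
})

test_that("zero noise and zero interaction reproduce Bliss independence exactly", {
  cfg <- generator_config(n_drugs = 5, n_cells = 2, n_pairs = 4, n_genes = 30,
                          noise_sd = 0, interaction_strength = c(0, 0),
                          seed = 8)
  sim <- generate_dataset(cfg)
  m <- sim$dataset$measurements
  combo <- !is.na(m$drug2_id)
  # reconstruct the Bliss reference from the monotherapy rows
  mono <- m[!combo, ]
  E_of <- function(d, cc, dose) {
    row <- mono$drug1_id == d & mono$cell_id == cc & mono$dose1 == dose
    100 - mono$response[row]
  }
  idx <- which(combo)[seq(1, sum(combo), by = 7)]
  for (i in idx) {
    e1 <- E_of(m$drug1_id[i], m$cell_id[i], m$dose1[i])
    e2 <- E_of(m$drug2_id[i], m$cell_id[i], m$dose2[i])
    bliss <- 100 - (e1 + e2 - e1 * e2 / 100)
    expect_equal(m$response[i], bliss, tolerance = 1e-9)
  }
})

test_that("noise-free monotherapy curves are monotone when slopes are positive", {
  cfg <- generator_config(n_drugs = 6, n_cells = 3, n_pairs = 5, n_genes = 30,
                          noise_sd = 0, seed = 9)
  sim <- generate_dataset(cfg)
  m <- sim$dataset$measurements
  mono <- m[is.na(m$drug2_id), ]
  for (key in unique(paste(mono$drug1_id, mono$cell_id))) {
    sub <- mono[paste(mono$drug1_id, mono$cell_id) == key, ]
    sub <- sub[order(sub$dose1), ]
    expect_true(all(diff(sub$response) <= 1e-9), info = key)
  }
})

test_that("responses respect the clipping range and clips are counted", {
  cfg <- generator_config(n_drugs = 5, n_cells = 2, n_pairs = 4, n_genes = 30,
                          noise_sd = 80, seed = 10)
  sim <- generate_dataset(cfg)
  r <- sim$dataset$measurements$response
  expect_true(all(r >= cfg$response_range[1] & r <= cfg$response_range[2]))
  expect_gt(sim$truth$n_clipped, 0)
})

test_that("the expression matrix has heterogeneous per-gene variance", {
  sim <- tiny_simulation(seed = 12)
  v <- apply(sim$dataset$expression, 1, var)
  expect_gt(max(v) / stats::median(v), 3)
})

test_that("the generator's ranking is recovered by the oracle evaluation", {
  sim <- generate_dataset(generator_config(n_drugs = 5, n_cells = 2,
                                           n_pairs = 4, n_genes = 30,
                                           noise_sd = 0, seed = 13))
  split <- make_split(sim$dataset, "S1", fold = 1, seed = 13)
  ev <- evaluate_model(oracle_model(sim$truth$responses), sim$dataset, split)
  expect_equal(ev$within_list_spearman, 1, tolerance = 1e-12)
})

test_that("the ablation fixture tags modality-driven interactions by construction", {
  cfg <- generator_config(n_drugs = 6, n_cells = 4, n_pairs = 6, n_genes = 30,
                          noise_sd = 0, seed = 14)
  fx <- generate_ablation_fixture(cfg)
  g <- fx$truth$gamma
  expect_setequal(unique(g$tag), c("drug1", "drug2", "cell"))
  for (pk in unique(paste(g$drug1_id, g$drug2_id))) {
    sub <- g[paste(g$drug1_id, g$drug2_id) == pk, ]
    if (sub$tag[1] == "cell") {
      expect_gt(stats::sd(sub$gamma), 0) # varies across cells
    } else {
      expect_equal(stats::sd(sub$gamma), 0) # cell-invariant
    }
  }
  # cell-driven gamma is the same function of the cell across pairs
  cellpairs <- g[g$tag == "cell", ]
  if (length(unique(paste(cellpairs$drug1_id, cellpairs$drug2_id))) > 1) {
    wide <- split(cellpairs$gamma, paste(cellpairs$drug1_id,
                                         cellpairs$drug2_id))
    expect_equal(wide[[1]], wide[[2]], tolerance = 1e-12)
  }
  # drug1-driven gamma is invariant to the partner drug: same drug1, same gamma
  d1g <- unique(g[g$tag == "drug1", c("drug1_id", "gamma")])
  expect_equal(nrow(d1g), length(unique(d1g$drug1_id)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_drugs = 1), "counts|pairs")
  expect_error(generator_config(n_drugs = 100), "fixture")
  expect_error(generator_config(noise_sd = -1), "nonnegative")
  expect_error(generator_config(n_drugs = 4, n_pairs = 10), "pairs")
})
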
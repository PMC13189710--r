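test_that("sinusoidal encoding matches its closed form", {
  e0 <- sinusoidal_encode(0)
  expect_length(e0, 64)
  expect_equal(e0[seq(1, 63, 2)], rep(0, 32)) # even i (1-based odd) -> sin 0
  expect_equal(e0[seq(2, 64, 2)], rep(1, 32)) # odd i -> cos 0
  e1 <- sinusoidal_encode(1)
  expect_equal(e1[1], sin(1))          # i = 0
  expect_equal(e1[2], cos(1 * 10^(-4 / 64)))  # i = 1
  expect_equal(e1[3], sin(1 * 10^(-8 / 64)))  # i = 2
  expect_error(sinusoidal_encode(Inf), "finite")
})

test_that("sinusoidal components stay in [-1, 1] over a wide input sweep", {
  r <- seq(-1000, 1000, length.out = 4001)
  m <- sinusoidal_encode(r)
  expect_equal(dim(m), c(4001, 64))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("component frequencies are strictly decreasing in i", {
  i <- 0:63
  freq <- 10^(-4 * i / 64)
  expect_true(all(diff(freq) < 0))
  # and the encoding actually uses them: the zero-crossing scale grows with i
  expect_equal(sinusoidal_encode(pi / freq[1])[1], sin(pi), tolerance = 1e-12)
})

test_that("drug encoder is deterministic, 128-wide, and token-sensitive", {
  cfg <- tiny_model_config(seed = 5)
  model <- build_model(cfg, n_genes = 10)
  toks <- tokenize_smiles("CC(=O)OC1=CC=CC=C1C(=O)O", cfg)
  e1 <- encode_drug(toks, model)
  e2 <- encode_drug(toks, model)
  expect_length(e1, 128)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  # wrong length -> shape error
  expect_error(encode_drug(toks[-1], model), class = "shape_error")
  # changing one non-pad token changes the output; tested at the default
  # desk encoder width, where the max-pooled representation is reliably
  # sensitive to single-token edits (a very narrow CNN can pool a single
  # edit away)
  for (seed in 1:3) {
    cfg_w <- model_config(preset = "desk", max_smiles_length = 40,
                          seed = seed)
    m <- build_model(cfg_w, n_genes = 10)
    tw <- tokenize_smiles("CC(=O)OC1=CC=CC=C1C(=O)O", cfg_w)
    t2 <- tw
    t2[2] <- unname(cfg_w$vocabulary[["N"]])
    expect_false(isTRUE(all.equal(encode_drug(tw, m), encode_drug(t2, m))))
  }
  # the null (all-pad) sequence has its own embedding
  null_emb <- encode_drug(integer(cfg$max_smiles_length), model)
  expect_true(all(is.finite(null_emb)))
  expect_false(isTRUE(all.equal(null_emb, e1)))
})

test_that("cell encoder is deterministic and 256-wide", {
  cfg <- tiny_model_config(seed = 2)
  model <- build_model(cfg, n_genes = 30)
  x <- rnorm(30)
  e <- encode_cell(x, model)
  expect_length(e, 256)
  expect_identical(e, encode_cell(x, model))
  z <- encode_cell(numeric(30), model) # bias response, finite
  expect_true(all(is.finite(z)))
  expect_error(encode_cell(rnorm(29), model), class = "shape_error")
})

test_that("batch prediction equals per-sample prediction elementwise", {
  fx <- tiny_filtered_dataset()
  ds <- fx$dataset
  cfg <- tiny_model_config(seed = 8)
  model <- build_model(cfg, n_genes = nrow(ds$expression))
  rows <- c(1, 5, 20, nrow(ds$measurements))
  batch <- predict_responses(model, ds, rows = rows)
  for (k in seq_along(rows)) {
    mm <- ds$measurements[rows[k], ]
    d1 <- tokenize_smiles(ds$drugs$smiles[ds$drugs$drug_id == mm$drug1_id], cfg)
    d2 <- if (is.na(mm$drug2_id)) NULL else
      tokenize_smiles(ds$drugs$smiles[ds$drugs$drug_id == mm$drug2_id], cfg)
    single <- predict_synergy(model, d1, d2, mm$dose1, mm$dose2,
                              ds$expression[, mm$cell_id])
    expect_equal(single, batch[k], tolerance = 1e-12)
  }
})

test_that("monotherapy inputs produce finite predictions", {
  fx <- tiny_filtered_dataset()
  ds <- fx$dataset
  cfg <- tiny_model_config(seed = 4)
  model <- build_model(cfg, n_genes = nrow(ds$expression))
  toks <- tokenize_smiles(ds$drugs$smiles[1], cfg)
  p <- predict_synergy(model, toks, NULL, 1e-6, 0, ds$expression[, 1])
  expect_true(is.finite(p))
  expect_error(predict_synergy(model, toks, NULL, 1e-6, 1e-7,
                               ds$expression[, 1]), "dose2")
})

test_that("linear dose encoding is a 64-wide affine map", {
  cfg <- tiny_model_config(seed = 3, dose_encoding = "linear")
  model <- build_model(cfg, n_genes = 10)
  e <- encode_dose_linear(5, model)
  expect_length(e, 64)
  expect_identical(e, encode_dose_linear(5, model))
  # affine identity: f(a) + f(b) - f(0) == f(a + b)
  a <- 3.2; b <- -1.7
  expect_equal(encode_dose_linear(a, model) + encode_dose_linear(b, model) -
                 encode_dose_linear(0, model),
               encode_dose_linear(a + b, model), tolerance = 1e-10)
  # models without the linear layer refuse
  m2 <- build_model(tiny_model_config(), n_genes = 10)
  expect_error(encode_dose_linear(5, m2), "linear")
})

test_that("dose scaling maps concentrations to encoder positions", {
  cfg <- tiny_model_config()
  expect_equal(dose_position(c(1e-8, 1e-5), cfg), c(8, 5))
  expect_equal(dose_position(0, cfg), 0) # empty monotherapy slot
  mm <- tiny_model_config(dose_scale_mode = "minmax")
  expect_equal(dose_position(c(1e-8, 1e-4), mm), c(0, 100))
  expect_error(dose_position(-1, cfg), "nonnegative")
})

test_that("ECFP drug encoders project or pass through the bit vector", {
  smi <- "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O"
  cfg <- tiny_model_config(seed = 6, drug_encoding = "ecfp")
  model <- build_model(cfg, n_genes = 10)
  e <- encode_drug_ecfp(smi, model)
  expect_length(e, 128)
  expect_identical(e, encode_drug_ecfp(smi, model))
  cfgF <- tiny_model_config(seed = 6, drug_encoding = "ecfp_folded")
  modelF <- build_model(cfgF, n_genes = 10)
  eF <- encode_drug_ecfp(smi, modelF)
  expect_length(eF, 1024)
  expect_equal(as.integer(eF), as.integer(morgan_fingerprint(smi)))
  expect_error(encode_drug_ecfp("C1CC", model), class = "chemistry_error")
  # head input widens for the folded variant
  expect_length(modality_slices(cfgF)$cell, 256)
  expect_equal(max(unlist(modality_slices(cfgF))), 2 * 1024 + 2 * 64 + 256)
})

test_that("fixed seeds give identical initialization", {
  m1 <- build_model(tiny_model_config(seed = 42), n_genes = 15)
  m2 <- build_model(tiny_model_config(seed = 42), n_genes = 15)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_model_config(seed = 43), n_genes = 15)
  expect_false(identical(m1$params, m3$params))
})
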
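# The synergy model: three input encoders (SMILES CNN, sinusoidal dose
# encoder, expression MLP), ablation-variant encoders (linear dose, ECFP),
# and the fused MLP prediction head.

#' Model architecture configuration
#'
#' Embedding widths fixed by the architecture: 128-dimensional drug
#' embeddings, 64-dimensional dose embeddings, 256-dimensional cell
#' embeddings (the fused head input is 128+128+64+64+256 = 640 for the CNN
#' and projected-ECFP drug encoders). Internal widths are preset-dependent:
#' the `"desk"` preset is small enough to train in seconds on one CPU, the
#' `"paper"` preset uses the larger reference widths.
#'
#' @param preset `"desk"` (default) or `"paper"`; sets internal widths
#'   unless overridden explicitly.
#' @param vocabulary token-to-index map, see [default_vocabulary()].
#' @param max_smiles_length padded/truncated SMILES token length.
#' @param embed_dim token embedding width of the drug CNN.
#' @param conv_filters integer vector of filters per 1-D conv layer.
#' @param kernel_size convolution kernel width.
#' @param cell_hidden hidden widths of the expression MLP.
#' @param head_hidden hidden widths of the prediction head.
#' @param dose_scale_mode how molar concentrations become encoder positions:
#'   `"neglog10"` (default; position = -log10(molar), so 1e-8 M -> 8),
#'   `"minmax"` (log-dose mapped onto \[0, 100\] over `dose_range`), or
#'   `"raw"`.
#' @param dose_range molar range used by the `"minmax"` mode.
#' @param dose_encoding `"sin"` (sinusoidal, default) or `"linear"` (single
#'   affine layer; ablation variant).
#' @param drug_encoding `"cnn"` (default), `"ecfp"` (1024-bit ECFP-style
#'   fingerprint projected to 128 dims) or `"ecfp_folded"` (the folded bit
#'   vector fed directly to the head).
#' @param ecfp_radius,ecfp_bits fingerprint parameters (defaults 2, 1024).
#' @param seed RNG seed for parameter initialization; a fixed seed gives
#'   identical initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(preset = c("desk", "paper"),
                         vocabulary = default_vocabulary(),
                         max_smiles_length = 64,
                         embed_dim = NULL, conv_filters = NULL,
                         kernel_size = 5,
                         cell_hidden = NULL, head_hidden = NULL,
                         dose_scale_mode = c("neglog10", "minmax", "raw"),
                         dose_range = c(1e-8, 1e-4),
                         dose_encoding = c("sin", "linear"),
                         drug_encoding = c("cnn", "ecfp", "ecfp_folded"),
                         ecfp_radius = 2, ecfp_bits = 1024,
                         seed = 1L) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper") {
    list(embed_dim = 64, conv_filters = c(64, 64), cell_hidden = 512,
         head_hidden = c(512, 128))
  } else {
    list(embed_dim = 32, conv_filters = c(32, 32), cell_hidden = 64,
         head_hidden = c(128, 64))
  }
  structure(list(
    preset = preset,
    vocabulary = vocabulary,
    max_smiles_length = as.integer(max_smiles_length),
    embed_dim = as.integer(embed_dim %||% defaults$embed_dim),
    conv_filters = as.integer(conv_filters %||% defaults$conv_filters),
    kernel_size = as.integer(kernel_size),
    drug_dim = 128L, dose_dim = 64L, cell_dim = 256L,
    cell_hidden = as.integer(cell_hidden %||% defaults$cell_hidden),
    head_hidden = as.integer(head_hidden %||% defaults$head_hidden),
    dose_scale_mode = match.arg(dose_scale_mode),
    dose_range = dose_range,
    dose_encoding = match.arg(dose_encoding),
    drug_encoding = match.arg(drug_encoding),
    ecfp_radius = ecfp_radius, ecfp_bits = as.integer(ecfp_bits),
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Width of the drug representation entering the head
#' @noRd
drug_out_dim <- function(config) {
  if (config$drug_encoding == "ecfp_folded") config$ecfp_bits else config$drug_dim
}

#' Per-modality column slices of the fused head input
#' @noRd
modality_slices <- function(config) {
  dd <- drug_out_dim(config)
  ends <- cumsum(c(dd, dd, config$dose_dim, config$dose_dim, config$cell_dim))
  starts <- c(1, utils::head(ends, -1) + 1)
  stats::setNames(lapply(seq_along(ends), function(i) starts[i]:ends[i]),
                  c("drug1", "drug2", "dose1", "dose2", "cell"))
}

#' Build a synergy model with freshly initialized parameters
#'
#' @param config a [model_config()].
#' @param n_genes number of expression features the cell encoder consumes.
#' @return a `synergy_model` (parameters + config); the forward pass is a
#'   deterministic function of (parameters, input).
#' @export
build_model <- function(config, n_genes) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  assert_that(n_genes >= 1, "n_genes must be positive")
  set.seed(config$seed)
  params <- list()
  if (config$drug_encoding == "cnn") {
    V <- max(config$vocabulary) + 1L
    params$drug.E <- matrix(stats::rnorm(V * config$embed_dim, sd = 0.1),
                            V, config$embed_dim)
    cin <- config$embed_dim
    for (l in seq_along(config$conv_filters)) {
      cout <- config$conv_filters[l]
      d <- init_dense(config$kernel_size * cin, cout)
      params[[paste0("drug.conv", l, ".W")]] <- d$W
      params[[paste0("drug.conv", l, ".b")]] <- d$b
      cin <- cout
    }
    d <- init_dense(cin, config$drug_dim)
    params$drug.proj.W <- d$W
    params$drug.proj.b <- d$b
  } else if (config$drug_encoding == "ecfp") {
    d <- init_dense(config$ecfp_bits, config$drug_dim)
    params$drug.proj.W <- d$W
    params$drug.proj.b <- d$b
  } # ecfp_folded: no drug parameters
  if (config$dose_encoding == "linear") {
    d <- init_dense(1L, config$dose_dim)
    params$dose.W <- d$W
    params$dose.b <- d$b
  }
  cell_dims <- c(n_genes, config$cell_hidden, config$cell_dim)
  for (l in seq_len(length(cell_dims) - 1)) {
    d <- init_dense(cell_dims[l], cell_dims[l + 1])
    params[[paste0("cell.", l, ".W")]] <- d$W
    params[[paste0("cell.", l, ".b")]] <- d$b
  }
  in_dim <- 2L * drug_out_dim(config) + 2L * config$dose_dim + config$cell_dim
  head_dims <- c(in_dim, config$head_hidden, 1L)
  for (l in seq_len(length(head_dims) - 1)) {
    d <- init_dense(head_dims[l], head_dims[l + 1])
    params[[paste0("head.", l, ".W")]] <- d$W
    params[[paste0("head.", l, ".b")]] <- d$b
  }
  structure(list(config = config, n_genes = as.integer(n_genes),
                 params = params,
                 n_cell_layers = length(cell_dims) - 1L,
                 n_head_layers = length(head_dims) - 1L),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<synergy_model> ", x$config$drug_encoding, " drug encoder, ",
      x$config$dose_encoding, " dose encoder, ", x$n_genes,
      " expression features, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

layers_from_params <- function(params, prefix, n) {
  lapply(seq_len(n), function(l)
    list(W = params[[paste0(prefix, l, ".W")]],
         b = params[[paste0(prefix, l, ".b")]]))
}

# ---------------------------------------------------------------------------
# Dose encoding

#' Scale molar concentrations to encoder positions
#'
#' A zero dose (the empty monotherapy slot) always maps to position 0.
#'
#' @param dose molar concentrations (>= 0).
#' @param config a [model_config()] (uses `dose_scale_mode`, `dose_range`).
#' @return numeric positions.
#' @export
dose_position <- function(dose, config) {
  assert_that(all(is.finite(dose)) && all(dose >= 0),
              "doses must be finite and nonnegative")
  switch(config$dose_scale_mode,
         neglog10 = ifelse(dose == 0, 0, -log10(dose)),
         minmax = ifelse(dose == 0, 0, {
           lr <- log10(config$dose_range)
           100 * (log10(pmax(pmin(dose, config$dose_range[2]),
                             config$dose_range[1])) - lr[1]) / (lr[2] - lr[1])
         }),
         raw = dose)
}

#' Sinusoidal dose encoding
#'
#' Component i (i = 0, ..., dim-1) of the embedding of a scaled dose
#' position r is `sin(r * 10^(-4i/dim))` for even i and
#' `cos(r * 10^(-4i/dim))` for odd i, i.e. the multiplicative frequency
#' `10000^(-i/dim)` is strictly decreasing in i. All components lie in
#' \[-1, 1\].
#'
#' @param dose_position finite scaled position(s), see [dose_position()].
#' @param dim embedding width (default 64).
#' @return a length-`dim` vector, or an n x dim matrix for vector input.
#' @export
sinusoidal_encode <- function(dose_position, dim = 64) {
  assert_that(all(is.finite(dose_position)), "dose_position must be finite")
  i <- 0:(dim - 1)
  freq <- 10^(-4 * i / dim)
  ang <- outer(as.numeric(dose_position), freq)
  even <- i %% 2 == 0
  out <- ang
  out[, even] <- sin(ang[, even, drop = FALSE])
  out[, !even] <- cos(ang[, !even, drop = FALSE])
  if (length(dose_position) == 1) drop(out) else out
}

#' Linear dose encoding (ablation variant)
#'
#' A single affine layer maps the scalar position to a 64-dimensional
#' embedding: `encode(r) = r * W + b`.
#'
#' @param dose_position finite scaled position(s).
#' @param model a `synergy_model` built with `dose_encoding = "linear"`.
#' @return a length-64 vector, or an n x 64 matrix for vector input.
#' @export
encode_dose_linear <- function(dose_position, model) {
  assert_that(all(is.finite(dose_position)), "dose_position must be finite")
  assert_that(!is.null(model$params$dose.W),
              "model was not built with dose_encoding = 'linear'")
  out <- add_bias(cbind(as.numeric(dose_position)) %*% model$params$dose.W,
                  model$params$dose.b)
  if (length(dose_position) == 1) drop(out) else out
}

encode_dose_batch <- function(model, positions) {
  if (model$config$dose_encoding == "sin") {
    m <- sinusoidal_encode(positions, model$config$dose_dim)
    if (is.null(dim(m))) m <- matrix(m, 1)
    m
  } else {
    m <- encode_dose_linear(positions, model)
    if (is.null(dim(m))) m <- matrix(m, 1)
    m
  }
}

# ---------------------------------------------------------------------------
# Drug encoder

#' Forward pass of the drug encoder over a batch of token sequences
#' (or fingerprint rows for the ECFP variants)
#' @noRd
drug_forward <- function(model, input) {
  cfg <- model$config
  if (cfg$drug_encoding == "ecfp_folded") {
    return(list(out = input, cache = NULL))
  }
  if (cfg$drug_encoding == "ecfp") {
    Zp <- add_bias(input %*% model$params$drug.proj.W,
                   model$params$drug.proj.b)
    return(list(out = pmax(Zp, 0), cache = list(input = input, projZ = Zp)))
  }
  U <- nrow(input)
  L <- cfg$max_smiles_length
  assert_that(ncol(input) == L, "token sequences must have length max_smiles_length",
              "shape_error")
  idx <- as.integer(t(input)) + 1L # row (u-1)*L + t
  X <- model$params$drug.E[idx, , drop = FALSE]
  caches <- list(idx = idx)
  L_cur <- L
  A <- X
  for (l in seq_along(cfg$conv_filters)) {
    cc <- conv1d_forward(A, L_cur, U, model$params[[paste0("drug.conv", l, ".W")]],
                         model$params[[paste0("drug.conv", l, ".b")]],
                         cfg$kernel_size)
    caches[[paste0("conv", l)]] <- cc
    A <- cc$A
    L_cur <- cc$Lp
  }
  C <- utils::tail(cfg$conv_filters, 1)
  pl <- pool_forward(A, U, L_cur, C)
  caches$pool <- pl
  caches$Lp <- L_cur
  caches$C <- C
  caches$U <- U
  # ReLU-activated embedding: sparse nonnegative representation for which
  # the zero baseline of the attribution layer means "feature inactive"
  Zp <- add_bias(pl$out %*% model$params$drug.proj.W, model$params$drug.proj.b)
  caches$pooled <- pl$out
  caches$projZ <- Zp
  list(out = pmax(Zp, 0), cache = caches)
}

drug_backward <- function(model, cache, dOut, grads) {
  cfg <- model$config
  if (cfg$drug_encoding == "ecfp_folded") return(grads)
  if (cfg$drug_encoding == "ecfp") {
    dZp <- dOut * (cache$projZ > 0)
    grads <- grad_add(grads, "drug.proj.W", crossprod(cache$input, dZp))
    grads <- grad_add(grads, "drug.proj.b", colSums(dZp))
    return(grads)
  }
  dZp <- dOut * (cache$projZ > 0)
  grads <- grad_add(grads, "drug.proj.W", crossprod(cache$pooled, dZp))
  grads <- grad_add(grads, "drug.proj.b", colSums(dZp))
  dPool <- tcrossprod(dZp, model$params$drug.proj.W)
  dA <- pool_backward(dPool, cache$pool$arg, cache$U, cache$Lp, cache$C)
  for (l in rev(seq_along(cfg$conv_filters))) {
    cc <- cache[[paste0("conv", l)]]
    bk <- conv1d_backward(dA, cc, model$params[[paste0("drug.conv", l, ".W")]])
    grads <- grad_add(grads, paste0("drug.conv", l, ".W"), bk$dW)
    grads <- grad_add(grads, paste0("drug.conv", l, ".b"), bk$db)
    dA <- bk$dX
  }
  dE <- matrix(0, nrow(model$params$drug.E), cfg$embed_dim)
  rs <- rowsum(dA, group = cache$idx)
  dE[as.integer(rownames(rs)), ] <- rs
  grads <- grad_add(grads, "drug.E", dE)
  grads
}

#' Encode a tokenized SMILES sequence to a 128-dimensional drug embedding
#'
#' The all-padding (null drug) sequence used for the empty monotherapy slot
#' maps through the learned padding embedding to its own dedicated vector.
#'
#' @param tokens integer vector of length `max_smiles_length` (see
#'   [tokenize_smiles()]), or a matrix of such rows.
#' @param model a `synergy_model`.
#' @return a length-128 vector (or matrix of rows).
#' @export
encode_drug <- function(tokens, model) {
  if (is.null(dim(tokens))) tokens <- matrix(as.integer(tokens), 1)
  assert_that(ncol(tokens) == model$config$max_smiles_length,
              sprintf("token sequence length %d != max_smiles_length %d",
                      ncol(tokens), model$config$max_smiles_length),
              "shape_error")
  out <- drug_forward(model, tokens)$out
  if (nrow(out) == 1) drop(out) else out
}

#' Encode a drug via its ECFP-style fingerprint (ablation variant)
#'
#' @param smiles SMILES string.
#' @param model a `synergy_model` built with `drug_encoding = "ecfp"` or
#'   `"ecfp_folded"`.
#' @return for `"ecfp"`, the 128-dimensional affine projection of the bit
#'   vector; for `"ecfp_folded"`, the raw 1024-bit vector.
#' @export
encode_drug_ecfp <- function(smiles, model) {
  cfg <- model$config
  assert_that(cfg$drug_encoding %in% c("ecfp", "ecfp_folded"),
              "model was not built with an ECFP drug encoding")
  fp <- morgan_fingerprint(smiles, radius = cfg$ecfp_radius, nbits = cfg$ecfp_bits)
  drop(drug_forward(model, matrix(as.numeric(fp), 1))$out)
}

# ---------------------------------------------------------------------------
# Cell encoder and head

cell_forward <- function(model, expr_rows) {
  layers <- layers_from_params(model$params, "cell.", model$n_cell_layers)
  mlp_forward(expr_rows, layers, final_relu = TRUE)
}

#' Encode an expression profile to a 256-dimensional cell embedding
#'
#' @param expression_column numeric vector of length `model$n_genes` (one
#'   cell line's selected-gene expression), or a matrix of such rows.
#' @param model a `synergy_model`.
#' @return a length-256 vector (or matrix of rows).
#' @export
encode_cell <- function(expression_column, model) {
  if (is.null(dim(expression_column)))
    expression_column <- matrix(as.numeric(expression_column), 1)
  assert_that(ncol(expression_column) == model$n_genes,
              sprintf("expression length %d != model n_genes %d",
                      ncol(expression_column), model$n_genes),
              "shape_error")
  out <- cell_forward(model, expression_column)$out
  if (nrow(out) == 1) drop(out) else out
}

head_forward <- function(model, X) {
  layers <- layers_from_params(model$params, "head.", model$n_head_layers)
  mlp_forward(X, layers)
}

head_backward <- function(model, fw, dOut, grads = list()) {
  layers <- layers_from_params(model$params, "head.", model$n_head_layers)
  bk <- mlp_backward(dOut, layers, fw$caches)
  for (l in seq_along(layers)) {
    grads <- grad_add(grads, paste0("head.", l, ".W"), bk$grads[[l]]$W)
    grads <- grad_add(grads, paste0("head.", l, ".b"), bk$grads[[l]]$b)
  }
  list(grads = grads, dX = bk$dX)
}

#' Gradient of the head output with respect to its fused input
#' @noRd
head_input_gradient <- function(model, X) {
  fw <- head_forward(model, X)
  layers <- layers_from_params(model$params, "head.", model$n_head_layers)
  bk <- mlp_backward(matrix(1, nrow(X), 1), layers, fw$caches)
  list(out = drop(fw$out), grad = bk$dX)
}

# ---------------------------------------------------------------------------
# Dataset-level plumbing

#' Precompute model inputs for every measurement of a dataset
#'
#' Tokenizes (or fingerprints) every drug once, transposes the expression
#' matrix into cell rows, and resolves each measurement to drug/cell indices
#' and scaled dose positions. Row 1 of the drug input block is the null
#' drug used for the empty monotherapy slot.
#'
#' @param model a `synergy_model`.
#' @param dataset a `synergy_dataset` whose expression matrix has exactly
#'   `model$n_genes` rows (apply [select_variable_genes()] first).
#' @return an opaque list consumed by [predict_responses()] and the trainer.
#' @export
prepare_model_data <- function(model, dataset) {
  cfg <- model$config
  assert_that(nrow(dataset$expression) == model$n_genes,
              sprintf("dataset has %d genes but model expects %d",
                      nrow(dataset$expression), model$n_genes),
              "shape_error")
  drug_ids <- dataset$drugs$drug_id
  if (cfg$drug_encoding == "cnn") {
    drug_in <- rbind(integer(cfg$max_smiles_length),
                     t(vapply(dataset$drugs$smiles,
                              function(s) tokenize_smiles(s, cfg),
                              integer(cfg$max_smiles_length))))
  } else {
    drug_in <- rbind(numeric(cfg$ecfp_bits),
                     t(vapply(dataset$drugs$smiles,
                              function(s) as.numeric(morgan_fingerprint(
                                s, cfg$ecfp_radius, cfg$ecfp_bits)),
                              numeric(cfg$ecfp_bits))))
  }
  rownames(drug_in) <- NULL
  cells <- colnames(dataset$expression)
  expr_rows <- t(dataset$expression)
  # apply the model's per-gene standardization, if trained with one
  es <- model$expr_scale
  if (!is.null(es)) {
    expr_rows <- sweep(sweep(expr_rows, 2, es$center), 2, es$scale, "/")
  }
  m <- dataset$measurements
  list(
    drug_in = drug_in,
    expr_rows = expr_rows,
    d1_idx = match(m$drug1_id, drug_ids) + 1L,
    d2_idx = ifelse(is.na(m$drug2_id), 1L, match(m$drug2_id, drug_ids) + 1L),
    cell_idx = match(m$cell_id, cells),
    pos1 = dose_position(m$dose1, cfg),
    pos2 = dose_position(m$dose2, cfg),
    response = m$response,
    n = nrow(m)
  )
}

#' Full forward pass for a set of measurement rows
#' @return list with predictions, the fused input X and all caches.
#' @noRd
model_forward <- function(model, md, rows = seq_len(md$n)) {
  dr <- drug_forward(model, md$drug_in)
  cl <- cell_forward(model, md$expr_rows)
  e1 <- encode_dose_batch(model, md$pos1[rows])
  e2 <- encode_dose_batch(model, md$pos2[rows])
  X <- cbind(dr$out[md$d1_idx[rows], , drop = FALSE],
             dr$out[md$d2_idx[rows], , drop = FALSE],
             e1, e2,
             cl$out[md$cell_idx[rows], , drop = FALSE])
  hd <- head_forward(model, X)
  list(pred = unname(drop(hd$out)), X = X, head = hd, drug = dr, cell = cl,
       rows = rows)
}

#' Backward pass: gradient of a scalar loss given d(loss)/d(pred)
#' @noRd
model_backward <- function(model, md, fw, dpred) {
  cfg <- model$config
  rows <- fw$rows
  hb <- head_backward(model, fw$head, matrix(dpred, ncol = 1))
  grads <- hb$grads
  sl <- modality_slices(cfg)
  dX <- hb$dX
  # drug encoder: accumulate over both slots, then one backward pass
  n_drug_rows <- nrow(md$drug_in)
  dDrug <- matrix(0, n_drug_rows, drug_out_dim(cfg))
  rs1 <- rowsum(dX[, sl$drug1, drop = FALSE], group = md$d1_idx[rows])
  dDrug[as.integer(rownames(rs1)), ] <- dDrug[as.integer(rownames(rs1)), ] + rs1
  rs2 <- rowsum(dX[, sl$drug2, drop = FALSE], group = md$d2_idx[rows])
  dDrug[as.integer(rownames(rs2)), ] <- dDrug[as.integer(rownames(rs2)), ] + rs2
  grads <- drug_backward(model, fw$drug$cache, dDrug, grads)
  # cell encoder
  dCell <- matrix(0, nrow(md$expr_rows), cfg$cell_dim)
  rsc <- rowsum(dX[, sl$cell, drop = FALSE], group = md$cell_idx[rows])
  dCell[as.integer(rownames(rsc)), ] <- rsc
  layers <- layers_from_params(model$params, "cell.", model$n_cell_layers)
  cb <- mlp_backward(dCell, layers, fw$cell$caches, final_relu = TRUE)
  for (l in seq_len(model$n_cell_layers)) {
    grads <- grad_add(grads, paste0("cell.", l, ".W"), cb$grads[[l]]$W)
    grads <- grad_add(grads, paste0("cell.", l, ".b"), cb$grads[[l]]$b)
  }
  # linear dose encoder (sinusoidal has no parameters)
  if (cfg$dose_encoding == "linear") {
    d1 <- dX[, sl$dose1, drop = FALSE]
    d2 <- dX[, sl$dose2, drop = FALSE]
    grads <- grad_add(grads, "dose.W",
                      rbind(md$pos1[rows]) %*% d1 + rbind(md$pos2[rows]) %*% d2)
    grads <- grad_add(grads, "dose.b", colSums(d1) + colSums(d2))
  }
  grads
}

#' Predict responses for measurement rows of a dataset
#'
#' @param model a `synergy_model` or an [oracle_model()].
#' @param dataset a `synergy_dataset` (expression already gene-filtered for
#'   `synergy_model`s).
#' @param rows integer row indices into `dataset$measurements` (default all).
#' @param md optional precomputed [prepare_model_data()] result.
#' @return numeric vector of predicted responses.
#' @export
predict_responses <- function(model, dataset, rows = NULL, md = NULL) {
  UseMethod("predict_responses")
}

#' @export
predict_responses.synergy_model <- function(model, dataset, rows = NULL,
                                            md = NULL) {
  if (is.null(md)) md <- prepare_model_data(model, dataset)
  if (is.null(rows)) rows <- seq_len(md$n)
  pred <- model_forward(model, md, rows)$pred
  # back-transform to the raw response scale when the model was trained on
  # min-max-scaled targets
  rs <- model$response_scale
  if (!is.null(rs)) pred <- rs[1] + pred * (rs[2] - rs[1])
  pred
}

#' Predict the synergy/response value for a single input
#'
#' @param model a `synergy_model`.
#' @param d1_tokens tokenized SMILES of drug 1.
#' @param d2_tokens tokenized SMILES of drug 2, or `NULL` for monotherapy
#'   (the null drug embedding is used and `dose2` must be 0).
#' @param dose1,dose2 molar concentrations (`dose2 = 0` for monotherapy).
#' @param expression expression vector of length `model$n_genes`.
#' @return a finite scalar prediction.
#' @export
predict_synergy <- function(model, d1_tokens, d2_tokens, dose1, dose2,
                            expression) {
  cfg <- model$config
  if (is.null(d2_tokens)) {
    assert_that(dose2 == 0, "monotherapy (NULL drug 2) requires dose2 = 0")
    d2_tokens <- integer(cfg$max_smiles_length)
  }
  e_d1 <- encode_drug(d1_tokens, model)
  e_d2 <- encode_drug(d2_tokens, model)
  p <- dose_position(c(dose1, dose2), cfg)
  e_r <- encode_dose_batch(model, p)
  e_c <- encode_cell(expression, model)
  X <- matrix(c(e_d1, e_d2, e_r[1, ], e_r[2, ], e_c), nrow = 1)
  pred <- drop(head_forward(model, X)$out)
  rs <- model$response_scale
  if (!is.null(rs)) pred <- rs[1] + pred * (rs[2] - rs[1])
  pred
}

# ---------------------------------------------------------------------------
# Checkpointing

#' Save a model checkpoint (parameters + full config, hashed together)
#' @param model a `synergy_model`.
#' @param path output file.
#' @param extra optional named list stored alongside (e.g. history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(c(list(model = model, config_hash = object_hash(model$config),
                 package_version = as.character(utils::packageVersion("synergyrank"))),
            extra), path)
  invisible(path)
}

#' Load a model checkpoint, validating the config hash
#' @param path checkpoint file.
#' @return the stored list (fields `model`, `config_hash`, ...).
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), paste0("checkpoint not found: ", path), "io_error")
  ck <- readRDS(path)
  assert_that(identical(ck$config_hash, object_hash(ck$model$config)),
              "checkpoint config hash mismatch: file is corrupt or was edited",
              "integrity_error")
  ck
}
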
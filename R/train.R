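# List-aware training loop under the hybrid MSE + ranking objective.

#' Training configuration
#'
#' The `"paper"` preset carries the reference settings (10 000 epochs,
#' batch size 256, AdamW with learning rate 1e-4 and weight decay 1e-5).
#' The `"desk"` preset is a small-budget configuration for CPU-scale runs:
#' 400 epochs with a larger learning rate, suitable for the synthetic
#' benchmarks.
#'
#' @param preset `"paper"` (default) or `"desk"`.
#' @param epochs,batch_size,learning_rate,weight_decay optimizer settings
#'   (preset defaults unless given).
#' @param lambda_rank weight of the ranking term in the hybrid objective.
#' @param loss_variant `"hybrid"`, `"mse_only"` or `"pairwise"`.
#' @param gain_mode uRank gain reading, `"exp"` or `"linear"`.
#' @param swap_augment if `TRUE`, each combination record is presented with
#'   its (drug, dose) slots swapped with probability 1/2 per epoch, a
#'   training-time augmentation for drug-order symmetry (off by default:
#'   slot symmetry is not enforced).
#' @param response_scaling `"minmax"` (default) rescales responses to
#'   \[0, 1\] over the training set before fitting, so the network output is
#'   O(1) and the exponential listwise term is commensurate with the MSE
#'   term; predictions are mapped back to the raw response scale. `"none"`
#'   fits on the raw scale.
#' @param eval_every if > 0, evaluate on the split's test set every this
#'   many epochs and record the within-list Spearman in the history.
#' @param patience if > 0, stop early when the validation Spearman has not
#'   improved for `patience` evaluations (requires `eval_every > 0`). Off by
#'   default: the reference configuration trains for a fixed epoch count.
#' @param seed seed for batch shuffling.
#' @return a `training_config` list.
#' @export
training_config <- function(preset = c("paper", "desk"), epochs = NULL,
                            batch_size = NULL, learning_rate = NULL,
                            weight_decay = NULL, lambda_rank = 1,
                            loss_variant = c("hybrid", "mse_only", "pairwise"),
                            gain_mode = c("exp", "linear"),
                            swap_augment = FALSE,
                            response_scaling = c("minmax", "none"),
                            eval_every = 0L, patience = 0L, seed = 1L) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper") {
    list(epochs = 10000L, batch_size = 256L, learning_rate = 1e-4,
         weight_decay = 1e-5)
  } else {
    list(epochs = 400L, batch_size = 256L, learning_rate = 3e-3,
         weight_decay = 1e-5)
  }
  structure(list(
    preset = preset,
    epochs = as.integer(epochs %||% defaults$epochs),
    batch_size = as.integer(batch_size %||% defaults$batch_size),
    learning_rate = learning_rate %||% defaults$learning_rate,
    weight_decay = weight_decay %||% defaults$weight_decay,
    lambda_rank = lambda_rank,
    loss_variant = match.arg(loss_variant),
    gain_mode = match.arg(gain_mode),
    swap_augment = isTRUE(swap_augment),
    response_scaling = match.arg(response_scaling),
    eval_every = as.integer(eval_every),
    patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "training_config")
}

#' Train a synergy model on one scenario fold
#'
#' Batches hold whole response lists (a list larger than the batch size
#' becomes its own batch), because the listwise loss is undefined across
#' partial lists. The batch objective is the mean over its lists of
#' `mse + lambda_rank * rank_loss`; monotherapy lists of length 1
#' contribute only the regression term. Optimization uses AdamW. The output
#' bias of the head is initialized to the mean training response so the
#' regression term starts centred. Fixed seeds give bitwise-reproducible
#' runs on CPU.
#'
#' @param dataset a `synergy_dataset` (expression already gene-filtered).
#' @param split a `scenario_split` from [make_split()].
#' @param config a [model_config()]; its `seed` controls initialization.
#' @param control a [training_config()]; its `seed` controls shuffling.
#' @param quiet suppress per-epoch log lines (default TRUE).
#' @return list with `model` (the trained `synergy_model`) and `history`
#'   (data.frame: epoch, mse, urank, total, and validation Spearman where
#'   evaluated).
#' @export
train_model <- function(dataset, split, config = model_config(),
                        control = training_config(), quiet = TRUE) {
  assert_that(length(split$train_idx) > 0, "training set is empty", "data_error")
  model <- build_model(config, n_genes = nrow(dataset$expression))
  # standardize expression features per gene (stored on the model so the
  # identical transform applies at prediction time)
  mu <- rowMeans(dataset$expression)
  sdv <- sqrt(pmax(rowMeans(dataset$expression^2) - mu^2, 1e-12))
  model$expr_scale <- list(center = mu, scale = sdv)
  md <- prepare_model_data(model, dataset)
  # fit on min-max-scaled responses so the network output is O(1) and the
  # exponential listwise term is commensurate with the regression term
  if (control$response_scaling == "minmax") {
    rng <- range(md$response[split$train_idx])
    if (rng[2] == rng[1]) rng[2] <- rng[1] + 1
    model$response_scale <- rng
    target <- (md$response - rng[1]) / (rng[2] - rng[1])
  } else {
    target <- md$response
  }
  # whole-list batching on the training side
  train_m <- dataset$measurements[split$train_idx, , drop = FALSE]
  lists <- group_into_lists(train_m)
  list_rows <- lapply(lists, function(rl) split$train_idx[rl$idx])
  # centre the regression output at the mean training target
  bkey <- paste0("head.", model$n_head_layers, ".b")
  model$params[[bkey]] <- mean(target[split$train_idx])
  state <- adamw_state(model$params)
  set.seed(derive_seed(control$seed, "shuffle"))
  history <- vector("list", control$epochs)
  best_val <- -Inf
  stall <- 0L
  n_lists <- length(list_rows)
  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n_lists)
    batches <- list()
    cur <- integer(0)
    cur_lists <- list()
    for (li in ord) {
      rows_li <- list_rows[[li]]
      if (length(cur) > 0 &&
          length(cur) + length(rows_li) > control$batch_size) {
        batches[[length(batches) + 1]] <- cur_lists
        cur <- integer(0)
        cur_lists <- list()
      }
      cur <- c(cur, rows_li)
      cur_lists[[length(cur_lists) + 1]] <- rows_li
    }
    if (length(cur) > 0) batches[[length(batches) + 1]] <- cur_lists
    ep_mse <- ep_rank <- ep_total <- 0
    for (bl in batches) {
      rows <- unlist(bl, use.names = FALSE)
      md_b <- md
      if (control$swap_augment) {
        # present combination records with swapped (drug, dose) slots with
        # probability 1/2; monotherapy rows keep the null drug in slot 2
        sw <- rows[md$d2_idx[rows] != 1L & stats::runif(length(rows)) < 0.5]
        if (length(sw)) {
          md_b$d1_idx[sw] <- md$d2_idx[sw]
          md_b$d2_idx[sw] <- md$d1_idx[sw]
          md_b$pos1[sw] <- md$pos2[sw]
          md_b$pos2[sw] <- md$pos1[sw]
        }
      }
      fw <- model_forward(model, md_b, rows)
      dpred <- numeric(length(rows))
      offset <- 0L
      nb <- length(bl)
      for (rl_rows in bl) {
        nn <- length(rl_rows)
        sel <- offset + seq_len(nn)
        lb <- hybrid_loss(target[rl_rows], fw$pred[sel],
                          lambda_rank = control$lambda_rank,
                          gain_mode = control$gain_mode,
                          variant = control$loss_variant, grad = TRUE)
        dpred[sel] <- lb$grad / nb
        ep_mse <- ep_mse + lb$mse
        ep_rank <- ep_rank + lb$urank
        ep_total <- ep_total + lb$total
        offset <- offset + nn
      }
      if (!is.finite(ep_total)) {
        sr_abort(sprintf("non-finite training loss at epoch %d", epoch),
                 "training_divergence_error")
      }
      grads <- model_backward(model, md_b, fw, dpred)
      upd <- adamw_step(model$params, grads, state,
                        lr = control$learning_rate,
                        weight_decay = control$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    rec <- data.frame(epoch = epoch, mse = ep_mse / n_lists,
                      urank = ep_rank / n_lists, total = ep_total / n_lists,
                      val_spearman = NA_real_)
    if (control$eval_every > 0 && epoch %% control$eval_every == 0 &&
        length(split$test_idx) > 0) {
      ev <- evaluate_model(model, dataset, split, md = md)
      rec$val_spearman <- ev$within_list_spearman
      if (!quiet) {
        message(sprintf("epoch=%d total=%.4f mse=%.4f rank=%.4f val_spearman=%.4f",
                        epoch, rec$total, rec$mse, rec$urank, rec$val_spearman))
      }
      if (control$patience > 0) {
        if (rec$val_spearman > best_val + 1e-6) {
          best_val <- rec$val_spearman
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
    } else if (!quiet) {
      message(sprintf("epoch=%d total=%.4f mse=%.4f rank=%.4f",
                      epoch, rec$total, rec$mse, rec$urank))
    }
    history[[epoch]] <- rec
    if (control$patience > 0 && stall >= control$patience) {
      history <- history[seq_len(epoch)]
      break
    }
  }
  list(model = model, history = do.call(rbind, history))
}
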
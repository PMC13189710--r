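# Shared fixtures: tiny configs and datasets built in code at test time.

tiny_model_config <- function(seed = 1, max_smiles_length = 40,
                              head_hidden = c(16, 8), ...) {
  model_config(preset = "desk", embed_dim = 8, conv_filters = c(8, 8),
               cell_hidden = 8, head_hidden = head_hidden,
               max_smiles_length = max_smiles_length, seed = seed, ...)
}

tiny_simulation <- function(seed = 7, noise_sd = 2, ...) {
  generate_dataset(generator_config(n_drugs = 5, n_cells = 3, n_pairs = 4,
                                    n_genes = 60, noise_sd = noise_sd,
                                    seed = seed, ...))
}

tiny_filtered_dataset <- function(seed = 7, k = 20, ...) {
  sim <- tiny_simulation(seed = seed, ...)
  ds <- sim$dataset
  ds$expression <- select_variable_genes(ds$expression, k)
  list(dataset = ds, sim = sim)
}

# canonical measurement data.frame without going through the generator
make_measurements <- function(drug1, drug2, dose1, dose2, cell, response) {
  data.frame(record_id = sprintf("R%06d", seq_along(drug1)),
             drug1_id = drug1, drug2_id = drug2, dose1 = dose1,
             dose2 = dose2, cell_id = cell, response = response,
             stringsAsFactors = FALSE)
}

# random valid measurement table over a dose grid (for property tests)
random_measurements <- function(seed, n_drugs = 4, n_cells = 3,
                                grid = 10^c(-7, -6, -5), p_mono = 0.25) {
  set.seed(seed)
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  cells <- sprintf("C%02d", seq_len(n_cells))
  rows <- list()
  for (i in seq_len(n_drugs - 1)) {
    for (j in (i + 1):n_drugs) {
      for (cc in cells) {
        if (stats::runif(1) < 0.7) {
          gg <- expand.grid(dose1 = grid, dose2 = grid)
          keep <- stats::runif(nrow(gg)) < 0.8
          if (!any(keep)) keep[1] <- TRUE
          rows[[length(rows) + 1]] <- data.frame(
            drug1_id = drugs[i], drug2_id = drugs[j],
            dose1 = gg$dose1[keep], dose2 = gg$dose2[keep],
            cell_id = cc, response = stats::rnorm(sum(keep), 50, 30),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (p_mono > 0) {
    for (d in drugs) {
      for (cc in cells) {
        if (stats::runif(1) < p_mono * 2) {
          rows[[length(rows) + 1]] <- data.frame(
            drug1_id = d, drug2_id = NA_character_, dose1 = grid, dose2 = 0,
            cell_id = cc, response = stats::rnorm(length(grid), 70, 20),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  m$record_id <- sprintf("R%06d", seq_len(nrow(m)))
  m[, c("record_id", "drug1_id", "drug2_id", "dose1", "dose2", "cell_id",
        "response")]
}
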
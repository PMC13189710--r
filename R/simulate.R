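# Synthetic ALMANAC-shaped data with known ground truth.
#
# Monotherapy inhibition follows a Hill curve per (drug, cell); combination
# responses follow Bliss independence on the percent-growth scale plus a
# dose-localized interaction bump with a per-(pair, cell) strength gamma, a
# part of which is a function of the latent cell vector so cell-dominant
# synergies exist. Expression is a latent-factor model with heteroscedastic
# per-gene noise, so variance-based gene filtering is meaningful.

#' Configuration of the synthetic dataset generator
#'
#' Defaults mimic the screening design the package targets: a 4x4 molar
#' concentration grid per drug pair (1e-8 to 1e-5 M in decade steps) plus
#' monotherapy rows at the same concentrations, percent-growth responses,
#' and a genes x cells expression matrix.
#'
#' @param n_drugs number of drugs (drawn from [fixture_smiles()], max 32).
#' @param n_cells number of cell lines.
#' @param n_pairs number of unordered drug pairs.
#' @param dose_grid molar concentrations per drug (default 1e-8..1e-5).
#' @param n_genes number of genes before variance filtering (default 2000).
#' @param latent_dim latent cell-factor dimension.
#' @param emax_range Hill maximal-inhibition range (percent).
#' @param ec50_log10_range log10 molar EC50 sampling range.
#' @param slope_range Hill-slope range (> 0 gives monotone curves).
#' @param interaction_strength range of the synergy strength gamma
#'   (percent-growth points at the bump peak).
#' @param noise_sd Gaussian response noise standard deviation (>= 0).
#' @param response_range clipping range for responses (percent growth).
#' @param seed RNG seed; a fixed seed yields a bitwise-identical dataset.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_drugs = 12, n_cells = 6, n_pairs = 20,
                             dose_grid = 10^c(-8, -7, -6, -5),
                             n_genes = 2000, latent_dim = 8,
                             emax_range = c(40, 95),
                             ec50_log10_range = c(-7.5, -5.5),
                             slope_range = c(0.8, 2),
                             interaction_strength = c(10, 40),
                             noise_sd = 5, response_range = c(-100, 120),
                             seed = 1L) {
  assert_that(n_drugs >= 2 && n_cells >= 1 && n_pairs >= 1 &&
                n_genes >= 1 && latent_dim >= 1, "counts must be positive")
  assert_that(n_drugs <= length(fixture_smiles()),
              sprintf("n_drugs must not exceed the %d packaged fixture SMILES",
                      length(fixture_smiles())))
  assert_that(n_pairs <= choose(n_drugs, 2),
              "n_pairs exceeds the number of distinct unordered pairs")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(all(dose_grid > 0), "dose_grid concentrations must be positive")
  assert_that(diff(range(emax_range)) >= 0 && diff(range(slope_range)) >= 0 &&
                min(slope_range) > 0, "invalid Hill parameter ranges")
  structure(list(
    n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
    n_pairs = as.integer(n_pairs), dose_grid = sort(dose_grid),
    n_genes = as.integer(n_genes), latent_dim = as.integer(latent_dim),
    emax_range = emax_range, ec50_log10_range = ec50_log10_range,
    slope_range = slope_range, interaction_strength = interaction_strength,
    noise_sd = noise_sd, response_range = response_range,
    seed = as.integer(seed)
  ), class = "generator_config")
}

hill_inhibition <- function(dose, emax, ec50, h) {
  emax * dose^h / (ec50^h + dose^h)
}

#' Unimodal interaction bump over the log-dose plane, peaking mid-grid
#' @noRd
interaction_bump <- function(d1, d2, grid) {
  mu <- mean(log10(grid))
  sg <- 0.75 * mean(diff(log10(grid)))
  exp(-((log10(d1) - mu)^2 + (log10(d2) - mu)^2) / (2 * sg^2))
}

#' Shared scaffolding: drugs, cells, latent factors, expression, Hill params
#'
#' With `cell_invariant_hill` the Hill parameters are drawn per drug and
#' shared across cell lines, so cell identity influences responses only
#' through the interaction term (used by the tagged ablation fixture).
#' @noRd
generate_backbone <- function(config, cell_invariant_hill = FALSE) {
  set.seed(config$seed)
  drug_ids <- sprintf("D%02d", seq_len(config$n_drugs))
  drugs <- data.frame(drug_id = drug_ids,
                      smiles = fixture_smiles()[seq_len(config$n_drugs)],
                      stringsAsFactors = FALSE)
  cell_ids <- sprintf("C%02d", seq_len(config$n_cells))
  Z <- matrix(stats::rnorm(config$latent_dim * config$n_cells),
              config$latent_dim, config$n_cells,
              dimnames = list(NULL, cell_ids))
  loadings <- matrix(stats::rnorm(config$n_genes * config$latent_dim),
                     config$n_genes, config$latent_dim) *
    stats::rlnorm(config$n_genes, meanlog = -0.8, sdlog = 0.8)
  gene_noise_sd <- stats::rlnorm(config$n_genes, meanlog = -1, sdlog = 0.6)
  expr <- loadings %*% Z +
    matrix(stats::rnorm(config$n_genes * config$n_cells), config$n_genes) *
    gene_noise_sd
  rownames(expr) <- sprintf("G%05d", seq_len(config$n_genes))
  # all unordered pairs, sampled
  all_pairs <- utils::combn(drug_ids, 2)
  sel <- sample.int(ncol(all_pairs), config$n_pairs)
  pairs <- t(all_pairs[, sel, drop = FALSE])
  # Hill parameters per (drug, cell), or per drug for the ablation fixture
  nd <- config$n_drugs; nc <- config$n_cells
  npar <- if (cell_invariant_hill) nd else nd * nc
  expand <- function(x) matrix(x, nd, nc, dimnames = list(drug_ids, cell_ids))
  emax <- expand(stats::runif(npar, config$emax_range[1], config$emax_range[2]))
  ec50 <- expand(10^stats::runif(npar, config$ec50_log10_range[1],
                                 config$ec50_log10_range[2]))
  slope <- expand(stats::runif(npar, config$slope_range[1],
                               config$slope_range[2]))
  list(drugs = drugs, cell_ids = cell_ids, Z = Z, expr = expr, pairs = pairs,
       emax = emax, ec50 = ec50, slope = slope)
}

#' Assemble measurements from a backbone and a gamma table
#' @noRd
assemble_dataset <- function(config, bk, gamma_tab) {
  grid <- config$dose_grid
  E_of <- function(d, c, dose) {
    hill_inhibition(dose, bk$emax[d, c], bk$ec50[d, c], bk$slope[d, c])
  }
  rows <- list()
  truth_rows <- list()
  gg <- expand.grid(dose1 = grid, dose2 = grid)
  for (p in seq_len(nrow(bk$pairs))) {
    d1 <- bk$pairs[p, 1]; d2 <- bk$pairs[p, 2]
    for (cc in bk$cell_ids) {
      e1 <- E_of(d1, cc, gg$dose1)
      e2 <- E_of(d2, cc, gg$dose2)
      bliss <- e1 + e2 - e1 * e2 / 100
      gam <- gamma_tab$gamma[gamma_tab$drug1_id == d1 &
                               gamma_tab$drug2_id == d2 &
                               gamma_tab$cell_id == cc]
      clean <- 100 - bliss - gam * interaction_bump(gg$dose1, gg$dose2, grid)
      rows[[length(rows) + 1]] <- data.frame(
        drug1_id = d1, drug2_id = d2, dose1 = gg$dose1, dose2 = gg$dose2,
        cell_id = cc, clean = clean, stringsAsFactors = FALSE)
    }
  }
  for (d in bk$drugs$drug_id) {
    for (cc in bk$cell_ids) {
      clean <- 100 - E_of(d, cc, grid)
      rows[[length(rows) + 1]] <- data.frame(
        drug1_id = d, drug2_id = NA_character_, dose1 = grid, dose2 = 0,
        cell_id = cc, clean = clean, stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  m$record_id <- sprintf("R%06d", seq_len(nrow(m)))
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(nrow(m), sd = config$noise_sd)
  } else {
    numeric(nrow(m))
  }
  raw <- m$clean + noise
  m$response <- clamp(raw, config$response_range[1], config$response_range[2])
  n_clipped <- sum(raw != m$response)
  truth <- data.frame(record_id = m$record_id, true_response = m$clean,
                      stringsAsFactors = FALSE)
  meas <- m[, c("record_id", "drug1_id", "drug2_id", "dose1", "dose2",
                "cell_id", "response")]
  rownames(meas) <- NULL
  list(
    dataset = synergy_dataset(bk$drugs, meas, bk$expr),
    truth = list(responses = truth, gamma = gamma_tab,
                 n_clipped = n_clipped, latent_cells = bk$Z),
    config = config
  )
}

#' Generate a synthetic combination-screening dataset with ground truth
#'
#' See the module header for the response model. The returned ground truth
#' holds the noise-free response of every record, the per-(pair, cell)
#' interaction strength gamma, the latent cell vectors, and the count of
#' responses clipped to `response_range`.
#'
#' @param config a [generator_config()].
#' @return list of class `synergy_simulation` with elements `dataset` (a
#'   `synergy_dataset`), `truth` and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  assert_that(inherits(config, "generator_config"),
              "config must be a generator_config")
  bk <- generate_backbone(config)
  # gamma: pair baseline modulated by a logistic function of the latent
  # cell vector, so part of the synergy signal is cell-intrinsic
  lo <- config$interaction_strength[1]
  hi <- config$interaction_strength[2]
  gam_pair <- stats::runif(nrow(bk$pairs), lo, hi)
  w <- matrix(stats::rnorm(nrow(bk$pairs) * config$latent_dim),
              nrow(bk$pairs), config$latent_dim)
  gamma_tab <- do.call(rbind, lapply(seq_len(nrow(bk$pairs)), function(p) {
    mod <- stats::plogis(drop(w[p, , drop = FALSE] %*% bk$Z))
    data.frame(drug1_id = bk$pairs[p, 1], drug2_id = bk$pairs[p, 2],
               cell_id = bk$cell_ids, gamma = gam_pair[p] * (0.5 + mod),
               tag = "mixed", stringsAsFactors = FALSE)
  }))
  structure(assemble_dataset(config, bk, gamma_tab),
            class = "synergy_simulation")
}

#' Generate the tagged ablation fixture
#'
#' Like [generate_dataset()], but each drug pair is tagged `drug1`, `drug2`
#' or `cell` and its interaction strength gamma depends exclusively on that
#' modality's latent factor: a per-drug susceptibility scalar for the drug
#' tags (constant across cells and the partner drug), or a per-cell scalar
#' derived from the latent cell vector for the cell tag (constant across
#' pairs). To keep the modality drivers identifiable, the monotherapy Hill
#' backbone is drawn per drug and shared across cell lines, so cell
#' identity affects responses only through the interaction term. Tags are
#' exported in the ground-truth gamma table.
#'
#' @param config a [generator_config()].
#' @return a `synergy_simulation`; `truth$gamma$tag` holds the construction
#'   tags.
#' @export
generate_ablation_fixture <- function(config = generator_config()) {
  assert_that(inherits(config, "generator_config"),
              "config must be a generator_config")
  bk <- generate_backbone(config, cell_invariant_hill = TRUE)
  hi <- config$interaction_strength[2]
  u_drug <- stats::setNames(stats::runif(config$n_drugs, 0.25, 1),
                            bk$drugs$drug_id)
  wc <- stats::rnorm(config$latent_dim)
  v_cell <- stats::setNames(stats::plogis(drop(wc %*% bk$Z) * 2),
                            bk$cell_ids)
  tags <- rep_len(c("drug1", "drug2", "cell"), nrow(bk$pairs))
  gamma_tab <- do.call(rbind, lapply(seq_len(nrow(bk$pairs)), function(p) {
    d1 <- bk$pairs[p, 1]; d2 <- bk$pairs[p, 2]
    g <- switch(tags[p],
                drug1 = rep(hi * u_drug[[d1]], config$n_cells),
                drug2 = rep(hi * u_drug[[d2]], config$n_cells),
                cell = hi * unname(v_cell))
    data.frame(drug1_id = d1, drug2_id = d2, cell_id = bk$cell_ids,
               gamma = g, tag = tags[p], stringsAsFactors = FALSE)
  }))
  structure(assemble_dataset(config, bk, gamma_tab),
            class = "synergy_simulation")
}

#' Write a simulation (dataset + ground-truth sidecars) to a directory
#' @param sim a `synergy_simulation`.
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset(sim$dataset, dir)
  utils::write.table(sim$truth$responses, file.path(dir, "truth_responses.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$gamma, file.path(dir, "truth_gamma.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read the ground-truth sidecars written by [write_simulation()]
#' @param dir directory.
#' @return list with `responses` and `gamma` data.frames.
#' @export
read_simulation_truth <- function(dir) {
  list(
    responses = utils::read.table(file.path(dir, "truth_responses.csv"),
                                  header = TRUE, sep = ",",
                                  stringsAsFactors = FALSE),
    gamma = utils::read.table(file.path(dir, "truth_gamma.csv"),
                              header = TRUE, sep = ",",
                              stringsAsFactors = FALSE)
  )
}
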
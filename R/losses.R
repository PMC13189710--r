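# Hybrid objective: mean squared error plus the uRank listwise ranking loss.
#
# The uRank loss operates on one response list (all dose combinations of a
# drug pair in one cell line). With true synergy values S and predictions O:
#   P = S e' - e S'          (pairwise true-score differences)
#   M = [P > 0]              (item i is ranked above item j)
#   T_i = sum_j M_ij exp(o_j)
#   L_i = ln(1 + T_i / exp(o_i))
#   G_i = gain(s_i)          (DCG-style 2^s - 1 on min-max-normalized s)
#   loss = sum_i L_i G_i / (n - 1)
# The implementation is loop-free over pairs and log-sum-exp stabilized; it
# must agree with the naive double-loop transcription to ~1e-9 relative.

normalize_list_scores <- function(s) {
  rng <- range(s)
  if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(0, length(s))
}

gain_values <- function(s_norm, gain_mode) {
  switch(gain_mode,
         exp = 2^s_norm - 1,
         linear = 2 * s_norm - 1,
         sr_abort(paste0("unknown gain_mode '", gain_mode, "'")))
}

#' uRank listwise ranking loss
#'
#' Gain-weighted listwise loss over one response list. True scores are
#' min-max normalized within the list before the gain computation; the mask
#' compares raw true scores with a strict `>` (optionally relaxed by a tie
#' tolerance `eps`, since replicate responses can differ by noise alone).
#' Lists of length 1 and fully tied lists return 0. Predictions may be
#' large: the log-sum-exp path keeps the value finite for |O| up to 1e3 and
#' beyond.
#'
#' @param s_true numeric vector of true synergy/response values.
#' @param s_pred numeric vector of predicted values, same length.
#' @param gain_mode `"exp"` (2^s - 1, default) or `"linear"` (2s - 1), both
#'   on the normalized true scores.
#' @param eps tie tolerance: |s_i - s_j| <= eps counts as tied (default 0).
#' @param grad if `TRUE`, also return the gradient with respect to `s_pred`.
#' @return the scalar loss, or (with `grad`) a list `(loss, grad)`.
#' @export
urank_loss <- function(s_true, s_pred, gain_mode = c("exp", "linear"),
                       eps = 0, grad = FALSE) {
  gain_mode <- match.arg(gain_mode)
  n <- length(s_true)
  assert_that(length(s_pred) == n && n >= 1,
              "s_true and s_pred must have equal positive length")
  assert_that(all(is.finite(s_true)) && all(is.finite(s_pred)),
              "scores must be finite")
  if (n == 1) {
    return(if (grad) list(loss = 0, grad = 0) else 0)
  }
  M <- outer(s_true, s_true, function(a, b) (a - b) > eps)
  G <- gain_values(normalize_list_scores(s_true), gain_mode)
  if (!any(M)) {
    return(if (grad) list(loss = 0, grad = numeric(n)) else 0)
  }
  # X_ij = o_j - o_i where masked, -Inf elsewhere
  X <- matrix(s_pred, n, n, byrow = TRUE) - matrix(s_pred, n, n)
  X[!M] <- -Inf
  row_max <- apply(X, 1, max)               # -Inf for empty rows
  m <- pmax(row_max, 0)
  sum_exp <- rowSums(exp(X - m))            # exp(-Inf - m) = 0
  log1pT <- m + log(exp(-m) + sum_exp)      # = log(1 + sum_j exp(x_ij))
  L <- log1pT
  loss <- sum(L * G) / (n - 1)
  if (!grad) return(loss)
  # dL_i/do_j = exp(x_ij - log1pT_i) for masked j; dL_i/do_i = -(1 - exp(-log1pT_i))
  W <- exp(X - log1pT)                      # n x n, zero where unmasked
  diag_term <- -(1 - exp(-log1pT))
  g <- (colSums(W * G) + diag_term * G) / (n - 1)
  list(loss = loss, grad = g)
}

#' Naive double-loop uRank loss (reference transcription)
#'
#' Literal line-by-line transcription of the listwise loss used as the
#' independent oracle in tests: plain `exp`, explicit loops over pairs.
#' Not numerically stabilized; for moderate prediction magnitudes only.
#'
#' @inheritParams urank_loss
#' @return scalar loss value.
#' @export
urank_loss_naive <- function(s_true, s_pred, gain_mode = c("exp", "linear"),
                             eps = 0) {
  gain_mode <- match.arg(gain_mode)
  n <- length(s_true)
  if (n == 1) return(0)
  G <- gain_values(normalize_list_scores(s_true), gain_mode)
  total <- 0
  for (i in seq_len(n)) {
    Ti <- 0
    for (j in seq_len(n)) {
      if ((s_true[i] - s_true[j]) > eps) Ti <- Ti + exp(s_pred[j])
    }
    Li <- log(1 + Ti / exp(s_pred[i]))
    total <- total + Li * G[i]
  }
  total / (n - 1)
}

#' Pairwise logistic ranking loss (ablation variant)
#'
#' Mean over ordered pairs (i, j) with s_i > s_j of
#' `log(1 + exp(-(o_i - o_j)))`; 0 when no such pair exists.
#'
#' @inheritParams urank_loss
#' @return the scalar loss, or (with `grad`) a list `(loss, grad)`.
#' @export
pairwise_ranking_loss <- function(s_true, s_pred, eps = 0, grad = FALSE) {
  n <- length(s_true)
  assert_that(length(s_pred) == n && n >= 1,
              "s_true and s_pred must have equal positive length")
  assert_that(all(is.finite(s_true)) && all(is.finite(s_pred)),
              "scores must be finite")
  M <- outer(s_true, s_true, function(a, b) (a - b) > eps)
  np <- sum(M)
  if (np == 0) {
    return(if (grad) list(loss = 0, grad = numeric(n)) else 0)
  }
  D <- matrix(s_pred, n, n) - matrix(s_pred, n, n, byrow = TRUE) # o_i - o_j
  # log(1 + exp(-d)) stabilized
  ll <- ifelse(D > 0, log1p(exp(-D)), -D + log1p(exp(D)))
  loss <- sum(ll[M]) / np
  if (!grad) return(loss)
  sig <- 1 / (1 + exp(D)) # sigmoid(-(o_i - o_j))
  sig[!M] <- 0
  g <- (colSums(sig) - rowSums(sig)) / np
  list(loss = loss, grad = g)
}

#' Hybrid regression + ranking objective
#'
#' `total = mse + lambda_rank * urank`, with the MSE computed on the
#' un-normalized targets and the uRank term on within-list normalized gains.
#'
#' @inheritParams urank_loss
#' @param lambda_rank nonnegative weight of the ranking term.
#' @param variant `"hybrid"` (default), `"mse_only"` (ranking term forced to
#'   weight 0) or `"pairwise"` (pairwise logistic loss replaces uRank).
#' @return a `loss_breakdown` list: `mse`, `urank`, `total`, `lambda_rank`
#'   and, with `grad`, the gradient with respect to `s_pred`.
#' @export
hybrid_loss <- function(s_true, s_pred, lambda_rank = 1,
                        gain_mode = c("exp", "linear"),
                        variant = c("hybrid", "mse_only", "pairwise"),
                        eps = 0, grad = FALSE) {
  gain_mode <- match.arg(gain_mode)
  variant <- match.arg(variant)
  assert_that(is.numeric(lambda_rank) && length(lambda_rank) == 1 &&
                lambda_rank >= 0, "lambda_rank must be nonnegative")
  n <- length(s_true)
  err <- s_pred - s_true
  mse <- mean(err^2)
  lam <- if (variant == "mse_only") 0 else lambda_rank
  rk <- if (lam == 0) {
    if (grad) list(loss = 0, grad = numeric(n)) else 0
  } else if (variant == "pairwise") {
    pairwise_ranking_loss(s_true, s_pred, eps = eps, grad = grad)
  } else {
    urank_loss(s_true, s_pred, gain_mode = gain_mode, eps = eps, grad = grad)
  }
  if (grad) {
    out <- list(mse = mse, urank = rk$loss, lambda_rank = lam,
                total = mse + lam * rk$loss,
                grad = 2 * err / n + lam * rk$grad)
  } else {
    out <- list(mse = mse, urank = rk, lambda_rank = lam,
                total = mse + lam * rk)
  }
  structure(out, class = "loss_breakdown")
}
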
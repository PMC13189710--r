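# Minimal dense/convolutional network machinery with manual
# backpropagation and a decoupled-weight-decay Adam optimizer. All math is
# base-R matrix code so forward passes are bitwise reproducible on CPU.

init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Forward pass of a dense stack (ReLU hidden; output linear or ReLU)
#' @return list(out, caches)
#' @noRd
mlp_forward <- function(X, layers, final_relu = FALSE) {
  nl <- length(layers)
  caches <- vector("list", nl)
  A <- X
  for (l in seq_len(nl)) {
    Z <- add_bias(A %*% layers[[l]]$W, layers[[l]]$b)
    caches[[l]] <- list(A_in = A, Z = Z)
    A <- if (l < nl || final_relu) pmax(Z, 0) else Z
  }
  list(out = A, caches = caches)
}

#' Backward pass of a dense stack
#' @return list(dX, grads) where grads[[l]] has W and b
#' @noRd
mlp_backward <- function(dOut, layers, caches, final_relu = FALSE) {
  nl <- length(layers)
  grads <- vector("list", nl)
  dA <- dOut
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl || final_relu) dA * (caches[[l]]$Z > 0) else dA
    grads[[l]] <- list(W = crossprod(caches[[l]]$A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(dX = dA, grads = grads)
}

#' Valid 1-D convolution (ReLU) over a batch of equal-length sequences
#'
#' `X` is (U*L_in) x C_in with sequence u occupying rows (u-1)*L_in + 1..L_in.
#' Implemented as im2col + matrix product.
#' @noRd
conv1d_forward <- function(X, L_in, U, W, b, k) {
  Cin <- ncol(X)
  Lp <- L_in - k + 1
  base <- rep((seq_len(U) - 1) * L_in, each = Lp) + rep(seq_len(Lp), U)
  Xcol <- matrix(0, U * Lp, k * Cin)
  for (j in seq_len(k)) {
    Xcol[, ((j - 1) * Cin + 1):(j * Cin)] <- X[base + (j - 1), , drop = FALSE]
  }
  Z <- add_bias(Xcol %*% W, b)
  list(A = pmax(Z, 0), Z = Z, Xcol = Xcol, base = base, Lp = Lp, Cin = Cin,
       L_in = L_in, U = U, k = k)
}

conv1d_backward <- function(dA, cache, W) {
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, W)
  dX <- matrix(0, cache$U * cache$L_in, cache$Cin)
  for (j in seq_len(cache$k)) {
    idx <- cache$base + (j - 1)
    dX[idx, ] <- dX[idx, ] +
      dXcol[, ((j - 1) * cache$Cin + 1):(j * cache$Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

#' Global max pooling over sequence positions
#' @noRd
pool_forward <- function(A, U, Lp, C) {
  out <- matrix(0, U, C)
  arg <- matrix(0L, U, C)
  for (u in seq_len(U)) {
    seg <- A[((u - 1) * Lp + 1):(u * Lp), , drop = FALSE]
    am <- max.col(t(seg), ties.method = "first")
    arg[u, ] <- am
    out[u, ] <- seg[cbind(am, seq_len(C))]
  }
  list(out = out, arg = arg)
}

pool_backward <- function(dOut, arg, U, Lp, C) {
  dA <- matrix(0, U * Lp, C)
  rows <- (rep(seq_len(U), times = C) - 1) * Lp + as.integer(arg)
  cols <- rep(seq_len(C), each = U)
  dA[cbind(rows, cols)] <- as.numeric(dOut)
  dA
}

# ---------------------------------------------------------------------------
# AdamW: adaptive moment estimation with decoupled weight decay.

adamw_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps)) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Accumulate a gradient contribution into a named gradient list
#' @noRd
grad_add <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}
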
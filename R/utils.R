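`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' @param msg message text.
#' @param class error subclass, e.g. "argument_error", "shape_error".
#' @noRd
sr_abort <- function(msg, class = "synergyrank_error") {
  stop(errorCondition(msg, class = unique(c(class, "synergyrank_error"))))
}

assert_that <- function(cond, msg, class = "argument_error") {
  if (!isTRUE(cond)) sr_abort(msg, class)
  invisible(TRUE)
}

#' Deterministic polynomial hash of an integer sequence
#'
#' Exact in double arithmetic: intermediate products stay below 2^53.
#' Used for fingerprint hashing and config digests; not cryptographic.
#'
#' @param x numeric vector (treated as integers).
#' @param seed starting value.
#' @return a nonnegative integer-valued double below 2^31 - 1.
#' @noRd
poly_hash <- function(x, seed = 17) {
  mod <- 2147483647
  h <- seed %% mod
  for (v in as.numeric(x)) {
    h <- (h * 31 + (v %% mod)) %% mod
  }
  h
}

#' Hash an arbitrary R object via its deparsed form
#' @noRd
object_hash <- function(obj) {
  txt <- paste(deparse(obj, control = c("keepNA", "keepInteger")), collapse = "\n")
  poly_hash(utf8ToInt(txt))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Seed derived from a base seed and a stream label, kept below 2^31
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer(poly_hash(c(seed, utf8ToInt(as.character(stream)))) %% 2147483629L)
}
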
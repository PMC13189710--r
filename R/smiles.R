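# SMILES handling: character-level tokenization for the CNN encoder, a
# minimal molecular-graph parser, and an ECFP-style hashed circular
# fingerprint used by the fingerprint ablation encoders.

#' Default SMILES token vocabulary
#'
#' Character-level vocabulary with the two-letter halogens `Cl` and `Br` as
#' single tokens. Index 0 is the reserved padding / null-drug token and
#' index 1 the unknown-character token; real tokens start at 2.
#'
#' @return named integer vector mapping token string to index.
#' @export
default_vocabulary <- function() {
  toks <- c(
    "Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
    "b", "c", "n", "o", "p", "s",
    "(", ")", "[", "]", "=", "#", "-", "+", ":", "/", "\\", ".",
    "@", "H", "%", as.character(0:9)
  )
  stats::setNames(c(0L, 1L, seq_along(toks) + 1L), c("<pad>", "<unk>", toks))
}

#' Tokenize a SMILES string to a fixed-length integer sequence
#'
#' Character-level tokens with `Cl`/`Br` kept whole; unknown characters map
#' to the reserved unknown token; the sequence is right-padded with the
#' padding token (or truncated) to `config$max_smiles_length`.
#'
#' @param smiles non-empty SMILES string.
#' @param config a [model_config()] carrying `vocabulary` and
#'   `max_smiles_length`.
#' @return integer vector of length `config$max_smiles_length`.
#' @export
tokenize_smiles <- function(smiles, config) {
  assert_that(is.character(smiles) && length(smiles) == 1 && !is.na(smiles) &&
                nzchar(smiles), "smiles must be a non-empty string")
  vocab <- config$vocabulary
  n <- nchar(smiles)
  toks <- integer(0)
  i <- 1
  while (i <= n) {
    two <- substr(smiles, i, i + 1)
    if (i < n && two %in% c("Cl", "Br")) {
      ch <- two
      i <- i + 2
    } else {
      ch <- substr(smiles, i, i)
      i <- i + 1
    }
    idx <- vocab[ch]
    toks <- c(toks, if (is.na(idx)) 1L else as.integer(idx))
  }
  L <- config$max_smiles_length
  out <- integer(L) # zeros = padding
  n_keep <- min(length(toks), L)
  out[seq_len(n_keep)] <- toks[seq_len(n_keep)]
  out
}

# ---------------------------------------------------------------------------
# Minimal SMILES graph parser. Covers the organic subset used by the packaged
# fixture drugs: aliphatic/aromatic C N O S P B + halogens, branches, ring
# closures (including %nn), explicit bonds - = # :, bracket atoms with charge
# and explicit H counts. Stereo markers are read as single bonds.

.element_z <- c(B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                Cl = 17, Br = 35, I = 53)
.element_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into an atom/bond graph
#'
#' @param smiles SMILES string over the supported organic subset.
#' @return list with `atoms` (data.frame: element, aromatic, charge,
#'   explicit_h) and `bonds` (data.frame: a1, a2, order; aromatic bonds have
#'   order 1.5).
#' @keywords internal
parse_smiles <- function(smiles) {
  assert_that(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
              "smiles must be a non-empty string", "chemistry_error")
  elem <- character(0); arom <- logical(0); chg <- integer(0); exh <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0)
  prev <- NA_integer_
  stack <- integer(0)
  ring <- list()
  pend <- NA_real_ # pending explicit bond order
  i <- 1
  n <- nchar(smiles)

  add_atom <- function(e, ar, charge, hcount) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    chg[length(chg) + 1L] <<- charge
    exh[length(exh) + 1L] <<- hcount
    id <- length(elem)
    if (!is.na(prev)) {
      ord <- if (!is.na(pend)) pend else if (arom[prev] && ar) 1.5 else 1
      b1 <<- c(b1, prev); b2 <<- c(b2, id); bord <<- c(bord, ord)
    }
    pend <<- NA_real_
    prev <<- id
    invisible(id)
  }
  close_ring <- function(key) {
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, ord = pend)
      pend <<- NA_real_
    } else {
      other <- ring[[key]]
      ord <- if (!is.na(pend)) pend else if (!is.null(other$ord) && !is.na(other$ord)) other$ord
      else if (arom[prev] && arom[other$atom]) 1.5 else 1
      b1 <<- c(b1, other$atom); b2 <<- c(b2, prev); bord <<- c(bord, ord)
      ring[[key]] <<- NULL
      pend <<- NA_real_
    }
  }

  while (i <= n) {
    ch <- substr(smiles, i, i)
    two <- substr(smiles, i, i + 1)
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, 0L, NA_integer_); i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_); i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_); i <- i + 1
    } else if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      assert_that(j > 0, "unclosed bracket atom in SMILES", "chemistry_error")
      body <- substr(smiles, i + 1, i + j - 2)
      i <- i + j
      m <- regmatches(body, regexec(
        "^([0-9]*)(Cl|Br|[BCNOPSFI]|[bcnops])(@{0,2})(H([0-9]?))?([+-][0-9]?|\\++|-+)?$",
        body))[[1]]
      assert_that(length(m) > 0, paste0("unsupported bracket atom [", body, "]"),
                  "chemistry_error")
      e <- m[3]
      ar <- e %in% c("b", "c", "n", "o", "p", "s")
      hc <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      cg <- 0L
      if (nzchar(m[7])) {
        sign <- if (substr(m[7], 1, 1) == "+") 1L else -1L
        num <- gsub("[+-]", "", m[7])
        cg <- sign * if (nzchar(num)) as.integer(num) else nchar(m[7])
      }
      add_atom(toupper(e), ar, cg, hc)
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      assert_that(length(stack) > 0, "unbalanced parenthesis in SMILES",
                  "chemistry_error")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (ch == "-") { pend <- 1; i <- i + 1
    } else if (ch == "=") { pend <- 2; i <- i + 1
    } else if (ch == "#") { pend <- 3; i <- i + 1
    } else if (ch == ":") { pend <- 1.5; i <- i + 1
    } else if (ch %in% c("/", "\\")) { pend <- 1; i <- i + 1
    } else if (ch == ".") { prev <- NA_integer_; pend <- NA_real_; i <- i + 1
    } else if (ch == "%") {
      key <- substr(smiles, i + 1, i + 2)
      close_ring(key); i <- i + 3
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1
    } else {
      sr_abort(paste0("unsupported SMILES character '", ch, "'"), "chemistry_error")
    }
  }
  assert_that(length(ring) == 0, "unclosed ring bond in SMILES", "chemistry_error")
  assert_that(length(stack) == 0, "unbalanced parenthesis in SMILES",
              "chemistry_error")
  assert_that(length(elem) > 0, "SMILES contains no atoms", "chemistry_error")
  list(
    atoms = data.frame(element = elem, aromatic = arom, charge = chg,
                       explicit_h = exh, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord)
  )
}

#' ECFP-style hashed circular fingerprint
#'
#' Morgan-iteration fingerprint over the parsed molecular graph: each atom
#' starts from an invariant built from (atomic number, degree, summed bond
#' order, charge, aromaticity, estimated hydrogen count), neighborhood
#' invariants are rehashed out to `radius`, and every substructure
#' identifier is folded into `nbits` bits. The hydrogen count is estimated
#' from standard valences, so identifiers are ECFP-like rather than
#' bit-compatible with a specific toolkit; they are invariant to the SMILES
#' spelling of the same graph.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius (default 2).
#' @param nbits folded length (default 1024).
#' @return integer 0/1 vector of length `nbits`; attribute `n_features`
#'   gives the number of distinct substructure identifiers before folding.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, nbits = 1024) {
  g <- parse_smiles(smiles)
  na <- nrow(g$atoms)
  nbrs <- vector("list", na)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]; o <- g$bonds$order[b]
      nbrs[[a1]] <- rbind(nbrs[[a1]], c(a2, o))
      nbrs[[a2]] <- rbind(nbrs[[a2]], c(a1, o))
    }
  }
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bondsum <- vapply(nbrs, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  z <- .element_z[g$atoms$element]
  val <- .element_valence[g$atoms$element]
  hcnt <- ifelse(is.na(g$atoms$explicit_h),
                 pmax(0, val + pmin(g$atoms$charge, 0) +
                        ifelse(g$atoms$element %in% c("N", "P"),
                               pmax(g$atoms$charge, 0), 0) - ceiling(bondsum)),
                 g$atoms$explicit_h)
  inv <- vapply(seq_len(na), function(a) {
    poly_hash(c(z[a], degree[a], round(bondsum[a] * 2), g$atoms$charge[a],
                as.integer(g$atoms$aromatic[a]), hcnt[a]))
  }, numeric(1))
  feats <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(na), function(a) {
      if (is.null(nbrs[[a]])) return(poly_hash(c(r, inv[a])))
      pairs <- cbind(round(nbrs[[a]][, 2] * 2), inv[nbrs[[a]][, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      poly_hash(c(r, inv[a], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    inv <- inv_new
    feats <- c(feats, inv)
  }
  feats <- unique(feats)
  bits <- integer(nbits)
  bits[(feats %% nbits) + 1] <- 1L
  structure(bits, n_features = length(feats))
}

#' Packaged fixture SMILES strings
#'
#' Thirty-two short, valid drug-like SMILES strings used by the synthetic
#' generator so that datasets can be produced without any chemistry
#' download.
#'
#' @return character vector of SMILES.
#' @export
fixture_smiles <- function() {
  c(
    "CC(=O)OC1=CC=CC=C1C(=O)O",          # aspirin
    "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",      # caffeine
    "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",     # ibuprofen
    "C1=CC=C(C=C1)C(=O)O",               # benzoic acid
    "CC(=O)NC1=CC=C(O)C=C1",             # paracetamol
    "C1=CC=C2C(=C1)C=CC=C2O",            # naphthol
    "CN(C)CCC1=CC=C(Cl)C=C1",            # chloro phenethylamine
    "COC1=CC=C(CCN)C=C1",                # methoxyphenethylamine
    "CC1=CC(=O)C=CC1=O",                 # methylquinone
    "C1CCNC(=O)C1",                      # valerolactam
    "OC(=O)CCC(=O)O",                    # succinic acid
    "NC1=NC=NC2=C1N=CN2",                # adenine
    "OC1=NC=NC2=C1N=CN2",                # hypoxanthine
    "CC(N)C(=O)O",                       # alanine
    "NCCC1=CNC2=CC=CC=C12",              # tryptamine
    "OCC1=CC=CO1",                       # furfuryl alcohol
    "CSCCC(N)C(=O)O",                    # methionine
    "ClC1=CC=C(C=C1)C(=O)NC2=CC=CC=C2",  # chlorobenzanilide
    "BrCC1=CC=CC=C1",                    # benzyl bromide
    "CC(C)(C)NCC(O)C1=CC(=CC=C1)O",      # beta-agonist fragment
    "O=C(O)C1=CC=CN=C1",                 # nicotinic acid
    "CN1CCC(CC1)OC(=O)C2=CC=CC=C2",      # benzoate ester
    "FC1=CC=C(C=C1)C2=NC=CC=C2",         # fluorophenylpyridine
    "O=S(=O)(N)C1=CC=C(N)C=C1",          # sulfanilamide
    "CCN(CC)CCNC(=O)C1=CC=C(N)C=C1",     # procainamide
    "CC1=NC=C(CO)C(=C1O)CN",             # pyridoxamine-like
    "OCC(O)C1=CC=CC=C1",                 # phenylglycol
    "CC(C)NCC(O)COC1=CC=CC2=CC=CC=C12", # propranolol
    "N#CC1=CC=C(C=C1)C(=O)O",            # cyanobenzoic acid
    "CC1=CC=C(C=C1)S(=O)(=O)NC(=O)NN2CCCCC2", # sulfonylurea-like
    "COC(=O)C1=CC=CC=C1N",               # methyl anthranilate
    "CCOC(=O)C1=CC=C(O)C=C1"             # ethyl paraben
  )
}
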
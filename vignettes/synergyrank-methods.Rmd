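---
title: "Ranking drug-combination dose responses: models and methods"
author: "synergyrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug-combination dose responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices, and the design
decisions behind `synergyrank`, in the spirit of a methods supplement. It
states no empirical results beyond what the package's tests and
`scripts/acceptance.R` compute.

## 1. Data model

The atomic observation is a measurement record
`(drug1, drug2, dose1, dose2, cell, response)`: percent growth of one cell
line under a pair of molar concentrations (100 = untreated growth, 0 =
full growth inhibition, negative = killing). A *monotherapy* record has an
empty second-drug slot, encoded as `drug2 = NA` and `dose2 = 0`; the two
conditions are kept equivalent by normalization at load time, so a single
prediction head serves both record kinds. A *response list* collects all
records sharing one (unordered drug pair, cell line) combination — one
dose-response matrix — and is the unit over which the listwise loss and
the within-list evaluation metrics operate. The drug-pair key is
unordered, because the pair-exclusion scenarios must treat `(A, B)` and
`(B, A)` as the same combination.

Gene expression enters as a genes × cell-lines matrix; only the `k` genes
with the largest *population* variance across cell lines are kept
(default 1000). Ties in variance are broken by input row order so the
selection is deterministic.

## 2. Encoders

**Drugs.** SMILES strings are tokenized at character level with `Cl`/`Br`
as single tokens, padded to a fixed length, and embedded; two valid 1-D
convolutions (kernel 5) with ReLU, global max pooling and a dense layer
yield a 128-dimensional embedding. The all-padding sequence is the *null
drug* that fills the monotherapy slot; its embedding is learned like any
other. The encoder output is ReLU-activated, giving a sparse nonnegative
embedding in which a zero coordinate means "feature inactive" — this
matters for the attribution layer (§6), whose baseline and ablations are
zero vectors.

**Doses.** Concentrations are first scaled to encoder positions; the
default is `r = -log10(molar)`, so the screen's typical 1e-8..1e-4 M range
maps to positions 8..4, and the empty monotherapy slot maps to 0. Raw
molar values (~1e-9..1e-4) would make any fixed-frequency encoding
numerically degenerate, which is why the scaling is applied first; minmax
(onto [0, 100]) and raw modes exist for sensitivity checks. The encoding
of a position `r` is the 64-vector with components `sin(r · 10^(-4i/64))`
for even `i` and `cos(r · 10^(-4i/64))` for odd `i`, `i = 0..63`. Two
points were deliberately resolved: the exponent is read as the
multiplicative frequency `10000^(-i/64)` (the standard positional-encoding
family), and the index `i` is used literally rather than paired as
`2⌊i/2⌋` — the even/odd components therefore do *not* share frequencies.
All components lie in [−1, 1] and the frequency is strictly decreasing in
`i`; both are asserted in tests. The ablation variant replaces this with a
learned affine map of the scalar position to 64 dimensions.

**Cell lines.** The selected-gene expression vector passes through an MLP
(one hidden layer by default) to a 256-dimensional ReLU-activated
embedding. The trainer standardizes each gene to zero mean and unit
variance over the cell lines and stores the transform on the model, so
prediction applies the identical scaling.

**Head.** The five embeddings are concatenated
(128 + 128 + 64 + 64 + 256 = 640) and passed through a dense stack to a
single output. Drug-order symmetry is *not* enforced: the head may use
slot identity. Presets: `"desk"` (32-wide CNN, 64/128/64 hidden widths)
and `"paper"` (64-wide CNN, 512-wide hidden layers).

**Fingerprint variants.** For the drug-encoder ablation, an ECFP-style
hashed circular fingerprint (radius 2, 1024 bits) is computed from a
minimal SMILES graph parser: atom invariants combine atomic number,
degree, bond-order sum, charge, aromaticity and an estimated implicit
hydrogen count; neighborhoods are rehashed per radius and folded modulo
the bit length. Identifiers are invariant to the SMILES spelling of the
same graph (asserted against hand-written alternative spellings), but the
hydrogen estimate is approximate, so bits are not interchangeable with any
specific toolkit's ECFP — hence "ECFP-style" throughout. The `projected`
mode maps the bit vector to 128 dimensions through a learned affine layer;
the `folded` mode feeds the raw 1024-bit vector to the head directly.

## 3. The hybrid objective

For one response list with true values `S`, predictions `O` and length
`n`:

- `P = S e' − e S'`, so `P_ij = s_i − s_j`;
- mask `M_ij = 1` iff `P_ij > 0` (strict; an optional tie tolerance ε
  treats `|s_i − s_j| ≤ ε` as tied, because replicate responses can differ
  by noise alone — default ε = 0);
- `T_i = Σ_j M_ij exp(o_j)`, `L_i = ln(1 + T_i / exp(o_i))`;
- gains `G_i = 2^{s̃_i} − 1` on the within-list min-max-normalized true
  values `s̃` (the printed `(2s−1)` is read as the DCG-family exponential
  gain; a literal linear reading `2s̃ − 1` is available as
  `gain_mode = "linear"` for sensitivity analysis — normalization makes
  both readings bounded);
- `loss = Σ_i L_i G_i / (n − 1)`; lists of length 1 (monotherapy) return
  0 and train only the regression term.

The implementation is loop-free over pairs and log-sum-exp shifted, so it
is finite for prediction magnitudes up to 1e3 and beyond; tests require
agreement with a literal double-loop transcription to 1e-9 relative on
random lists including ties and singletons. The mask is built from *true*
values only — the surrounding prose description ("incorrect order between
predictions") conflicts with the formulas, and the formulas are taken as
authoritative. Analytic gradients are exercised against finite differences.

The full objective is `total = mse + λ · urank` with `λ = 1` by default
(the mixing weight is otherwise unstated); `mse` is computed on the
(globally scaled, see §4) targets, *not* on the within-list-normalized
values used for the gains. The pairwise ablation variant replaces the
listwise term with the mean logistic pairwise loss
`mean_{s_i > s_j} ln(1 + e^{-(o_i - o_j)})`.

## 4. Training

Batches are assembled from whole response lists (a list larger than the
batch size becomes its own batch) because the listwise term is undefined
across partial lists; the batch objective is the mean of the per-list
totals. The optimizer is Adam with decoupled weight decay. Reference
configuration (`"paper"` preset): 10 000 epochs, batch 256, learning rate
1e-4, weight decay 1e-5. The `"desk"` preset (400 epochs, learning rate
3e-3) is sized so a benchmark-scale run takes about a minute on one CPU.

Responses are min-max scaled to [0, 1] over the training set before
fitting, and predictions are mapped back to percent growth afterwards.
This is not cosmetic: the listwise term exponentiates predictions, so on
the raw percent-growth scale (|o| up to ~100) correctly ordered pairs
saturate to zero loss and the ranking signal degenerates to ~1% of the
objective — in single-precision frameworks `exp(100)` overflows outright.
With O(1) outputs the two terms are commensurate at λ = 1. Pearson and
Spearman metrics are invariant to this affine transform. The head's
output bias is initialized to the mean training target, and early
stopping is off by default (the reference trains a fixed epoch count); a
patience option exists for desk-scale experimentation.

Everything is seeded: parameter initialization through the model config,
shuffling through the training config, fold assignment through the split
seed. Two runs with equal seeds agree bitwise on CPU.

## 5. Scenarios and evaluation

- **S1** — within every combination matrix, entries are assigned uniformly
  at random to the five folds (stratified per matrix, so each matrix
  appears in every fold's test set); the held-out fraction is 1/5, which
  the source protocol leaves unstated.
- **S2** — unordered drug pairs are partitioned into five groups; all
  matrices of held-out pairs, in all cell lines, form the test set. The
  partition is purely random (no tissue stratification).
- **S3** — S2's partition with every monotherapy record removed from
  training.

Monotherapy records stay in the S1/S2 training sides: S3's separate
definition implies they were present otherwise. Fold assignment depends
only on (dataset, scenario family, seed), so the five test sets partition
the eligible records; these contracts are property-tested over random
datasets.

Evaluation reports Pearson r between predicted and observed responses over
test records (the correlation convention of the comparable baselines; the
upstream benchmark leaves its metric unnamed), the mean within-list
Spearman over test lists with at least two entries and non-constant truth,
and NDCG@k with exponential gains on normalized truth. A constant
prediction vector makes correlation undefined; it is reported as 0 with a
degeneracy flag.

## 6. Attribution and driver classification

For a selected sample, integrated gradients attribute the prediction over
the fused 640-dimensional embedding against a zero baseline:
`Attr_i = (x_i − x'_i) · mean_α ∂f/∂x_i`, midpoint Riemann rule with 64
path points by default (the discretization is otherwise unstated; the
completeness residual `|Σ Attr − (f(x) − f(x'))|` is reported, is exact
for a linear head, and shrinks as the step count grows). Attribution runs
on the embeddings, not on raw tokens, and dose modalities are attributed
but never ablated.

Scores are *oriented* before use: `direction = -1` (the default in the
pipeline) negates percent-growth-style outputs so that larger always means
more synergistic; the orientation and normalization are recorded in every
output. Triplet selection takes each (drug1, drug2, cell)'s maximum
predicted score over its dose grid, min-max normalizes the maxima across
triplets (the confidence threshold's scale is otherwise ambiguous; the
model's normalized output scale is the natural choice), and keeps those
strictly above the threshold (default 0.8), ranked, truncated at top-k
(default 50).

Critical dimensions of a modality are those with
`|Attr_i| > fraction · max_j |Attr_j|` (strict, fraction 0.6); the arg-max
dimension is force-included so the set is non-empty whenever the
attribution is non-zero. Three forward passes zero the critical dimensions
of drug 1, drug 2 and cell in turn; `Δ_m = original − ablated_m` on the
oriented scale. The label is the modality with the largest Δ when it
exceeds the runner-up by `dominance_margin · |original|` (default 0.1 —
the balanced category is otherwise defined only qualitatively), else
Balanced. The margin, like every interpretation parameter, is recorded in
the reports.

## 7. Synthetic data

The generator emulates an ALMANAC-shaped screen: per-(drug, cell) Hill
monotherapy curves `E(d) = Emax d^h / (EC50^h + d^h)` (Emax 40–95%, EC50
log-uniform within the grid, slope 0.8–2); Bliss independence on the
percent-growth scale as the combination backbone
(`100 − (E1 + E2 − E1·E2/100)`); and an interaction term
`γ_pc · g(d1, d2)` with a Gaussian bump `g` in log-dose space peaking
mid-grid — so identifying the optimal dose region is a real task — and a
per-(pair, cell) strength γ whose cell component is a logistic function of
a latent cell vector. The same latent vectors generate the expression
matrix through random loadings with heteroscedastic per-gene noise, so
variance-based gene filtering and the cell encoder have real signal to
find. Responses are clipped to [−100, 120] (clips are counted), Gaussian
noise is configurable (default sd 5 percent-growth points; the benchmark
uses 0), and the ground truth (noise-free response per record, γ per pair
and cell, latent vectors) ships as a sidecar next to the dataset files.
Drugs are drawn from 32 packaged drug-like SMILES strings, so nothing is
downloaded.

What the generator does *not* emulate: assay plate artefacts, replicate
structure, dose-grid irregularities, heavy-tailed response noise, or any
relationship between a drug's structure and its potency (Hill parameters
are independent of the SMILES). Passing tests on this generator therefore
demonstrates that the machinery works under a controlled, well-specified
signal — not that the architecture's real-data advantages transfer.

The **tagged ablation fixture** exists to validate the driver classifier.
Each pair is tagged `drug1`, `drug2` or `cell`, and its γ depends
exclusively on that modality's latent factor (a per-drug susceptibility
scalar, constant across cells and partner drugs, or a per-cell scalar
shared across pairs). Two construction choices make the tags identifiable
at all: the fixture's Hill parameters are drawn per drug and shared across
cell lines, so cell identity enters the response only through the
interaction term; and the validation experiment configures weak
monotherapy (Emax 10–30) with strong interaction (γ up to 60), because a
drug's ablation Δ inevitably contains its monotherapy contribution and
would otherwise swamp the tagged signal. A remaining structural limit is
worth stating: within a single pair, a drug1-driven and a drug2-driven
constant γ are observationally equivalent (the model can attribute a
memorized pair-level synergy to either slot); only drugs recurring across
pairs with consistent susceptibility provide the disambiguating signal.
The acceptance check accordingly asks for tag recovery above the 1/3
chance rate over several seeds, not for high accuracy.

## 8. Problem sizes and budgets

The package's own benchmarks are desk-scale by design: the ranking
benchmark uses 25 pairs × 4 cell lines on 4×4 grids (100 combination
lists, 1792 records), 300 genes filtered to 100, and 400-epoch desk
training — about a minute per run on one CPU; the fixture experiment uses
18 pairs × 6 cell lines. The acceptance suite shares trained models
between checks, and each configuration is fitted once per seed. The
reference-scale configuration (1000 genes, 10 000 epochs, 512-wide
layers) is expressed by the `"paper"` presets and runs unchanged, just
longer.

## 9. Known limitations

- No pretrained weights, attention mechanisms, or graph-based molecular
  encoders; no triplet or NDCG-direct objectives.
- The SMILES grammar covered by the fingerprint parser is the organic
  subset used by the packaged fixtures (brackets, charges, ring closures,
  aromatic lowercase; no isotopes-as-mass semantics, no multi-fragment
  reaction strings).
- Drug-order symmetry is not enforced; swapped-slot augmentation is a
  config flag away but off by default.
- The driver classifier's drug1/drug2 distinction is only weakly
  identifiable (see §7); its labels on real screens should be read as
  model explanations, not biological ground truth.
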
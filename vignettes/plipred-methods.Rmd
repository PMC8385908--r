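---
title: "Methods: k-mer featurization and the two-branch ensemble"
author: "plipred maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer featurization and the two-branch ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plipred)
```

## The prediction problem

Long non-coding RNAs (lncRNAs) act largely through physical association
with RNA-binding proteins. Experimentally mapping which of a plant's
lncRNAs bind which proteins is slow and expensive, and plant lncRNAs are
poorly conserved, so models trained on animal data transfer badly.
`plipred` frames the question as binary classification: given an (RNA,
protein) pair, predict interacting (1) or non-interacting (0) from the
two sequences and, optionally, their secondary structures. Reference
collections for this task have a characteristic shape — a few dozen
protein chains paired many-to-many with a larger set of lncRNA chains,
with as many sampled negative pairs as curated positives — and the
synthetic generator below reproduces exactly that shape.

## Featurization

Sequences of wildly different lengths (tens to thousands of residues)
are mapped to fixed-length vectors of normalized k-mer frequencies.
One-hot or positional encodings are deliberately avoided: at these
lengths they are enormous and sparse.

* **RNA sequence** — input is canonicalized to the DNA alphabet (U
  becomes T), and k-mers for k = 1..4 are counted, giving
  4 + 16 + 64 + 256 = **340** features.
* **Protein sequence** — the 20 amino acids are first collapsed onto
  seven physicochemical groups (conjoint-triad style): {V,G,A},
  {F,P,L,I}, {S,Y,M,T}, {H,N,W,Q}, {R,K}, {E,D}, {C}. k = 1..3 over the
  7-letter alphabet gives 7 + 49 + 343 = **399** features. Without the
  reduction the 3-mer space alone would have 8000 cells — far too many
  for these sample sizes.
* **RNA structure** (optional) — a dot-bracket string is collapsed to
  unpaired/paired; k = 1..4 over two symbols adds 2 + 4 + 8 + 16 =
  **30** features, for a 370-dimensional RNA vector.
* **Protein structure** (optional) — a three-state helix/sheet/coil
  string; k = 1..3 over three symbols adds 3 + 9 + 27 = **39** features,
  for a 438-dimensional protein vector.

Each k-block is normalized by its window count L − k + 1, so every block
of a sequence with L ≥ k is an empirical probability distribution (it
sums to 1). This per-block normalization is a deliberate choice: it is
length-invariant and keeps all features on a common scale. Sequences
shorter than k (possible only below 4 residues, well under the lengths
seen in practice) yield an all-zero block rather than an error. Within a
block, k-mers are ordered lexicographically with a fixed alphabet order
(A\<C\<G\<T; groups 1..7; unpaired\<paired; H\<E\<C). Structure blocks
are appended after the sequence blocks of the same molecule.

```{r dims}
featureLayout("rna", withStructure = TRUE)
```

## The two branches

Both branches consume a pair of feature vectors (RNA, protein), embed
each molecule separately, concatenate the embeddings, and classify with
a fully-connected head ending in a 2-way softmax; both are trained with
binary cross-entropy by backpropagation. Before training, every feature
is min–max scaled to [0, 1] using the training rows (the scaler is
stored in the model); this keeps inputs inside the sigmoid's useful
range and gives the narrow-variance k-mer frequencies usable dynamic
range.

**Stacked denoising autoencoder (SDAE) branch.** Each molecule tower is
a stack of three sigmoid layers (defaults 256 → 128 → 64). A layer's
encoder is y = s(Wx + b) and its decoder z = s(W′y + b′) with s the
logistic sigmoid; the reconstruction z only ever approximates x.
Pretraining is greedy and layer-wise: each layer reconstructs its
*clean* input from a corrupted copy (minimizing squared reconstruction
error), and its clean encoding becomes the next layer's input. A fresh
corruption is drawn every minibatch. Two corruption modes are
implemented — masking (zero a component with probability `noiseLevel`)
and additive Gaussian noise — with masking at 0.2 as the default. After
pretraining, the towers plus head are fine-tuned end to end.

**Convolutional (CNN) branch.** Each feature vector is treated as a
length-D, one-channel 1-D signal passed through three ReLU convolutions
(defaults 64/32/16 filters, kernel 5) with width-2 max pooling after the
first and second, then flattened. A k-mer vector has no intrinsic
spatial order, so the convolution is best understood as a learned,
heavily weight-shared projection rather than a motif detector; it
nevertheless extracts a complementary representation in practice, and
the layout keeps adjacent k-mers (which share prefixes) adjacent in the
signal.

**Optimization.** Both branches train with Adam first (quick
convergence; default 30 epochs at 1e-3) and plain SGD afterwards
(fine-tuning; default 20 epochs at 1e-4). Early stopping watches the
cross-entropy on a stratified 15% validation holdout across both
phases: when it fails to improve for `patience` (default 5) consecutive
epochs, training stops and the best weights are restored. Dropout 0.5
is applied to the fully-connected head's hidden layers only, and is
disabled at inference, so prediction is deterministic. All
initialization, shuffling, corruption and dropout derive from
`TrainConfig@seed`: identical seeds give identical models.

**Ensemble combiner.** The two branches' class-probability pairs are
concatenated (4 inputs) and fed to a single softmax layer (4 → 2)
trained with full-batch Adam on the same labels. By default the
combiner is fit on in-sample branch predictions; a held-out
(stacking-flavoured) variant is available via
`trainEnsemble(..., combinerData = "heldout")`. The head of each branch
consumes both molecules' embeddings jointly — the "cross-prediction"
reading of a two-tower architecture.

Layer widths, filter counts, kernel size, learning rates and epoch
budgets were not dictated by the problem and are exposed in
`trainConfig()`; the defaults above are conventional middle-of-the-road
choices for input dimensions of a few hundred.

## Evaluation

`classMetrics()` implements accuracy, precision, sensitivity,
specificity and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

the standard form of the coefficient. A metric whose denominator is
zero is reported as `NA` — an explicit "undefined" — never silently 0,
so aggregate means are not quietly inflated. A probability exactly at
the decision threshold classifies positive. `aucScore()` is the
rank-based (Mann–Whitney) area under the ROC curve with midrank tie
handling. The CLI prints metrics as percentages, matching the field's
reporting convention; internally everything is a fraction.

Because no canonical train/test protocol exists for the benchmark
collections, the package's default experiment is **pair-level
stratified 5-fold cross-validation** (`crossValidate()`): a fresh
ensemble per fold, metrics per fold plus mean ± sd, everything seeded.
`ablationStructure()` repeats the cross-validation with and without the
structure blocks under identical fold assignments and seeds, producing
a two-row comparison. Note that pair-level splitting lets the same
molecule (with different partners) appear on both sides of a split;
molecule-level generalization is a different, harder question that this
protocol does not measure.

## The synthetic generator

`simConfig()` / `simulateDataset()` produce datasets with the benchmark
shape: defaults of 200 RNAs × 20 proteins and 400 positive + 400
negative pairs, sequence lengths drawn uniformly from 50–500 (kept at
the low end of the real collections' 20–3000 range so that default runs
are quick; both ranges are configurable). Residues are i.i.d. uniform —
a sticky first-order Markov option exists but is off by default —
which is sufficient for exercising the mechanics, though it reproduces
neither codon structure, GC skew nor real binding motifs.

Structures are synthetic too: RNA dot-brackets come from a stochastic
left-to-right walk that always balances its parentheses; protein
H/E/C strings are geometric runs (mean length 5). They emulate the
*format* of folding and secondary-structure predictors, not their
physics.

Labels carry a **planted logistic signal** in the very feature space
the encoders produce: a fixed set of k-mer columns (four RNA, four
protein by default) is standardized across each store, combined with
±1 coefficients, scaled by `signalStrength`, and pushed through a
logistic to give every possible pairing an interaction probability. The
logistic is centered at the (1 − n_pos/n_total) quantile of the scores
so that high-probability pairings are about as abundant as the
positives to be drawn; without this offset, the uniformly-sampled
negatives would contain so many high-score pairs that even the true
rule could not separate the classes. Positives are then drawn without
replacement weighted by that probability, and negatives uniformly from
the remaining pairings — mirroring how the real collections construct
negatives by random pairing with positives removed. At
`signalStrength = 0` all probabilities are 0.5 and the labels are
exchangeable; `oracleAccuracy()` evaluates the true rule itself and
serves as the (near-)Bayes reference that trained models are compared
against. Because the planted rule lives in the encoder's own feature
space, recovering it certifies the whole encode → train → predict path,
which is precisely what the test suite uses it for. What it does *not*
certify is performance on real data, where the signal is not a sparse
linear function of k-mer frequencies.

## Numerical and design notes

* Softmax rows are computed with a max-shift; cross-entropy clamps
  probabilities at 1e-12; training aborts on non-finite losses.
* Weights use Glorot-uniform initialization; biases start at zero.
* Max-pooling ties keep the earlier position; odd trailing elements are
  dropped.
* Validation loss must improve by more than 1e-8 to reset the early
  stopping counter.
* The convolution's unfold/fold, fused bias+ReLU and pooling run in
  compiled code (`src/conv.cpp`); the heavy contractions are BLAS
  matrix products. Forward/backward passes are verified against
  finite-difference gradients in the test suite.
* Feature scaling is fitted on all rows passed to `trainBranch()`
  (training plus early-stopping holdout); test folds in
  cross-validation never touch it.
* Problem sizes in the test suite: unit tests use 400-pair datasets
  with narrow layers; the acceptance checks run the full default
  configuration (800 pairs, 5-fold cross-validation) once with and once
  with permuted labels.

## Known limitations

* Pure-R + small-kernel training is single-threaded and sized for
  datasets of hundreds to a few thousand pairs, not for the largest
  collections (tens of thousands of pairs) at default epoch budgets.
* The seven-group map places tryptophan (W) in the {H,N,W,Q} group;
  published listings of this grouping sometimes print the ambiguous
  token "Tpr" there, which this package reads as Trp — any other
  reading would leave W unmapped and the partition incomplete.
* Pair-level cross-validation measures interpolation over known
  molecules more than generalization to unseen ones.
* The generator's i.i.d. sequences make the planted task easier than
  real biology; passing the recovery tests demonstrates correctness of
  the pipeline, not expected field performance.
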
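---
title: "Methods: 2Lk encoding, the KDeep predictors, and motif recovery"
author: "kdeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2Lk encoding, the KDeep predictors, and motif recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdeep)
```

This vignette records the model, its assumptions, the numerical choices,
and the design decisions behind them — the things a maintainer would want
written down. Empirical statements here are limited to what the test
suite and `scripts/acceptance.R` themselves compute.

## The 2Lk encoding

A strand over `{A,C,G,T,N}` (RNA is mapped to the DNA alphabet by U→T at
ingest, so one encoder serves both strand types; IUPAC ambiguity codes
collapse to N rather than erroring) is encoded in two levels:

1. an outer sliding window of size $k_1$ (stride 1) produces the
   $L - k_1 + 1$ overlapping words of the strand;
2. each word is profiled by its frequency chaos game representation
   (FCGR) at resolution $k_2$: a $2^{k_2}\times 2^{k_2}$ grid whose
   $4^{k_2}$ cells are in bijection with the possible $k_2$-mers, each
   cell holding the k-mer's occurrence count in the word.

The encoded strand is the $(L-k_1+1)\times 4^{k_2}$ matrix of flattened
FCGR vectors. Two invariants pin the implementation down exactly:

* **Shape law**: dimensions are $(L-k_1+1)\times 4^{k_2}$, always.
* **Count conservation**: each row sums to $k_1 - k_2 + 1$ (the number of
  $k_2$-windows in a $k_1$-word), exactly for N-free rows and to within
  $10^{-9}$ otherwise.

**Cell ordering.** Classical CGR assigns bases to grid corners; published
diagrams of the corner convention vary, and any fixed bijection between
k-mers and cells carries identical information for a downstream
convolution (the network sees a fixed permutation of columns). We
therefore use the lexicographic digit encoding A=0, C=1, G=2, T=3 with
$\mathrm{index}=\sum_i d_i 4^{k_2-1-i}$, which makes every cell auditable
by hand (`kmerCellIndex("TG")` is 14, and so on).

**N handling.** A window containing $m$ N characters adds $4^{-m}$ to
each of the $4^m$ compatible cells instead of being dropped or zeroed.
This preserves count conservation and lets the precomputed lookup table
cover the complete $5^{k_1}$ vocabulary (125 entries at $k_1=3$) — the
reason encoding cost is independent of dataset size.

**Raw counts, not frequencies.** Rows are occurrence counts; for the
short words used here normalisation would rescale by the constant
$k_1-k_2+1$ and is omitted. No further row scaling is applied before the
network.

**One-hot baseline.** `encodeOneHot()` gives the $L\times 4$ comparator
with columns in A,C,G,T order; N rows are all-zero, matching
DeepBind-style encodings.

**Variable lengths.** Batches are right-padded with all-zero rows to a
common row count and carry an explicit validity mask; every layer that
aggregates over positions consumes the mask (below), so padding is
representational only.

## The predictors

`buildModel()` assembles, per the `KDeepConfig`:

```
conv(nFilters, F, valid) → ReLU → maxpool(M, non-overlapping) → dropout
  → [additive attention]            (KDeep+ only)
  → BiLSTM(U per direction) → dropout → dense(D, ReLU) → dense(T, sigmoid)
```

Defaults (all overridable): filter width $F=16$ encoded rows, pool
$M=13$, dropout 0.2 (post-pool) and 0.5 (post-BiLSTM), BiLSTM units 320
per direction for the DNA-scale configuration and 32 for RNA-scale,
dense 128, 320 first-layer kernels, Adam at learning rate $10^{-3}$,
early stopping on validation loss with patience 5 and
best-validation-checkpoint retention. These follow the DanQ-family
conventions this architecture descends from. Valid (no) convolution
padding is deliberate: it keeps the scan arithmetic $P = S - F + 1$ exact,
which the interpretation pipeline relies on.

Design decisions that were genuinely open:

* **Attention form and placement.** The attention block is single-head
  additive (location-free) attention over *pooled* positions:
  $e_p = v^\top\tanh(W h_p + b)$, $\alpha=\mathrm{softmax}(e)$, features
  rescaled as $\alpha_p h_p$. Only per-fragment weight scores (for
  heatmaps) are required of it, and applying it after pooling keeps the
  score vector short and legible. Scores are retrievable via
  `attentionScores()`.
* **BiLSTM readout.** The per-position forward and backward hidden states
  are concatenated and *flattened* into the dense classifier (the DanQ
  convention), rather than using only the final hidden states. This keeps
  positional information available to the classifier — which matters
  whenever binding sites have positional structure, as in the synthetic
  benchmark below — and is why a `KDeepConfig` carries a fixed
  `inputRows`: like any flatten-based network, the model is built for one
  input geometry and shorter inputs are zero-padded up to it.
* **Masking.** A convolution site is valid only if every spanned row is
  real; invalid sites are zeroed after ReLU, pooled windows inherit
  validity, attention softmaxes over valid pooled positions only, and the
  backward LSTM consumes each strand's positions in its own reversed
  order. Consequence (tested): a strand predicts identically alone or
  inside a padded batch.
* **Initialisation.** Glorot-uniform weights from the config seed,
  forget-gate biases 1, and a small positive dense-hidden bias (0.01) so
  tiny configurations cannot start with a fully dead ReLU layer. Two
  builds from one seed are bitwise identical; training consumes a private
  RNG stream derived from the seed, so runs are exactly reproducible and
  the caller's RNG state is untouched.
* **Loss.** Binary cross-entropy on independent sigmoids (computed from
  logits in the numerically stable softplus form); multi-label targets
  are *not* a simplex. A non-finite loss aborts with a diagnostic rather
  than training on.

The engine is plain vectorised R (im2col convolution, batched BPTT,
Adam). Its analytic gradients are checked against central finite
differences for every parameter tensor, with and without attention, in
`test-model.R`.

## Filter-to-motif interpretation

For each first-layer filter: activations are inner products at the
$P=S-F+1$ scan sites (ties in the argmax go to the leftmost site). One
maximal-activation site is harvested per strand — "one per strand"
because the site with the highest value is the one credited with the
decision — and kept when its activation is positive and reaches
`activationFraction` (default 0.5, DeepBind-style) of the filter's
maximum over the strand set; `activationFraction = 0` keeps all.

A site at row $p$ is decoded to nucleotides $p \ldots p+F+k_1-2$: a
filter spanning $F$ consecutive $k_1$-words covers $W = F + k_1 - 1$
bases. Harvested substrings are tallied into a PFM (N contributes to no
base) and normalised with pseudocount 0.25 per cell,
$\mathrm{PWM}_{bj} = (c_{bj} + 0.25)/(n_j + 1)$, so MEME output never
contains zero probabilities; a filter with no valid sites still emits the
uniform motif with `nSites = 0`, keeping the one-motif-per-filter
contract. The BiLSTM's contribution is deliberately ignored in
interpretation; only first-layer kernels are decoded.

Motif similarity (`pwmSimilarity()`) is the best mean per-column Pearson
correlation over alignments of the narrower PWM within the wider — the
package's stand-in for a TOMTOM match in recovery experiments, where the
implanted ground-truth PWM is known. Zero-variance columns score 0, not
NA.

## The synthetic benchmark

`makeDataset()` emulates the structure of CLIP-seq-derived benchmark sets:
fixed- or variable-length strands (101 nt by default), i.i.d. (order-0)
background at a chosen GC content, positives carrying exactly one
PWM-sampled motif instance, negatives pure background. The default motif
is 8 bp wide with consensus probability 0.85 per column (consensus
TGACGTCA) — high-information but stochastic. Implantation is centred by
default, jittered up to half a motif width around the exact centre
(starts 44–51 on a 101-nt strand), giving the positional signal the
attention-localisation experiment needs; `"uniform"` placement is
available.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: higher-order background composition
(repeats, CpG structure), crosslink/read-level artefacts, multiple or
overlapping motif instances, secondary structure, and label noise. The
order-0 background is a deliberate choice: it keeps the null model
analysable, so recovery thresholds can be reasoned about rather than
fitted.

Problem sizes in the routine experiments were chosen to keep the whole
suite comfortable on a laptop-class single core while leaving the
conclusions stable: 2000 strands of 101 nt, a 16-filter RNA-scale model,
10 training epochs, three seeds for the recovery experiment (about 15 s
per training run in plain R). At these sizes the held-out auROC
criterion (≥ 0.9), the motif-recovery criterion (best PWM mean
per-column Pearson ≥ 0.7), and the attention-localisation criterion
(argmax in the central third of pooled positions for ≥ 80% of positives)
are all computed — not asserted — by `test-acceptance.R`.

## Metrics

auROC is the rank statistic (probability a random positive outranks a
random negative, ties counting ½, via midranks), so it is invariant under
strictly monotone score transforms and exactly complementary under score
negation. auPRC is step-wise average precision over distinct descending
thresholds with no trapezoidal interpolation — the conservative standard.
Single-class inputs are errors, never silent 0.5s; in per-target reports
degenerate targets are flagged and excluded from macro averages with a
warning. Both metrics are validated against brute-force oracles
(pairwise counting; threshold enumeration) and auROC additionally against
an independent library implementation.

## Known limitations

* The network engine favours clarity over speed; it is adequate for the
  RNA-scale configurations exercised here, but the full 919-target
  DNA-scale training regime is out of reach of a plain-R training loop.
* `inputRows` fixes the model's geometry; datasets with wildly different
  strand lengths should be padded to a common envelope (as the benchmark
  sets this architecture targets are).
* Interpretation decodes first-layer filters only; motifs represented
  distributively across filters or recognised by the recurrent layer are
  invisible to it.
* The MEME writer emits the minimal motif format with a uniform
  background line; database-specific background models are not supported.
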
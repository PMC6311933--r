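---
title: "m6Ascan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6Ascan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

m6Ascan detects N6-methyladenosine (m6A) in RNA sequence windows and
characterizes what a trained classifier has learned. This vignette is the
package's own account of its models and of the design choices that were
genuinely open; every empirical claim made here is recomputed by the test
suite (`tests/testthat/`, in particular `test-acceptance.R`) — nothing
below is a number we assert without computing.

## The problem and the data model

Single-base m6A callers (miCLIP-type protocols) yield, per transcript, a
list of 0-based positions of methylated adenosines. m6Ascan converts these
into a supervised dataset of fixed-size sequence windows:

* **Site merging.** m6A sites cluster; to avoid near-duplicate training
  windows, sites on one transcript are merged by single-linkage chaining —
  consecutive sites at most `merge_distance` (default 50 nt) apart join a
  cluster — and each cluster is represented by its central member site
  (the lower median on even cluster sizes). Chaining is the simplest rule
  consistent with "merge within d"; the alternative, the member closest to
  the cluster's geometric midpoint, differs only on asymmetric clusters
  and is not implemented.
* **Positive windows.** For each representative site, a `window_size`
  (default 101 nt) window is placed with its start drawn uniformly from
  all placements that contain the site and fit on the transcript, so the
  site lands at a random in-window offset; near a terminus the range
  collapses and the window clamps to the terminus (transcripts shorter
  than the window yield one truncated window). The window records *all*
  original (pre-merge) sites it covers.
* **Negative windows.** Candidates are enumerated start-to-start at
  offsets `gap + k * stride` (defaults 100 + k·10, k = 0..99) on both
  sides of the positive window; a candidate is valid if it fits on the
  transcript and covers none of the original sites (screening is against
  pre-merge sites: "contains no m6A" is absolute). The closest valid
  candidate wins; an exact two-sided tie is broken uniformly at random;
  absence of any valid candidate is a legitimate outcome, so the
  positive:negative ratio is approximately, not exactly, 1:1.
* **Split.** Windows are shuffled and assigned 80% train / 20% test, with
  1/8 of the training part held out as validation. The split is at the
  window level by default; transcript-level grouping is available
  (`group_by_transcript`) but off, mirroring the published protocol.

All coordinates in the package are 0-based, half-open `[start, end)`.
Inputs are transcript-oriented (5'→3'); BED sites on the "−" strand are
rejected rather than silently flipped. The internal alphabet is
A, C, G, U; T is accepted on input and converted.

## Encoding

Windows are one-hot encoded column-per-base with A=(1,0,0,0),
C=(0,1,0,0), G=(0,0,1,0), U=(0,0,0,1) and N the all-zero column, flanked
by `floor(filter_size_1 / 2)` all-zero columns on each side (5 for the
default width-10 first filter), so the first convolution effectively sees
symmetric zero padding. Batches right-pad to the batch maximum width;
true lengths travel with the batch, invalid positions are zeroed after
each convolution, and the recurrent layer freezes its state beyond each
sequence's valid range — consequently scores are exactly invariant to how
inputs are batched and to extra zero padding.

## The classifier

The architecture is a hybrid CNN + BLSTM:

```
one-hot (4 x L) -> conv(width 10, 256 filters) -> BN -> ReLU -> [pool] -> dropout
               -> conv(width 5, 128 filters)  -> BN -> ReLU -> [pool] -> dropout
               -> bidirectional LSTM (tanh) over positions
               -> fully connected layer (tanh) -> linear unit -> sigmoid
```

trained with Adam on binary cross-entropy, batch size 256, at most 50
epochs, early stopping on validation loss with patience 5 — these
full-scale defaults (`model_config()`) follow the published protocol,
including *no* max-pooling. Batch-norm is placed conv→BN→ReLU (the
standard ordering; the source protocol states only "BN and dropout after
each convolution"). The BLSTM's final forward and backward hidden states
are concatenated into the FC layer by default; `blstm_reduction =
"flatten"` instead concatenates the hidden states of every timestep.
Early stopping monitors validation loss (the metric was unstated; loss is
the conservative choice). Dropout is not applied after the BLSTM.

Because no deep-learning runtime ships with this environment, the network
is implemented in vectorized base R: im2col convolutions, exact
backpropagation through batch norm, max-pooling, the length-masked BLSTM
and down to the one-hot input (needed for saliency), and Adam with global
gradient-norm clipping (default 5). Every gradient path is checked
against central finite differences in `test-model.R`.

Three choices here deserve their reasoning on record:

* **FC activation = tanh.** The source states ReLU for the conv layers,
  tanh for the BLSTM and sigmoid after the FC layer, leaving the hidden
  FC layer's own activation unstated. With ReLU there, small-data Adam
  training repeatedly drove *all* FC units permanently negative — the
  classic dying-ReLU collapse, after which the model emits a constant
  logit and no gradient ever flows again. tanh has no such absorbing
  state and removed the collapse entirely.
* **Identity-passthrough init of conv2.** The second convolution starts
  as Glorot noise plus 1 added at its central tap so filter j forwards
  first-layer channel j (mod n1). This is an initialization, not an
  architecture change: at init, first-layer motif responses already reach
  the read-out instead of having to route through a fully random layer.
* **Forget-gate bias** defaults to 1 (standard); `forget_bias` is exposed
  because chrono-style values near log(sequence length) lengthen the
  initial memory horizon of the BLSTM.

### The desk-scale configuration

`tiny_config()` (16+8 filters, 16 BLSTM units, 16 FC units, ≤20 epochs)
exists because the full-scale configuration is *not trainable* at desk
scale, and this is worth stating precisely. With ~700 windows, the
no-pooling final-state architecture must push credit for a 5-nt motif
through a random second conv layer and ~90 recurrent steps; measured
behavior is memorization (training AUROC → 1, held-out AUROC ≈ 0.5),
while a single conv layer with global max pooling and a logistic read-out
learns the same data to AUROC 1.0 in 15 epochs with the same optimizer.
The tiny configuration therefore borrows that geometry within the same
architecture family: max-pooling of width 8 after each conv block (local
position invariance, BLSTM shortened to ~2 steps), the flatten read-out
(a direct gradient path from the loss to every position), batches of 16
at learning rate 0.03 under gradient clipping, dropout 0.25, and early
stopping disabled (patience = max_epochs) because small-data runs plateau
for several epochs before the loss starts moving. With this recipe the
held-out AUROC on planted-motif data is 0.95–0.99 in most seeds; roughly
one seed in five escapes the plateau too late to clear 0.95 within 20
epochs — a known limitation of the small-sample regime, not of the
architecture.

## Filter-to-motif conversion

For filter k and input sequence i, the position with the maximal
first-layer post-ReLU activation is found; if that activation
$\alpha_i^{(k)}$ is strictly positive, the one-hot subsequence of filter
length at that position is added into a cumulative matrix

$$M^{(k)} = \sum_{i=1}^{n} \alpha_i^{(k)} X^{(i)},$$

whose rows are then normalized to a PWM,
$m_{p,q} \leftarrow m_{p,q} / \sum_{q'} m_{p,q'}$. Scanning runs over the
padded input, so a maximal subsequence may overlap the zero padding;
those rows accumulate nothing and are emitted as uniform (uninformative)
rows. No pseudocounts are added. `support` counts sequences with a
positive maximum; because batch-normalized ReLU activations are positive
for roughly half of all inputs, support saturates near n for every
filter, so `rank_motifs()` orders motifs by the accumulated activation
mass instead (support as tie-break). Motifs with zero support have no PWM
and are excluded from the MEME minimal-format output (`write_meme()`),
which is the package's hand-off point to TOMTOM-style alignment tools.

## Saliency maps

The class score $S_c$ is the **pre-sigmoid logit** — the sigmoid
saturates exactly where predictions are confident, which is where
saliency is wanted, and the first-order Taylor framing
$S_c(X) \approx w^T X + b$ with $w = \partial S_c / \partial X$ is
scale-free in the logit. The per-position saliency is $|w| \odot X$
collapsed over the four channels; since at most one channel is hot per
position this picks the gradient magnitude at the observed base, N
positions score 0, and pad positions are dropped. For a linear scorer the
construction is exact (tested); for the trained network the gradient is
verified against finite differences. Downstream analyses: the most
salient nucleotide per window (leftmost argmax on ties), the mid-rank
percentile of a known site's saliency among all A positions of its
window (computed per-window), and signed distances to the nearest site
(ties resolved to the negative, downstream-site value).

## Evaluation and confidence tiers

Accuracy, sensitivity, specificity, F1 and MCC are evaluated exactly as
printed, with decision rule score ≥ threshold; an MCC denominator of zero
yields 0 with an `mcc_undefined` flag. ROC curves step through distinct
score thresholds and AUROC is the trapezoidal area, which equals the
Mann–Whitney probability P(pos > neg) + ½P(tie) — asserted to 1e-9
against an explicit pair-count oracle. AUPR uses the interpolation-free
step rule (average precision). Confidence tiers are score cutoffs
calibrated on validation negatives: for each target specificity s
(90/95/99%), the smallest threshold t with at least a fraction s of
negative scores strictly below t. The construction is an empirical
quantile, hence monotone in s by construction; fewer than 100 negatives
triggers an instability warning for the 99% tier.

## Position profiling

Transcripts are tiled into non-overlapping `window_size` bins from
position 0; a final partial bin is kept only if at least half a bin long,
and transcripts shorter than one bin become a single whole-transcript
bin (both rules are ours; the source does not state its binning
details). A short tail bin is *scored* on the terminus-clamped full-size
window — the model never sees sub-size training windows, and measured
scores on truncated inputs are systematically inflated — while keeping
its nominal coordinates. Each bin gets a score and a tier; for bins whose
center lies in the last exon the normalized distance to the 3' UTR start
is `(center − utr3_start) / utr3_length` with `center = (start + end −
1)/2`; values below −2 are flagged for exclusion from displays (tiny
3' UTRs blow the normalization up). In transcript space the mature
transcript is all exon, so the "whole transcript" and "all exons"
enrichment categories coincide; both are reported to mirror the
three-way comparison genome-space data would allow.

## The synthetic stated world

`simulate_dataset()` emulates miCLIP-like input with known ground truth:

* transcript lengths uniform on [500, 3000] nt — desk-scale, but long
  enough that the negative-window search (up to ±1090 nt) has room;
* i.i.d. uniform base composition;
* one planted GGACU instance per transcript (a DRACH consensus; the
  recorded site is its A, offset 2), with a 0.7 mixture weight of
  placement within the first half of the 3' UTR versus uniform — m6A is
  enriched just downstream of the 3' UTR start, and 0.7 gives a clear but
  not caricatured bias;
* `utr3_start` at 0.7 of transcript length, `last_exon_start` at 0.6;
* background **scrubbed** of chance exact-consensus matches (the central
  base of any unplanned GGACU is mutated and the sequence re-scanned):
  without scrubbing ~10% of negative windows would contain an unlabeled
  motif instance, and the recorded sites would not be the complete ground
  truth the acceptance properties assume;
* `spacing = "sparse"` keeps planted loci ≥ 1100 nt apart so the builder
  always finds negatives.

What the simulation does *not* emulate: read-level crosslink artifacts,
antibody bias, secondary structure, non-uniform background composition,
degenerate DRACH usage (a PWM motif can be supplied, but the default is
the sharp consensus), and overlapping transcript isoforms. A green test
on this world establishes that the machinery is correct and that the
pipeline recovers a strong planted signal — it does not establish
real-data performance, which requires real miCLIP training data.

## Numerical conventions, in one place

* Coordinates 0-based half-open; site = the modified base itself.
* Merging: single-linkage chain, lower-median representative.
* Negative candidates: start-anchored offsets, k = 0 included; exact
  ties broken uniformly at random from the builder's seeded RNG.
* One seeded RNG stream per build/training run; seeds recorded in
  metadata and checkpoints; all user-facing functions restore the
  caller's RNG state.
* MCC 0/0 → 0 with flag; percentile ties → mid-rank; saliency argmax
  ties → leftmost; distance ties → downstream (negative).
* Checkpoints are versioned; loading a different format version or a
  truncated file is an explicit error.
* Batch-norm statistics during training include the zeroed invalid
  positions of short windows in a batch (a documented simplification;
  windows of equal length — the overwhelming case — are unaffected).

## Known limitations

* The full-scale default configuration needs data volumes far beyond the
  synthetic world to train; only the desk-scale recipe is exercised by
  the tests.
* About one random seed in five, the 20-epoch tiny-config budget ends
  before plateau escape and the model underperforms; inspect the
  training record (`fit$record$history`) when in doubt.
* Motif extraction reports first-layer filters only; combinations of
  motifs captured by deeper layers are out of scope.
* The profiler's "all exons" category is meaningful only if intronic
  coordinates are absent, i.e. transcript-space input.
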
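---
title: "Predicting lysine crotonylation sites with kcrnet: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine crotonylation sites with kcrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcrnet)
```

## The problem

Lysine crotonylation (Kcr) is a post-translational modification of lysine
residues involved in transcriptional regulation and cellular metabolism.
Experimental identification of Kcr sites is expensive, so sequence-based
classifiers are used to prioritize candidate sites. The standard framing,
which kcrnet implements, scores a fixed-length peptide window centered on a
candidate lysine: 29 residues with the K at the center, labeled positive
(crotonylated) or negative. Balanced benchmark deposits for this task
(training pairs of 6,975 windows per class with independent test pairs of
2,989 per class) use exactly this window layout, and `load_labeled_pair()`
reads any such positive/negative FASTA pair.

## Encoding: k-mer word embeddings

Windows are tokenized into overlapping k-mers (default 1-mers at stride 1,
so a 29-residue window gives 29 tokens over a 22-token vocabulary: the 20
canonical residues plus the pad token `-` and the unknown token `X`). A
shallow two-layer network is trained on the token corpus and its input
weight matrix is used as the encoder: each token becomes a dense
`d`-dimensional vector (default `d = 80`), so a window becomes an 80 x 29
feature matrix. Encoding a window is exactly the matrix product of the
(transposed) weight matrix with the window's one-hot code, and the package
tests pin that identity.

The training objective is skip-gram with negative sampling. We chose
skip-gram as the canonical reading of a "two-layer word-embedding network";
the context half-width (5), negative-sampling rate (5), epochs (25) and
initial learning rate (0.025, linearly decayed) are exposed as arguments of
`train_embedding()`. The trainer is single-threaded with its own RNG
stream, so a fixed seed yields bit-identical weights. A one-hot encoder is
kept as the sparse baseline (`one_hot_encode()`, usable directly through
`encode_dataset()`).

Two leakage decisions worth making explicit: in `cross_validate()` the
embedding is retrained on each fold's training portion only, and
`grid_search()` and `run_train()` train it on the training split only.
Token co-occurrence statistics are weak signals, but retraining per fold is
cheap and removes the question entirely.

## The network

The classifier is a 1-D densely connected convolutional network over the
29 positions, with the embedding dimensions as input channels. There is no
initial convolution: the encoded matrix enters the first dense block
directly. Each dense-block layer computes `Conv(ReLU(BN(x)))` on the
channel-concatenation of everything before it and appends `growth_rate`
channels (default 32, kernel 3, same padding), so a block entered with `C`
channels leaves with `C + layers_per_block * growth_rate`. Between blocks a
transition layer applies batch normalization, a 1x1 convolution compressing
channels by `ceiling(compression * C)` (default compression 0.5), and
average pooling with window and stride 2, halving the length. With the
default four blocks of two layers the length trace is 29 -> 14 -> 7 -> 3
and the channel trace is 80 -> 144 -> 72 -> 136 -> 68 -> 132 -> 66 -> 130.

After the last dense block (no trailing transition, keeping more positions
for attention) the feature map is re-weighted by the residual channel
attention mechanism. Global average and max pooling over positions give two
per-channel vectors `a` and `m`; a shared two-layer bottleneck network
(`C -> C/r -> C`, reduction `r = 8`) maps each, and

* `mc = sigmoid(FNN(a) + FNN(m))` — the learned channel weights,
* `mr = sigmoid(a + m)` — the short-circuit term on the raw pooled values,
* `mrc = mc + mr` — the residual weights, elementwise in (0, 2),

and each channel is scaled by its `mrc` entry. Setting
`attention = "cam"` drops `mr` (the plain channel-attention ablation);
`"none"` removes the stage. The sigmoid of `mr` is applied to the raw,
unnormalized pooled sums — their magnitude is unbounded, so `mr` can
saturate; we keep this form deliberately because the short-circuit term is
defined on the pooled values themselves, and saturation simply makes the
residual path a constant gain of ~1 for strongly activated channels.

The head flattens the attended map and applies one hidden fully connected
layer (64 units, ReLU, dropout 0.5) and a 2-unit softmax. The kernel size,
growth rate, compression, head widths and dropout are not dictated by the
task; the defaults are conventional DenseNet-style values scaled to the
tiny 29-position input, and all are `model_config()` arguments. The
bottleneck sharing between the two pooled paths follows the single-network
form of the attention equations.

## Training

`fit()` minimizes the 2-class cross-entropy with Adam (learning rate 1e-3,
batch size 64) and early-stops on the loss of a stratified validation
split (fraction 0.1, patience 10), restoring the best-epoch weights.
Nothing about the optimizer is forced by the method; these are robust
defaults and all are `train_config()` arguments. Batch normalization uses
batch statistics during training (minimum batch size 2 is enforced; a
trailing 1-sample minibatch is dropped) and running statistics at
evaluation time, so prediction is deterministic. All randomness —
initialization, shuffling, dropout masks, splits — derives from
`train_config$seed`, and two fits with the same seed produce identical
histories; the forward/backward pass is compiled, single-threaded code
checked against a pure-R composition of the stage functions and against
numerical gradients.

`make_folds()` builds stratified, size-balanced partitions (per-class
round-robin after shuffling, so fold sizes and per-fold class counts each
differ by at most one). `grid_search()` scans (blocks x layers/block)
combinations, marking as infeasible any depth whose repeated length
halving underflows (at 29 positions, 6 blocks would need a transition on a
length-1 map); the winner is chosen by accuracy, then MCC, then fewer
parameters. On the real benchmark the reported optimum is four blocks of
two layers, which is the package default.

## Evaluation

`evaluate()` reports sensitivity, specificity, accuracy and Matthews
correlation from the confusion matrix at a 0.5 threshold (scores equal to
the threshold count as positive calls; MCC is 0 when its denominator
vanishes; Sn/Sp are `NA` when their class is absent), plus the ROC curve
and AUC via a threshold sweep with trapezoidal integration. Tie groups
move as one threshold step, which makes the trapezoid area equal the
Mann-Whitney pairwise statistic (ties counting one half); the tests verify
this identity to 1e-9.

## The synthetic benchmark

Real Kcr deposits require a download, so the package ships a generator
whose statistics are fully known. Windows are 29 residues with a central
K in both classes; negatives draw every other position i.i.d. from a
background composition (uniform by default; a natural-composition preset
is provided); positives additionally place a consensus residue at each of
four motif positions (offsets -2, -1, +1, +2) with probability
`motif_strength`, else a background draw. The default strength of 0.9
models a strong but noisy linear motif — high enough that a correct
implementation must learn it, low enough that positives are not a trivial
string match.

Because positions are independent and the classes agree conditionally on
whether a motif position matches its consensus, the match-pattern vector
is a sufficient statistic, and `expected_separability()` computes the
exact Bayes accuracy by enumerating the 2^m match patterns
(`1/2 + TV/2` under balanced priors). At strength 0.9 this is 0.9914; at
strength 0 it is exactly 0.5. These values calibrate the learning checks:
a trained default model should approach, and cannot legitimately exceed,
the Bayes accuracy, and on strength-0 data held-out accuracy must stay at
chance. What the generator does not emulate: positional correlations,
homology between windows, compositional differences far from the site,
and class imbalance — so passing these checks demonstrates a correct
learning machine, not benchmark-level biology.

## Problem sizes and numerical choices

The shipped checks train the full default architecture (127,674
parameters) on 2,000 generated windows with a 20% held-out split, which
keeps a complete train-and-evaluate cycle at a few minutes on one CPU
core; unit tests of the training loop use a reduced architecture on a few
hundred windows. Batch-norm uses eps 1e-5 and momentum 0.1 with biased
batch variance; He-style initialization; softmax via the log-sum-exp
stabilized form; early stopping compares losses with a 1e-8 slack to avoid
floating-point plateau churn. Convolution weights are stored tap-major so
the compiled engine and the R reference index identically; the parameter
vector layout is walked by both sides and any mismatch aborts rather than
misreads.

## Known limitations

* Sp on real benchmark data is reported lower than Sn for this family of
  models; the synthetic benchmark is symmetric between classes and will
  not show that asymmetry.
* The embedding treats pad and unknown symbols as ordinary tokens; for
  proteins with many non-canonical residues the unknown token's vector
  carries substantial mass.
* `mr` saturation (above) means the residual attention path contributes
  little gradient for strongly activated channels.
* Training is CPU-only and single-threaded by design (bit
  reproducibility); wall-clock scales linearly with dataset size.
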
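---
title: "DNA words, embeddings and adversarial augmentation: the models behind enhancerkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA words, embeddings and adversarial augmentation: the models behind enhancerkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

enhancerkit classifies 200-bp DNA fragments as enhancers vs non-enhancers
(layer 1) and grades called enhancers as strong vs weak (layer 2), treating
each fragment as a sentence over a vocabulary of short nucleotide "words".
This vignette explains the models, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the numerical choices a maintainer would want to know. It states no
empirical result that the test suite does not itself compute.

## Word segmentation

Three deterministic schemes and one learned scheme turn a sequence into
words:

* **Overlapped 3-gram** — a width-3 window with stride 1; a 200-bp
  sequence yields 198 trinucleotide words; vocabulary V = 64.
* **Non-overlapped 3-gram** — stride-3 windows starting at offsets 1, 2
  and 3. Offsets 2 and 3 emit their leading 1- or 2-nt fragment as a short
  word, and trailing fragments are emitted likewise, so each offset's words
  concatenate back to the sequence and every word has length 1–3; the
  vocabulary is all 4 + 16 + 64 = 84 such words. The three offset
  segmentations are *concatenated* in offset order into one word sequence
  per fragment (an open design point: the alternative, treating them as
  three samples, is available via `offsets = "separate"`); concatenation
  keeps one embedding matrix per sequence, which is what the classifier
  consumes.
* **Non-overlapped 2-gram** — dinucleotide tokens, used only as the
  GAN's token alphabet (a 200-bp sequence is 100 tokens over 16 symbols).
* **Statistical segmentation** — a unigram language model over a learned
  150-word dictionary, described next.

## The unigram segmentation model

Each dictionary word `w` carries a probability `p(w)`; a segmentation's
probability is the product of its words' probabilities, and the best
segmentation maximises that product over the segmentation lattice of the
sequence (found by Viterbi dynamic programming). The marginal likelihood of
a sequence sums over *all* segmentations and is computed by a forward pass
over the lattice in log space.

Dictionary learning (`learn_dictionary()`):

1. **BPE seeding** — starting from A/C/G/T, merge the most frequent
   adjacent symbol pair (ties broken lexicographically; merged symbols
   capped at `l_max = 8` nt) until `seed_size` symbols exist (default 1000)
   or no pair occurs twice. Initial probabilities are proportional to
   add-one-smoothed token counts; the smoothing exists because a merged-away
   mononucleotide would otherwise get probability zero, violating the
   invariant that all probabilities are positive.
2. **EM** — expected word counts by forward–backward posteriors over each
   lattice (all segmentations weighted by probability, not Viterbi-only,
   because the objective is the marginal likelihood), then
   counts-renormalisation, until the relative log-likelihood change drops
   below `em_tol = 1e-6` or 50 iterations.
3. **Pruning** — each non-protected word's loss is the corpus
   log-likelihood drop if the word were removed and the remaining
   probabilities renormalised, computed against the current fitted
   probabilities without per-candidate EM refits (a per-candidate refit
   would cost a full training per word; this is the standard unigram-LM
   pruning shortcut). The best 70 % of non-protected words are kept; the
   four mononucleotides are always kept so every sequence stays
   segmentable. The final round clamps to exactly the 150-word target.

Numerical choices: all lattice arithmetic is in log space; probabilities
below 1e-300 are floored with a warning; Viterbi ties break towards fewer
words, then the lexicographically smallest word sequence, making
segmentation fully deterministic.

## Skip-gram embeddings

Words are embedded with a skip-gram model and negative sampling. The input
table W (V × N, default N = 300) holds centre-word vectors, the context
table U (N × V) holds context vectors. For each (centre, context) pair in a
symmetric window of 4 context words (2 per side — the total-of-4 reading is
a design choice exposed in the config), m = 10 noise words are drawn from
the unigram distribution raised to 0.75 (redrawing the true context), and
one stochastic-gradient-ascent step raises `log σ(h·θ_q)` and lowers
`log σ(h·θ_t)` for each noise word. W and U start uniform in
±0.5/N; the learning rate decays linearly from 0.025 over 5 epochs
(both exposed; the source protocol states neither). The training corpus
defaults to the positive class of the current layer, switchable to all
training sequences.

A sequence is represented by vertically stacking its words' W rows and
zero-padding to a fixed row count; padded rows contribute exactly zero to
every convolution sum, so padding never changes a feature value whose
window lies inside real words. Mean/sum poolings are deliberately not
offered as classifier inputs — collapsing to one vector discards word
order, which is the point of the matrix representation.

## The convolutional classifier

Kernels of heights 2, 3 and 4 words span the full embedding width; 128
kernels per height (desk-scale tests use fewer), stride 1, ReLU, then max
pooling of each feature map and concatenation into a 128 × 3 = 384 feature
vector, a fully connected layer and a softmax over two classes. The
embedding table is initialised from the pre-trained skip-gram vectors and
fine-tuned by default (`embedding_trainable = FALSE` freezes it). Training
protocol (all unstated by the source and config-exposed): Adam at 1e-3,
batch 64, 30 epochs with early stopping on a 10 % validation split,
dropout 0.5 before the fully connected layer. The classification threshold
is 0.5, with exact ties resolved to the positive class.

The two-layer predictor gates layer 2 on layer 1: only fragments called
enhancer are graded strong vs weak.

## Sequence GAN augmentation

One generator per class (non-enhancer / strong / weak) is a single-layer
GRU policy over the 16 dinucleotide tokens with horizon T = 100; one
discriminator per class is a small two-height convolutional classifier over
token embeddings. The generator is warm-started by teacher-forced maximum
likelihood (the adversarial phase assumes a non-degenerate initial policy),
then updated by policy gradient: the reward of a complete sequence is the
discriminator output, the reward of an intermediate state is the mean
discriminator output over N Monte-Carlo rollouts (default 16) under a
frozen copy of the policy re-synchronised before each generator step.

The gradient estimator keeps the literal form of the policy-gradient
objective: at every sampled prefix the inner sum runs over **all** candidate
tokens, each weighted by its action value. This estimator is unbiased and —
unlike the score-function form that samples the action too — is *exactly*
zero when the reward is constant across actions, which the acceptance
suite asserts to 1e-8. The discriminator minimises the usual
real-vs-generated negative log-likelihood on fresh fakes each step.

Generated sequences are detokenised to 200-nt fragments and passed through
a redundancy filter replacing the external cd-hit-est binary: greedy
clustering in input order, where identity is the best ungapped sliding
alignment match count divided by the shorter length, with an 8-mer sharing
prefilter; a sequence at ≥ 80 % identity to anything retained (or,
optionally, to the real training set — off by default, matching the
source's silence) is dropped. An optional shell-out to a cd-hit-est binary
exists for users who have one.

Augmentation volumes follow the 2:1:1 protocol (twice as many non-enhancers
as each enhancer class) so the first layer stays class-balanced.

## Evaluation

Accuracy, sensitivity, specificity and the Matthews correlation
coefficient are computed from pooled confusion counts; an MCC with a zero
denominator is reported as 0 with an explicit flag (a convention; the
source is silent). Cross-validation is stratified 10-fold over *real*
records only. In the default slow mode every fold refits the dictionary,
the embeddings and the GAN on its training folds (strictly leakage-free);
`fast = TRUE` fits those shared components once on all real records —
mirroring the most plausible original protocol, which never says — while
still keeping generated sequences out of test folds and evaluating only
held-out real records. Both guarantees are asserted at run time and the
run aborts if they fail.

The real-vs-generated analytics compare pooled nucleotide composition and
the mean of five trinucleotide physicochemical properties over all
overlapping trinucleotides. The source never names its five properties, so
the bundled table (`trinucleotide_properties_synthetic.tsv`) is an
explicitly synthetic stand-in: deterministic composition-based formulas
shaped like published bendability / nucleosome-positioning / duplex-
stability / propeller-twist / DNase-sensitivity scales. Replace it with
measured scales via `read_property_table(path)` for real analyses.

## The synthetic benchmark

`simulate_dataset()` emulates the benchmark's statistical structure: 1484
non-enhancers and 742 + 742 strong/weak enhancers of 200 bp; negatives
drawn i.i.d. with A = T = 0.30, C = G = 0.20 (the elevated-A/T signature
of non-enhancers); enhancers drawn near-uniform. Enhancer strength is
encoded as planted-word dosage: two 8-mer motif words are derived from the
simulation seed (so tests cannot overfit a fixed motif) and planted at
non-overlapping uniform-random positions, 8 occurrences per strong and 1
per weak enhancer. Dosage is a stand-in — the benchmark gives no
generative description of strength — chosen because it is monotone and
learnable by a max-pooling CNN through extreme-value statistics of kernel
activations; the dosage values were fixed once, before any acceptance
measurement. The generator does **not** emulate positional motif grammar,
chromatin-state or histone-mark context, GC isochores, or repeat
structure, so a green end-to-end test establishes that the pipeline learns
compositional and dosage signals at benchmark shape — not that it
reproduces published benchmark accuracies.

## Known limitations

* Pure-R neural training loops: desk-scale configurations (small hidden
  sizes, tens of epochs) run in minutes on one CPU; full-scale runs
  (N = 300, 128 kernels, 20 000 generated sequences) are supported but
  slow.
* The statistical scheme's dictionary is corpus-dependent; per-fold
  refitting is the only strictly leakage-free option and is the default.
* The redundancy filter's 8-mer prefilter is a heuristic (as in the tool
  it replaces): a pair above the cutoff sharing no 8-mer would be missed;
  `prefilter = FALSE` forces exhaustive alignment.
* Embedding-vector cosine structure at tiny vocabularies is dominated by a
  shared mean direction; the property tests use corpora large enough for
  the co-occurrence signal to exceed it.
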
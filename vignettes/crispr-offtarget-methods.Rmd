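---
title: "Off-target prediction with recurrent networks: models, search and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target prediction with recurrent networks: models, search and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crisproff)
```

## The problem

CRISPR Cas-9 cleaves DNA wherever its single guide RNA (sgRNA) finds a
sufficiently similar protospacer next to an NGG PAM. Sites that differ from
the guide by a handful of substitutions can still be cut — off-target
activity — and predicting which candidate loci are active is a severely
imbalanced binary classification problem: genome-wide candidate collections
run at roughly 230 inactive sites per active one. `crisproff` implements a
complete modeling stack for this problem on 23-mer sgRNA/target pairs
(20-nt spacer + NGG context): pair encoding, a family of recurrent
classifiers, class-balanced training, genetic-algorithm model selection and
integrated-gradients interpretation, plus a synthetic benchmark generator
that makes the whole pipeline testable without any external download.

Throughout, positions are 1-based with position 1 at the PAM-distal end;
the PAM occupies positions 21–23 and position 21 is the N of NGG.

## Pair encoding

Both sequences are one-hot encoded over channels ordered (A, T, C, G) and
superposed with a logical OR. A matched position yields one active channel,
a mismatched position two — the classifier sees mismatch identity and
position but not, in the 4-channel form, which strand contributed which
base. The 5-channel form appends a direction bit, set at a mismatch exactly
when the higher-precedence base (precedence A > T > C > G, the channel
order) originates from the target DNA.

Two conventions are not dictated by the encoding scheme itself and were
fixed as follows:

* **Wildcard N** (always present at position 21 on the guide side) encodes
  as an all-zero row in its one-hot matrix, never counts as a mismatch, and
  never sets the direction bit. It carries no base identity, and inventing
  a fifth base channel would change every downstream shape.
* **Direction bit at matches** is 0; the direction concept only exists
  where the two strands disagree.

```{r encoding}
sg  <- "GACGTACGTACGTACGTACGNGG"
dna <- "GACGTACGTACGTACGAACGTGG"   # mismatch at position 17
encode_pair(sg, dna, channels = 5)[15:23, ]
mismatch_positions(sg, dna)
```

## The recurrent classifier family

A hyperparameter genome fixes one architecture out of a discrete space: one
or two recurrent layers (vanilla RNN, LSTM or GRU; uni- or bidirectional),
hidden size 32–512 (doubling), then a stack of 0–6 fully-connected hidden
layers whose widths halve starting from the hidden size, each followed by
ReLU and dropout, ending in a 2-unit output trained with cross-entropy.
Counting only the seven genes with hidden-size-independent grids, the space
holds `r search_space_size(default_search_space())` configurations.

Choices the architecture sketch leaves open, resolved here:

* **Recurrent-to-dense handoff**: the final time-step hidden state, with
  both directions concatenated when bidirectional. This keeps the dense
  stack independent of sequence length and is the standard
  sequence-classification head.
* **First dense width** equals the recurrent hidden size even under
  bidirectionality (where the handoff is twice as wide); the reference
  architecture (hidden 512 → dense 512, 256) pins this reading.
* **Hidden-layer cap**: widths must stay ≥ 2, so at hidden size `h` at most
  `min(6, floor(log2(h)))` dense layers are admissible. Crossover and
  mutation treat genes independently, so offspring are re-clamped to this
  cap.
* **Dropout between stacked recurrent layers** uses the same probability as
  the dense-stack dropout, applied only when two recurrent layers are
  stacked.
* **Optimizer**: Adam at the genome's learning rate with conventional
  moments (0.9/0.999, eps 1e-8).

The forward and backward passes are implemented directly on BLAS matrix
operations. With 23 time steps and hidden sizes ≤ 512 this is fast in
plain R, and owning reverse mode end to end yields exact gradients with
respect to the *input*, which the interpretation stage needs. Correctness
is anchored by finite-difference gradient checks over every cell type,
stacking and direction combination (see `test-gradients.R`).

```{r model}
g <- genome("LSTM", hidden_size = 512, n_recurrent_layers = 1,
            bidirectional = TRUE, n_hidden_layers = 2, dropout_p = 0.4,
            batch_size = 64, epochs = 50, learning_rate = 1e-4)
build_model(g, channels = 4, seed = 1)
```

## Class-balanced training

At a 1:230 imbalance, plain mini-batches starve the positive class.
Training therefore uses bootstrap-balanced batches: each batch holds equal
numbers of positives and negatives, negatives drawn without replacement
until exhausted, positives resampled with replacement. One *epoch* is
defined as one pass over the negatives — the resampling scheme itself does
not define an epoch, and this convention touches every real negative
exactly once per epoch while keeping epoch cost comparable to plain
training. Splitting into train/validation/test (60/20/20 by default) is
stratified at the locus level; a `stratified_split()` over loci matches the
single-dataset protocol this stack targets, though users concerned about
guide-level leakage should split by sgRNA themselves.

The decision threshold for the thresholded metrics is the argmax of the two
output units (0.5 on the softmax positive probability); AUPRC is computed
as step-wise average precision, not trapezoidal interpolation, which is
known to inflate the area under heavy imbalance. AUPRC on the validation
set is the model-selection objective.

## Genetic-algorithm model selection

Both a plain and an elitist GA run over the discrete genome space with the
study configuration: population 20, 4 elites, 2-way tournaments, per-gene
crossover probability 0.3, per-gene mutation probability 0.2,
20 generations, one recurrent cell type per run (recombining across cell
types is not meaningful). Interpretation choices:

* crossover/mutation probabilities act **per gene** (the crossover step is
  described as walking the hyperparameters and swapping each with a
  probability); mutation redraws from the full grid, so the realized
  change rate is `p * (1 - 1/grid)`;
* each tournament-selected pair produces two offspring; selection is with
  replacement across pairs; the elitist variant fills
  `population − elites` slots with offspring;
* identical genomes reuse a cached fitness — training is the bottleneck
  and each genome is trained once;
* the search returns the **best-ever** individual, not the best of the
  final generation (the two differ in the plain variant, which is exactly
  the failure mode elitism repairs).

The evolutionary loop is validated against exhaustive enumeration on a
64-genome sub-space with a deterministic landscape: the elitist
configuration recovers the global optimum in 100/100 seeded runs and its
per-generation best is non-decreasing (`test-ga.R`, `test-acceptance.R`).

## Integrated-gradients interpretation

Attributions use the straight path from an all-zero 23×C baseline to the
encoded input, with midpoint Riemann quadrature (default 50 steps; the
completeness residual is always reported and shrinks with the step count).
The all-zero matrix is the natural "no sequence information" reference for
a binary encoding. The target score is the positive-class logit; the
positive-vs-negative logit contrast was also evaluated and yields
near-identical attributions on these models, because balanced training
drives the two output units to near-opposite weights.

Per sample, attributions are L1-normalized over the *features present*
(the nonzero entries of the encoded input), summed over each position's
active channels, and labeled by the decoded base pair with a
match/mismatch/wildcard tag. Feature scores are averaged within
positive-labeled, negative-labeled and all samples. Ranking is by the
**magnitude** of the mean: a feature that strongly suppresses the positive
score is as much a "top contributor" as one that raises it, and the signed
mean carries the correlation direction. L1 (rather than L2 or max)
normalization keeps the per-sample scores on an interpretable
"share of total attribution" scale; the choice is a convention and is
flagged as such.

Region summaries average feature means over PAM (21–23), PAM-proximal seed
(16–20), seed core (11–15) and PAM-distal (1–10) positions — the two seed
sub-regions are configurable (`guide_regions(core_end = )`) since their
boundary is biologically fuzzy (15/16 vs 16/17). Neuron-level attribution
follows the same path with a conductance-style score,
`sum_k g(alpha_k) * (a(alpha_k) - a(alpha_(k-1)))` on post-ReLU activations,
which telescopes to exact completeness whenever the gradient above the
layer is constant along the path.

## The synthetic generator

`generate_dataset()` emulates the statistical shape of the benchmark this
stack targets: uniformly random 20-nt spacers with an NGG PAM, targets
derived by 0–6 substitutions at distinct non-wildcard positions (uniform
mismatch-count distribution by default — the real benchmark's per-count
distribution is not published), labels from a planted positional rule, and
an exact class ratio (default 1:230) achieved by rejection. The default
rule encodes the biological prior the interpretation stage should recover:
a pair is active iff its PAM is intact and it has no mismatch in the
proximal seed (16–20); distal and core mismatches are tolerated.

What passing tests on this generator do *not* show: real off-target data
has sequence-composition structure (GC bias, repeat content), guide-level
correlation, label noise from the detection assays, and mismatch-count
distributions skewed by the candidate-collection step. The generator makes
the *pipeline* falsifiable (a planted rule either is or is not recovered);
it does not certify benchmark-level accuracy numbers.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite stays in the minutes range on one CPU: the
end-to-end recovery experiment uses 20 000 noiseless records at 1:230
(≈ 87 positives), a single-layer unidirectional LSTM with hidden size 64,
two dense layers, batch 128 and 20 epochs at learning rate 1e-3 — training
on the combined train+validation split (the protocol also used for final
models in the study design this follows) and evaluating on the untouched
20 % test split. Attribution for the recovery check uses the test positives
plus 300 test negatives at 32 steps.

Other numerical conventions: parameters initialize uniformly on
`(-1/sqrt(fan), 1/sqrt(fan))`; softmax and cross-entropy are computed with
max-shift and probability floors; ties in tournament selection break toward
the earlier population index; tied scores enter the PR curve at a single
threshold; all randomness flows from named, derived integer seeds, so every
result in this vignette and in the test suite is bit-reproducible.

## Known limitations

* Substitution mismatches only — no insertion/deletion bulges, no context
  beyond the 23-mer, no epigenetic channels.
* The GRU uses the single-bias gate parameterization; parameter counts are
  exact for this package's cells but differ slightly from frameworks with
  two bias vectors per gate block.
* Training is CPU-bound pure R; it is sized for the desk-scale experiments
  above, not for GPU-scale sweeps over the full 72 000-configuration space.
* `read_dataset()` accepts any delimited file with sgrna/dna/label columns,
  but published benchmark tables must be fetched by the user; nothing is
  downloaded at build or test time.
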
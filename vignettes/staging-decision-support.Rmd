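---
title: "Staging decision support for NSCLC from medical-record text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging decision support for NSCLC from medical-record text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcstager)
```

## The problem

Non-small cell lung cancer (NSCLC) is staged I through IV, and the treatment
strategy differs sharply by stage: early, operable disease (I/II) is treated
surgically, while late disease (III/IV) calls for radiochemotherapy. Staging
from routine medical-record data — serum tumor markers, demographics,
symptoms — is attractive where imaging capacity is scarce, but two structural
problems get in the way:

1. **Class imbalance.** Because early NSCLC is usually silent, cohorts are
   dominated by stage III/IV cases. A classifier trained naively on a
   one-vs-rest (OvR) split sees perhaps one stage-I positive per twenty
   negatives and collapses to the majority class, which destroys minority
   recall exactly where early detection matters most.
2. **Small samples.** The rare stages do not merely unbalance the OvR split;
   they provide too little signal to train a model from scratch at all.

`nsclcstager` implements a text-classification pipeline that addresses both:
records are rendered as token sequences, embedded with skip-gram word
vectors, classified per stage by a small convolutional network, and trained
with (a) a *dynamic-sampling* iteration that rebalances each OvR task while
steering attention toward hard samples, and (b) a *transfer-learning* rule
that warm-starts a rare stage's model from the stage whose labels co-occur
with it most often.

## Pipeline and models

### Record text

A record's nine tumor markers (CYFRA21-1, CEA, CA-125, NSE, CA242, PSA, HGH,
Free-PSA, FERRITIN) are discretized against their normal reference ranges
into three categorical tokens: `normal` (at or below the upper limit
`hi`), `high` (up to ten times `hi`), and `very_high` (beyond ten times
`hi`). The 10x cut reflects the clinical reading that a marker an order of
magnitude over its critical value marks severe disease. How continuous
laboratory values become text is a genuinely open design point — no standard
tokenization exists for this — so the discretization is deliberately simple,
closed-vocabulary, and configurable; raw-value tokens can be appended but
are off by default because they open the vocabulary. Demographics (5-year
age band, gender, smoking duration band, family history) and symptom tokens
complete the sequence. FERRITIN has no published range in the reference
panel the other markers come from; the package default (upper limit 400
KU/L, a standard adult reference) is a package addition so the full panel
tokenizes.

### Skip-gram embeddings

Word vectors are pre-trained by maximizing the log-likelihood of context
words within a window of `d` positions around each center word, by
stochastic gradient descent. For the small closed vocabularies the generator
produces (tens of tokens) the exact softmax is affordable and is the
default; above 1,000 tokens the trainer switches to negative sampling (5
negatives, 3/4-power unigram distribution). Defaults `n = 64` dimensions,
`d = 2`, 5 epochs are configuration, not dogma: the objective is standard
and none of these values is critical on closed vocabularies. A document
becomes the `max_len x n` matrix of its tokens' vectors (prefix kept on
truncation, zero rows as padding, out-of-vocabulary tokens mapped to the
zero UNK vector). `max_len` defaults to 64; generator records are ~20
tokens.

### The CNN classifier

Each binary stage model is a text CNN: convolution kernels of window
lengths 3, 4, 5 (one kernel per window by default, with a multiplicity
knob) slide over the document matrix; each feature map is reduced by 1-max
pooling, so the pooled feature vector has exactly one entry per kernel;
dropout (rate 0.5) and a fully connected 2-way softmax produce the
positive-class probability `eta`. Training is minibatch SGD (constant
learning rate 0.05, batch 32 by default) on the cross-entropy loss, with
backpropagation verified against finite differences in the test suite. The
reference configuration lists an "epoch size" of 256 that is ambiguous
between an epoch budget and a batch size; both are independent
configuration here, with 256 kept as the default epoch budget. ReLU is the
default nonlinearity; tanh is selectable.

### Dynamic sampling

For one OvR task with `Npos` positives and `Nneg` negatives, each training
iteration draws a block by independent coin flips: sample `j` enters iff a
uniform draw falls at or below its probability `P_t(j)`. Probabilities are
initialized to `M/(2 Npos)` for positives and `M/(2 Nneg)` for negatives,
so each class contributes `M/2` to the block in expectation — a balanced
block from an arbitrarily imbalanced set. After training on the block, the
model scores *all* samples in evaluation mode, and each probability is
multiplied by `exp(1 - eta)` for positives and `exp(eta)` for negatives:
poorly recognized positives and hard negatives are boosted, confidently
correct samples are relatively dampened. Each class is then rescaled back
to mass `M/2` and entries are capped at 1.

The cap is a deliberate design decision: the initialization already exceeds
1 whenever `Npos < M/2`, and the multiplicative update can inflate entries
further, but a probability compared against a uniform [0,1) draw is
operationally 1 beyond that point. The cap is applied after the class
rescale; its documented consequence is that under active capping a class's
expected draw falls below `M/2`. The conservation invariant (both class
masses exactly `M/2`) therefore holds exactly in the uncapped regime, and
the tests exercise it there.

Two smaller decisions the algorithm statement leaves open: an empty block
draw is retried up to 10 times before erroring (empty draws are possible
but astronomically unlikely at sensible `M`), and the per-iteration
training step is a fixed number of SGD epochs on the block (default 1).

### Transfer by co-occurrence

The 4x4 label co-occurrence matrix `F` counts records carrying both of a
pair of stage labels. A rare stage's model is initialized from the trained
model of the stage with the largest `F` entry against it; ties break toward
the larger positive count, then the fixed severity order IV > III > II > I.
Clinically the stages are mutually exclusive, so strictly single-label data
makes every off-diagonal count zero and the selection rule vacuous; the
package then falls back to the largest-sample stage, which is an artifact
decision, not part of the original rule. The synthetic generator produces
co-occurrence only between adjacent stages (I–II, II–III, III–IV), on the
rationale that label ambiguity arises at clinical stage transitions.

### Decision value and staging map

The staging map partitions the decision-value axis into healthy `[0, 18)`,
I `[18, 58)`, II `[58, 119)`, III `[119, 180]`, IV `(180, ∞)`. The printed
reference bands are gapped (57 vs 58) and overlapping (119); a total
function needs contiguous intervals, so the gap is closed upward and the
shared endpoint 119 is assigned to III, as is 180.

How a `[0,1]` model confidence becomes a decision value on this axis is
never specified by the source material, which uses values like 233.52
directly. The package's mapping is an explicit stand-in: if the best OvR
confidence is below 0.5 the value lands in the healthy band (linearly in
the confidence); otherwise the winner's confidence, rescaled from `[0.5, 1]`
to `[0, 1)`, interpolates across the winning stage's interval (stage IV's
open interval is capped at 400 for interpolation only). The construction
guarantees the round trip — the stage looked up from the decision value is
always the argmax stage — so every staging conclusion that depends only on
the lookup is independent of the stand-in.

### Treatment rules and efficacy

Two rule tables ship: `"coarse"` (I/II surgery; III/IV radiochemotherapy
with surgery adjuvant; healthy, further tests) and `"stagewise"` for
trajectory tracking (IV chemotherapy, III radiation therapy, II surgery, I
late-stage drug therapy). The stagewise table resolves a small
inconsistency in its source narrative — a late-trajectory decision value of
67.75 sits in the stage-II band yet is narrated with a drug recommendation —
in favor of a deterministic per-stage table; custom tables are accepted.
Treatment efficacy compares each marker's first and last values along an
examination trajectory and, when predictions are available, the
decision-value delta; "decreased significantly" has no published threshold,
so the default is 40, one stage-I band width, exposed as configuration.

## The synthetic cohort generator

No hospital data ships with (or is usable by) the package; the generator is
first-class, tested code that emulates the study conditions:

- **Stage mix.** Default proportions I 5%, II 10%, III 35%, IV 40%
  (remainder non-NSCLC), reproducing the late-stage-heavy imbalance that
  motivates dynamic sampling.
- **Markers.** Log-normal draws (non-negative and right-skewed, like
  observed marker panels). For a staged record each highly relevant marker
  (CYFRA21-1, CEA, CA-125) is elevated with probability rising with stage
  (0.60/0.75/0.85/0.95) around a median of `severity_multiplier * hi`
  (defaults 2/5/10/20 by stage); low-relevance markers elevate rarely and
  mildly. Non-NSCLC records draw within their normal ranges (median
  0.35 hi, CV 0.35), which keeps ≥95% of healthy CEA draws inside [0, 5].
- **Ages 45–60**, matching the study population; symptoms scale in number
  with stage.
- **Determinism.** Every draw derives from the config seed through named
  RNG streams, so cohorts are byte-identical across runs and components
  are reproducible in isolation.

What the generator does *not* emulate: marker pharmacokinetics, survival,
within-patient correlation across markers beyond stage, free-text prose
(records render to a closed token vocabulary), or the scale of a real
hospital corpus. Passing tests therefore demonstrate that the algorithms
behave as specified under controlled, known-structure conditions — not that
the pipeline reaches any particular accuracy on real records.

## Numerical and protocol choices

- Embedding and CNN weights initialize from small uniform/Gaussian draws;
  output-side embedding vectors start at zero. All training is plain SGD.
- The severity order IV > III > II > I breaks all remaining selection ties.
- 1-max pooling takes the first argmax on ties (R's `which.max`).
- Stratified cross-validation deals each class round-robin into folds,
  continuing the rotation across classes so fold sizes differ by at most
  one even when a class has fewer members than folds; the source protocol
  (10-fold, means reported) is silent on stratification, which small
  minority classes make practically necessary.
- Metric denominators of zero return `NA`, never a silent 0.
- Experiment problem sizes in the tests and the acceptance script are
  scaled to desk hardware as the package's own study conditions: the
  imbalance-recovery experiment uses 25 positives vs 475 negatives (1:19)
  with 10 dynamic-sampling iterations at block size 50 over 10 paired
  seeds; the transfer experiment uses 500-record cohorts with stage I at
  5%. The reference study's headline accuracies come from millions of
  records and are not reproduction targets at this scale.

## Known limitations

- The decision-value interpolation is a stand-in (see above); absolute
  decision values are only as meaningful as the confidences behind them.
- The transfer effect is a soft, stochastic property: warm-starting the
  rare-stage model from its co-occurrence-selected source reaches a fixed
  loss threshold at least as fast as random initialization in most — not
  all — paired seeds, and the margin varies with the seed.
- Exact-softmax skip-gram scales quadratically in vocabulary and is meant
  for the generator's closed vocabularies; negative sampling handles larger
  ones but has seen less tuning here.
- The CNN is intentionally small (pure R, CPU); it is the method's
  architecture at study scale, not an engineered production model.
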
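---
title: "Extracting chemical-induced disease relations: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-induced disease relations: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidrex)
```

## The task

Chemical-induced disease (CID) relations are annotated at *document* level:
a curated abstract asserts that chemical concept `D008874` causes disease
concept `D006323`, without saying which of the many mentions of either
concept carries the assertion. cidrex follows the classical two-channel
decomposition of this problem. Every chemical mention is paired with every
disease mention; pairs inside one sentence ("intra-sentence") are scored by
a convolutional neural network over contextual and dependency-path
features, pairs spanning sentences ("inter-sentence") by a maximum-entropy
(logistic) classifier over sparse linguistic features. Mention-level
decisions are then merged back to concept level: a concept pair holds if at
least one of its mention pairs is predicted positive. Because the task asks
for the most *specific* concepts, a MeSH-hierarchy hypernym filter runs
during training (to clean distant labels) and after merging (to drop
over-general predictions), and two heuristic fallback rules fire for
documents where the classifiers found nothing.

## Instance construction and distant labeling

Instances are built pairwise from gold entity mentions. A mention carrying
several MeSH identifiers (composite mentions like `D012140|D003643`) forms
one instance per identifier; the unnormalized marker `-1` forms none and is
excluded from evaluation — neither case can carry a concept-level relation.
Labels are distant: an instance is positive exactly when its
(chemical id, disease id) pair is in the document's gold set. This is the
main source of label noise in real data — a positive concept pair labels
*all* of its mention pairs positive, including incidental co-occurrences.

Inter-sentence instances are built only for concept pairs that never
co-occur in a sentence anywhere in the document, which keeps the two
channels disjoint and makes merging well-defined. Cross-sentence mention
pairs are kept within a window of 3 sentences (configurable), falling back
to the single nearest pair when none is that close; building *all*
cross-sentence pairs is available behind `all_pairs = TRUE`. The windowed
policy bounds the otherwise quadratic instance count.

## Hypernym filtering

MeSH tree numbers are dot-separated codes (`C14.280.067`) locating a
concept in the hierarchy; concept A is a hypernym of concept B when one of
A's tree numbers is a proper segment-wise prefix of one of B's. Equal
numbers are *not* hypernymy — a concept is never its own hypernym — and
prefixes are compared at dot boundaries, so `C01.25` does not dominate
`C01.252`.

At training time, a negative instance is removed when its chemical (or
disease) is a hypernym of a chemical (disease) participating in any gold
relation of the same document: such instances are "negative" only because
the annotation kept the more specific concept, and training on them teaches
the model the wrong thing. Positives are never removed. At test time the
same relation is applied among the predicted pairs of each document. We
order the test-time pipeline merge → hypernym filter → post-processing: the
filter operates on document-level pairs, so it must follow merging, and the
fallback rules only fire on documents with *no* surviving prediction, so
re-filtering their output would contradict their purpose. Whether the
original system filtered before or after its fallback rules is not
documented; this order is our choice.

## The intra-sentence network

Tokens are embedded by column lookup in a table `T` (`d0 x |V|`); the
padding token `<PAD>` is a frozen all-zero column and out-of-vocabulary
tokens map to `<UNK>`. The classifier concatenates two feature blocks:

**Contextual features** — the mean embedding of each mention's tokens, the
`(w-1)/2` tokens left and right of each mention, and the verbs (POS tag
`VB*`) strictly between the mentions, padded or truncated to `V_max`
slots. Positions beyond the sentence end embed as `<PAD>`. With window
`w = 5` and `V_max = 5` this block has `d0 * (2 + 2(w-1) + V_max)`
entries.

**Dependency features** — three paths through the sentence's dependency
tree: root→chemical, root→disease, and chemical→disease, written as token
sequences that interleave words, dependency labels and traversal arrows
(`↓` for head→dependent steps, `↑` for dependent→head). For
"The dipyridamole induced his hyperemia." the chemical-to-disease path is
`dipyridamole ↑ nsubj ↑ induced ↓ dobj ↓ hyperemia`. Each path is padded to
`L_max` tokens; every position contributes a column stacking the `v`
embeddings of the window centred there; the three blocks concatenate into
`X0` (`v*d0 x 3*L_max`). A filter bank `Z = W1 X0 + b1` is max-pooled per
row over positions and passed through `tanh`, giving a fixed-size vector
`d` regardless of path length.

The concatenation `k = [c, d]` feeds a `tanh` hidden layer of size `n2`,
then a linear softmax layer over the two relation labels; the positive
probability is the instance's confidence. During training the hidden vector
is dropped out with probability `p_drop`. The objective is the mean
negative log-likelihood of the gold labels plus `lambda * ||theta||^2` over
all parameters `theta = {T, W1, b1, W2, b2, W3, b3}` (the frozen `<PAD>`
column excluded), minimized by mini-batch AdaGrad (per-coordinate
accumulator, update `lr * g / sqrt(G + 1e-8)`).

Defaults follow the published configuration: `w = 5`, `v = 9`, `n1 = 300`,
`n2 = 1500`, `lambda = 1e-4`, `p_drop = 0.3`, `lr = 0.002`, batch 64,
`d0 = 300`. Embeddings can be initialized from a user-supplied word-vector
file; tokens missing from it get uniform(-0.05, 0.05) vectors, as do all
weight matrices.

### Numerical and architectural choices the description leaves open

* **Binary output.** `n3 = 2`: the task has one relation type, so the
  softmax distinguishes positive from negative.
* **Dropout scaling.** Inverted dropout — kept units are scaled by
  `1/(1-p_drop)` at training time — so the test-time network is exactly the
  undropped forward pass and needs no weight rescaling.
* **Pooling and padding.** Max pooling skips columns whose window centre is
  `<PAD>`; pooling over padding is available via `pool_include_pad = TRUE`
  for comparison. Pooling spans all `3*L_max` columns jointly (one maximum
  per filter row); per-path pooling (three maxima concatenated, tripling
  the pooled dimension) is behind `pool_per_path = TRUE`.
* **Path lengths.** `L_max = 40` path tokens, truncating over-long paths
  at the end far from the mention; for the chemical→disease path both ends
  are mentions, so the middle is dropped (half kept from each end).
  `V_max = 5` verb slots keep the first five verbs in textual order.
* **Mention head token.** The path endpoints use the unique mention token
  whose governor lies outside the mention; if there is none or several,
  the last mention token.
* **Regularization of `T`.** The full objective penalizes every embedding
  column; during training the penalty is applied lazily to the columns
  touched by the current batch, which keeps the update sparse. The
  gradient-check entry point computes the full penalty.
* **Epochs.** 15 by default. The effective amount of optimization is the
  number of mini-batch updates, so small corpora (few batches per epoch)
  need proportionally more epochs at the fixed learning rate; the test
  suite trains ~100 epochs on its 60-document corpora to reach the same
  ~300-400 updates the 400-document runs get in 15.
* **Determinism.** One integer seed drives initialization, shuffling and
  dropout; repeated runs are bit-identical.

## The inter-sentence classifier

The original system delegates inter-sentence classification to an external
maximum-entropy toolkit with features described elsewhere; we re-specify it
as L2-penalized binary logistic regression with templates computable from
this package's inputs alone: mention surface forms and head lemmas,
side-prefixed bags of lemmas of the two host sentences, the sentence
distance bucket (1/2/3+), in-title flags, per-document mention-count
buckets, and a bag of verbs from both sentences. No claim of template
fidelity to the original is made.

The fit minimizes mean negative log-likelihood plus `l2 * ||w||^2` (bias
unpenalized) with BFGS and an analytic gradient, restarting until the
gradient norm is below 1e-6 — the problem is convex, so the optimizer, not
the algorithm, is the contract. Because the penalty multiplies a *mean*
log-likelihood, useful values of `l2` are small; the default 0.003 was
chosen on held-out synthetic splits where larger values visibly shrank the
informative weights toward the class prior. A predicted probability of
exactly 0.5 resolves to negative, favouring precision — inter-sentence
recall is the weak channel in this architecture, and asserting relations on
coin-flips would spend precision for nothing.

## Merging, post-processing, evaluation

A document-level pair is asserted when at least one of its instances is
predicted positive; its confidence is the maximum supporter confidence and
its provenance the level of that supporter. For documents with no surviving
prediction: rule (a) associates every title chemical with every disease in
the document; when the title has no chemical, rule (b) uses the most
frequently mentioned chemical (ties broken by earliest first occurrence —
the description does not say, and first mention is the natural reading
order choice). "In the title" is exact: the mention span lies within the
title segment of the document text. Post-processed relations are not
re-filtered.

Evaluation is micro-averaged precision, recall and F over
(document, chemical, disease) triples; undefined ratios are reported as 0
with a flag rather than NaN.

## The synthetic corpus generator

Real CID extraction needs external resources (the BC5CDR corpus, parses
from a full NLP stack, pretrained vectors). To make every stage testable
without them, `generate_corpus()` plants a fully controlled signal:

* Sentences come from subject-verb-object templates with hand-built,
  consistent dependency trees, e.g. "The chem07 induced the dis15 ."
  (root verb, `nsubj` chemical, `dobj` disease).
* A *trigger* verb (induced, caused, produced, triggered) marks a gold
  relation; *neutral* verbs (accompanied, preceded, followed, predated)
  mark negative co-occurrences. The first co-occurrence sentence of every
  document uses a trigger, mirroring a curated corpus in which every
  abstract carries at least one relation; later ones trigger with
  probability `intra_positive_rate`.
* A cross-sentence relation is planted via an anaphora template — an
  administration sentence for a "background" chemical followed by
  "This drug induced the &lt;disease&gt; ." The anaphora names its own
  disease concept so the planted relation is attributable to the template
  and recoverable from the inter-sentence features (distance bucket plus
  host-sentence lemmas).
* The background chemical is mentioned most often and is the only one
  appearing in titles, so the fallback rules, fed by frequency and title
  position, deliberately carry almost no relation signal: a pipeline that
  scores well does so through its classifiers.
* Concept identifiers get tree numbers from a rooted hierarchy (heap-shaped
  numbering), and documents occasionally mention a hypernym of one of
  their relation chemicals in a neutral sentence, exercising both filter
  stages. The relation concepts of a document are sampled pairwise
  hypernym-free, because a corpus annotated "between the most specific
  concepts" cannot contain gold pairs that the test-time filter is defined
  to remove.
* Finally, gold membership of every mentioned chemical x disease pair flips
  with probability `noise_rate`, from a per-document random stream separate
  from the structural one, so noise overlays the same planted corpus.

At `noise_rate = 0` the planted gold is exactly recoverable by
`rule_baseline_predict()` (trigger-root sentences plus the anaphora
pattern); the test suite asserts F = 1.0 there, so any classifier failure
on this data indicates an implementation bug, not an unlearnable corpus.

What the generator does **not** emulate: real MEDLINE vocabulary and
sentence variety, parse errors, tokenization noise, composite and
unnormalized mentions at corpus scale (these are covered by hand-built
fixtures), co-reference beyond the single anaphora template, and the true
density of candidate pairs per abstract. Passing the recovery study
therefore shows the pipeline is correctly wired and can learn a clean
relational signal end to end — not that it would match published F-scores
on the real corpus, which are reproducible only with the external data.

## Problem sizes used by the tests and the acceptance script

Unit tests run the network at reduced dimensions (`d0` 4-24, `n1` 3-16,
`n2` 5-32) on corpora of 3-60 documents; the gradient check covers every
parameter of a `d0 = 4` model against central finite differences. The
end-to-end recovery study trains on 400 documents and evaluates on 100
(noise 0.05) with `d0 = 50`, `n1 = 40`, `n2 = 80` and otherwise default
hyperparameters; the same study is what `scripts/acceptance.R` reruns,
alongside a majority-class contrast in which the CNN is replaced by an
always-negative classifier to show the learned signal is not leaked
through merging or the fallback rules.

## Known limitations

* The MaxEnt feature templates are a documented re-specification, not the
  original system's.
* No co-reference resolution; inter-sentence recall rests on shallow
  features by design.
* Negative down-sampling, position embeddings, multiple filter widths and
  attention are out of scope.
* The CNN trains on CPU in plain R; it is sized for corpora of hundreds of
  abstracts, not for large-scale pretraining.
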
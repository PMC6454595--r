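---
title: "Models and methods behind medner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medner)
```

# The task and the model

`medner` recognizes five categories of clinical entity — anatomy, surgery,
drug, independent symptom, and symptom description — in Chinese electronic
medical record (EMR) narratives. Chinese clinical text has no whitespace
word boundaries and annotation offsets are character positions, so the
package tokenizes at the single-character level throughout: this sidesteps
word-segmentation error entirely and keeps gold offsets exact.

Documents are split into sentences after any of `。 ； ！ ？` or a newline
(the delimiter stays with its sentence). Entities are represented as
0-based, half-open code-point spans `[start, end)`; a span of one character
therefore has `end - start = 1`, the only convention consistent with the
tagged-item annotation format the package reads and writes
(`name<TAB>start<TAB>end<TAB>category`). Whether third-party annotation
files count from 0 or 1 cannot always be determined from the data, so all
readers and writers take an `offset_base` argument, defaulting to 0 and
applied symmetrically.

Sentences are encoded with the BIO schema: one `O` tag plus `B-`/`I-`
pairs per category (`B-BO`/`I-BO` for anatomy, `B-SU`/`I-SU` surgery,
`B-DR`/`I-DR` drug, `B-SD`/`I-SD` symptom description, `B-IS`/`I-IS`
independent symptom), `k = 11` tags in total. Decoding is lenient: an
`I-X` that does not continue a same-category run opens a new entity and is
reported with a warning, because discarding it would silently delete
model output.

## BiLSTM-CRF

The baseline tagger is the standard character-level BiLSTM-CRF:

1. a look-up layer maps each character to a dense embedding
   $x_i \in \mathbb{R}^d$ (inverted dropout is applied here during
   training);
2. a bidirectional LSTM encodes each sentence, concatenating forward and
   backward states into $h_t \in \mathbb{R}^m$ with $m$ twice the
   per-direction hidden size;
3. a linear layer maps $h_t$ to $k$ per-tag emission scores, collected in
   the matrix $P \in \mathbb{R}^{n\times k}$;
4. a linear-chain CRF with transition matrix
   $A \in \mathbb{R}^{(k+2)\times(k+2)}$ (the two extra states are START
   and STOP) scores a tag path $y$ as

$$\mathrm{score}(X, y) = \sum_{i=1}^{n+1} A_{y_{i-1}, y_i}
   + \sum_{i=1}^{n} P_{i, y_i},$$

with $y_0 = \mathrm{START}$ and $y_{n+1} = \mathrm{STOP}$. Training
maximizes $\log P(y\mid X) = \mathrm{score}(X,y) - \log\sum_{y'}
\exp(\mathrm{score}(X,y'))$; the partition term is computed by the forward
algorithm entirely in log space (log-sum-exp recursions), which is exact
and stable for scores up to about $10^4$ — sentence-length products of
probabilities would underflow long before that. Decoding uses the Viterbi
dynamic program; ties are broken deterministically toward the lowest tag
index at the earliest differing position (the implementation computes
suffix-optimal scores and then greedily picks the smallest optimal tag
from the front, which realizes exactly that rule).

## Document-level attention

A sentence-level tagger can tag two mentions of the same string — often a
full form and an abbreviation of it — differently within one document
(*tagging inconsistency*). The attention variant injects document context
between the BiLSTM and the CRF. For a document with $N$ characters in
total, pairwise scores over the *embeddings* are

$$s_{ij} = (x_i - x_j)^\top W (x_i - x_j),$$

row-softmaxed into an attention matrix $\tilde A$ with
$\tilde a_{ij} = \exp(s_{ij}) / \sum_k \exp(s_{ik})$, and the global
context is $G = \tilde A H$ over the BiLSTM outputs $H$ (similarity is
measured on embeddings, weighting is applied to encoder states). Each
token's context row is concatenated with its own state, $Z = [G; H]$,
squashed with $\tanh$, and an affine map produces the $k$ emission scores
fed to the CRF.

Two choices here were genuinely open:

* **Sign and position of $W$.** Written as a bilinear form on the
  difference vector, a positive-definite $W$ would give the *largest*
  weight to the most dissimilar tokens, the opposite of a similarity
  kernel. We therefore initialize $W = -I$, so that at initialization
  $s_{ij}$ is the negative squared Euclidean distance and nearby
  embeddings attend to each other; $W$ remains a free parameter and may
  move away from $-I$ during training.
* **The emission head.** "tanh applied to $Z$, then affine to $k$" and
  "affine to $k$, then tanh" are both defensible readings of a layer
  described only as a tanh between $Z$ and the CRF. The second bounds
  every emission score in $(-1, 1)$, which caps the per-token score margin
  the CRF can express; in our experiments that variant optimizes far too
  slowly under Adam at batch size one to be usable. The package implements
  $P = \tanh(Z)\,W_z + b_z$ — the tanh squashes the concatenated vector
  and the affine map inside the CRF layer produces unbounded scores,
  mirroring the baseline's linear layer.

Attention weights are recomputed from the current embeddings at every
step rather than cached, so the similarity kernel co-adapts with the
look-up layer. Document attention costs $O(N^2)$ memory; the
`max_doc_tokens` control (default unlimited) splits very long documents
into non-overlapping attention blocks at sentence boundaries.

## Training

Both variants train with Adam at batch size one, the baseline taking one
optimizer step per sentence and the attention variant one step per
document (its loss is the sum of per-sentence CRF negative
log-likelihoods sharing one attention context). Defaults follow the
task's standard setup (45 epochs, Adam, batch size 1) and
are otherwise conventional choices documented in `medner_control()`:
`d = 100`, 100 hidden units per direction, dropout 0.5 on the look-up
layer, learning rate $10^{-3}$, global gradient-norm clipping at 5,
LSTM forget-gate bias 1, other weights uniform in $(-0.1, 0.1)$,
embeddings uniform in $(-0.25, 0.25)$ unless loaded from a word2vec text
file (out-of-vocabulary characters fall back to a trained `<unk>` row).
All randomness — initialization, dropout, shuffling — flows from the
single `seed` control, and single-threaded runs are exactly
reproducible. Every analytic gradient in the package (LSTM
backpropagation through time, the attention softmax/bilinear backward,
CRF forward-backward) is verified against central finite differences in
the test suite; the CRF forward and Viterbi scores are verified against
brute-force enumeration over all $k^n$ paths on small instances.

# Auxiliary correction passes

Three post-processing measures repair systematic neural-tagger defects.
They operate on entity lists and are composable in any order
(`postprocess_entities()`); the composed pipeline iterates its pass order
to a fixed point, which makes every order idempotent even when one pass
exposes work for an earlier one.

**Entity auto-correct.** An entity base tallies every
(surface form, category) pair seen in training. A recognized entity whose
pair is in the base is trusted verbatim. Otherwise all spans whose start
and end lie within `window` characters (default 3) of the recognized
boundaries are examined, and spans whose surface form occurs in the base
are candidates — preferring the entity's own category, then higher base
occurrence, then longer spans, then the leftmost. The algorithm is
realized as bounded span expansion/contraction against entity history —
the base records how entities were actually annotated — and it reproduces
every boundary-correction case in the package's reference fixtures
(左附件→左附件区 and its peers). Base entries are trusted at any count (the training annotations
are assumed noise-free), with a `min_occurrence` knob for stricter use;
category changes are off by default (`adopt_category`).

**Drug dictionary.** A drug-name list acts as a second authentication
factor for drug entities. Matching is leftmost-longest so that name
inclusions resolve to the longer form (`CPT-11`, never `CPT`, when both
are present); pure-ASCII entries match case-insensitively. Predicted drug
entities overlapping a match are replaced by it (boundary rectification),
matches with no overlapping prediction are added (extraction), and
non-drug predictions coinciding exactly with a match span are
re-categorized. Only fixture-scale dictionaries ship with the package;
the real national dictionary is out of scope.

**Boundary rules.** Four configurable rule kinds with defaults mirroring
the reference examples: strip a trailing 旁 from anatomy; merge a
preceding orientation phrase (右上, 左上, 右, 左) into anatomy; merge a
following orientation phrase (周, 上, 下, 外) into anatomy; merge a
following 术/手术 into surgery; and a gazetteer pass that scans the text
for anatomy and surgery base entries the model missed (the entity base
mainly serves those two categories). Token lists are open-ended starting
points, not closed sets, and live in a YAML rules file.

# Evaluation

`strict_prf()` implements the strict index: a prediction is correct only
if its span *and* category match a gold entity exactly, one-to-one, with
duplicates collapsed first; per-category counts micro-average into the
total row, and zero denominators score 0 by convention. The source
material defers the metric's definition to an external evaluation
platform, so exact-span-plus-category — the standard strict criterion —
is adopted here. `consistency_rate()` quantifies tagging inconsistency:
over all surface strings predicted at least twice within one document,
the fraction whose occurrences all carry a single category (1 when
nothing repeats).

# The synthetic corpus

Real Chinese EMR corpora are access-restricted, so the package carries a
seeded generator (`generate_corpus()`) producing EMR-like documents in
which every training signal the method relies on is present by
construction:

* five gazetteers (a few dozen names each, including the reference
  correction cases such as 左附件区, 卵巢切除术, 贝伐珠单抗 and the
  CPT/CPT-11 inclusion pair) placed into category-cued sentence templates;
* cue characters disjoint from entity characters, so entity category is a
  deterministic function of local context and the corpus is learnable to
  near-perfect held-out F1 by a *correct* tagger — acceptance therefore
  measures implementation correctness, not data difficulty;
* one repeated mention per document, emitted in truncated form with
  probability `abbreviation_rate` (default 0.3) — the abbreviation
  phenomenon behind tagging inconsistency;
* rule-trigger contexts at `rule_trigger_rate` (default 0.2): orientation
  prefixes/suffixes absorbed into gold anatomy spans, and a trailing 旁
  left outside them;
* companion fixtures: an entity base tallying each mention under its
  *full* form, and the drug gazetteer as dictionary.

Each document draws from an RNG stream derived from `(seed, doc index)`,
so corpora are byte-identical across runs and stable under `n_docs`
changes. `generate_boundary_noise()` manufactures boundary errors
(truncate or extend a span by 1-2 characters) on mentions whose surface
form is a full form in the companion base — gold abbreviated mentions are
left alone, since "restore the full form" is not a well-defined target
for them — and logs the intended correction so recovery is measurable
exactly (`recovery_rate()`).

What the generator deliberately does *not* emulate: real lexical
ambiguity (the same string as different categories in different
contexts), segmentation-hostile orthography, annotation noise, long
documents with topic drift, and realistic vocabulary sizes. Passing the
package's tests on this corpus shows the machinery is implemented
correctly; it does not predict absolute scores on clinical data.

## Problem sizes used in the checks

The held-out recovery check trains both variants on 150 synthetic
documents and evaluates on 50 (embedding and hidden size 50, 20 epochs,
Adam, batch size 1) and requires strict total F1 of at least 0.95. The
consistency comparison uses five seeds of an abbreviation-heavy corpus
(`abbreviation_rate = 0.6`; 60 training and 30 test documents, dimension
32, 10 epochs) and asks that the attention variant's consistency rate be
at least the baseline's in a majority of seeds — a soft, directional
check, since both variants often saturate the metric on this corpus. The
boundary-noise check perturbs 30% of eligible mentions across 60
documents and requires at least 90% of them restored. These sizes are
chosen so the whole battery runs in minutes on one CPU while leaving each
property comfortably away from its threshold.

# Known limitations

* Document attention is quadratic in document length; very long EMRs need
  `max_doc_tokens`.
* The CRF does not forbid schema-invalid transitions (e.g. `O → I-X`) by
  default — emissions and transitions learn the schema well on their own;
  `forbid_invalid_transitions = TRUE` masks them at decode time.
* `strict_prf()` requires exact span equality; whitespace-tolerant or
  overlap-based matching is out of scope.
* Training is plain R with BLAS matrix kernels: ample for the package's
  corpus scale, not for hundreds of real EMRs per epoch at
  production dimensions.
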
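---
title: "Trigger detection as word sense disambiguation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger detection as word sense disambiguation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triggersense)
```

## The problem

Biomedical event extraction systems must first find *trigger words*: the
tokens that anchor an event annotation, such as "transcribed" (or,
confusingly, "changes") anchoring a Transcription event. A single event
class surfaces through many different words, and — more importantly for
this package — a single frequent word surfaces under several different
event classes and very often under none at all. `triggersense` treats
that second problem as classical lexical-sample word sense
disambiguation (WSD): every frequent, ambiguous *word type* (lemma plus
coarse part of speech, e.g. `expression.N`) gets its own dedicated
classifier whose "senses" are the nine event classes of the BioNLP 2009
inventory plus a `NON-EVENT` class, and which is trained only on
contexts containing that word.

The package covers the full experimental loop: reading standoff
annotation with its sidecar layers, selecting which word types are worth
disambiguating, extracting collocational features, training and applying
a nearest-prototype vector space model (VSM), profiling the corpus by
feature class entropy, scoring, and exporting cross-validated
predictions as an extra feature column for a downstream CRF-style
sequence tagger.

## Target selection

Tokens are grouped by lowercased lemma and coarse POS (`NN* -> N`,
`VB* -> V`, `JJ* -> J`, `RB* -> R`; everything else is skipped). A word
type becomes a disambiguation target when, on the training split, it has

* at least `min_train = 50` instances — enough to fit per-class
  centroids, and enough test volume to matter downstream; and
* a majority-class bias strictly below `max_bias = 0.90` — types that
  are more than 90% one class leave little room for improvement over
  the majority baseline, so the interesting, higher-entropy types are
  the ones kept. The bound is strict: a bias of exactly 0.90 is
  excluded.

Bias is computed from training counts only; test instances of a
selected type are carried along whatever their classes.

## Features

All features are binary ("did this contextual event occur?"), flat
namespaced strings, and built per word type from training instances
only; unseen test-time features are dropped. Four families:

* **LOCAL** — bigrams and trigrams containing the target, over four
  parallel token attribute streams (lemma, word form, POS tag, protein
  B/I/O tag), at the five offset windows that include position 0;
  n-grams never cross a sentence boundary and there are no padding
  symbols. Plus the lemma and form of the nearest preceding and nearest
  following content word (coarse POS in {N, V, J, R}), direction-marked.
* **DEP** — for every dependency arc touching the target, in every
  loaded parser layer: an unlexicalised feature (layer + relation +
  direction) and a lexicalised one adding the other token's lemma.
  Direction (`up` = target is dependent) is encoded because it is
  strictly more informative and can be ignored downstream; layers are
  namespaced so several parsers can contribute simultaneously.
* **BOW** — lemmas of all content words in the sentence (excluding only
  the target token itself — another occurrence of the same lemma is a
  legitimate context signal), and, as a separately-keyed sub-family,
  lemmas of content words within 4 tokens either side. The window is
  counted in tokens, not content words, matching the window convention
  used for the sequence tagger export.
* **MESH** — one feature per MeSH descriptor attached to the document;
  document-level topical signal.

## The classifier

For one word type with training vectors $x_i \in \{0,1\}^V$ and classes
$c$, training computes one prototype per observed class,

$$\mathbf{m}_c = \frac{1}{|I_c|}\sum_{i \in I_c} x_i,$$

and prediction assigns $\hat{c} = \arg\max_c \cos(x, \mathbf{m}_c)$.
Because cosine is scale-invariant, the mean-versus-sum choice for the
prototype is irrelevant to predictions; the mean is used because its
entries are interpretable as per-class feature probabilities. There is
no smoothing, weighting, or tuned parameter.

Degenerate cases are made deterministic:

* exact score ties are broken by the larger training prior, then the
  alphabetically first class;
* an all-zero test vector (nothing in the vocabulary) ties all scores
  at 0 and therefore falls back to the majority-prior class, with a
  `fallback` flag on the prediction;
* cosine against a zero-norm vector is defined as 0.

The majority-class (MC) baseline predicts the modal training class
(alphabetical tie-break) for every test instance; its training accuracy
equals the selection bias by construction.

## Entropy profiling

The driving heuristic is *one sense per collocation*: in a fixed
collocation a word's class should be (nearly) invariant. For every
feature active in at least 2 training instances of a word type, the
class entropy

$$H(f) = -\sum_c p_c \log_2 p_c, \qquad p_c = \frac{n_{f,c}}{n_f}$$

measures how far that feature is from the ideal of determining the
class. The occurrence filter counts instances in which the feature is
active (binary), not raw multiplicity, and counts are kept within the
word type — profiles are per disambiguation problem, not pooled across
words. Base-2 logarithms are the default (and what the bin thresholds
below assume), exposed as an argument.

Unweighted means of $H(f)$ are reported per family and per word type,
and word types are binned at thresholds 0.3 and 0.4 bits (left-closed
upper bins: $H = 0.3$ is MID). Low-entropy words are the ones where a
collocational classifier is expected to do well, which is what the
synthetic experiments below verify in silico.

## Evaluation

Accuracy is measured over all instances; because the non-event class
usually dominates, the headline numbers are micro-averaged precision,
recall and F over the nine event classes only (pooled TP/FP/FN; a
cross-class confusion is both a false positive of the predicted class
and a false negative of the gold one). Zero denominators yield 0 rather
than NaN so F is always defined — in particular the all-`NON-EVENT`
baseline scores F = 0. Reports print percentages to one decimal.

System comparisons use paired approximate randomization: predictions of
the two systems are swapped per instance with probability ½, the
absolute metric difference is recomputed for each of R = 10,000 rounds,
and the p-value is $(b+1)/(R+1)$ — the add-one correction keeps p in
$(0,1]$ and slightly conservative. The seed is mandatory; the test
restores the caller's RNG state.

## The CRF bridge

The disambiguator's predictions are exported as one extra per-token
feature column for a sequence tagger: target tokens carry the predicted
class, every other token carries `NULL`. For training data the column
comes from 3-fold cross-validation so that no token's feature was
produced by a model that saw it; folds are cut per word type and
stratified by class (a seeded shuffle, then cyclic assignment within
each class), so no fold lacks a class unless the class has fewer
instances than folds. Types with fewer than `k` instances fall back to
leave-one-out; a type with a single instance gets `NULL` (there is
nothing to train on). For test data one model per word type is trained
on the type's full training set. The export is CoNLL-style TSV — form,
lemma, POS, chunk, protein, dependency function (the relation of the
arc where the token is dependent, in a designated parser layer), WSD
column, gold label in BIO encoding — plus a CRF++ template declaring
unigram features over a window of four tokens either side. Training the
tagger itself is outside the package's scope.

## The synthetic generator

Real shared-task corpora cannot be bundled, so the generator emulates
the statistical structure the method relies on, with ground truth
exposed through `truth_table()`:

* each word type has a majority `NON-EVENT` class with probability
  `skew` (β) and the remaining mass uniform over its sampled event
  classes — mirroring the dominant pattern in real data, where most
  occurrences of a trigger-capable word are not triggers;
* with probability `collocation_determinism` (π) a class-specific cue
  token is placed immediately before the target (offset −1, so the
  LOCAL bigram family alone suffices for recovery tests), otherwise a
  cue of one of the type's other classes is drawn uniformly; at
  π = 1/classes the cue distribution is identical across classes and
  carries no information;
* dependency arcs (all tokens governed by the sentence's verb), protein
  mentions and class-indicative MeSH descriptors are optional extras
  controlled by their own rates, so each feature family can be
  validated in isolation;
* the train/test split is by document, mirroring shared-task practice,
  and generation is byte-identical given the seed.

Default conditions are 4 word types, 3 classes per type, β = 0.6,
π = 1.0, and 1200 sentences (one target occurrence each, dealt
round-robin), giving 210 training and 90 test instances per type — a
scale chosen to match the mid-frequency targets of real trigger
corpora while keeping a full pipeline run in seconds. Two extensions
beyond the basic knobs exist because deterministic fixtures need them:
exact per-type occurrence counts, and class counts fixed at their
expectations instead of i.i.d. sampling (used where a bias must sit
provably on one side of the 0.90 filter; i.i.d. sampling remains the
default and is what the binomial-interval test checks).

What the generator does **not** emulate: real lexical variety, genuine
syntax, multi-token and overlapping triggers in natural density,
annotation noise, and the long-tailed class frequency spectrum of real
event corpora. Passing the synthetic recovery tests therefore shows the
machinery is correct and responsive to collocational signal; it does
not certify any particular accuracy level on real shared-task data.

## Numerical and degenerate-input choices

* Offsets are 0-based half-open, the standoff convention; every reader
  validates `text[start:end] == surface` and fails loudly otherwise.
* A token overlapped by triggers of two distinct classes takes the
  class of the earliest-starting trigger, ties broken alphabetically,
  with a warning — annotation of simultaneous events is genuinely
  ambiguous and the rule is a documented package choice.
* Vocabularies and class lists are radix-sorted so results are
  locale-independent and byte-reproducible.
* Score ties in the classifier are exact floating-point ties; the
  brute-force oracle in the test suite recomputes scores with the same
  summation order, which is what makes exact-agreement testing of tie
  cases meaningful.
* Entropy of a single-class feature is exactly 0; features below the
  2-occurrence filter are excluded rather than smoothed.

## Known limitations

* The nearest-prototype classifier is **prior-insensitive**: cosine
  scores do not encode class frequency (only the tie-break does). When
  features carry no class signal, its accuracy tends toward a uniform
  choice among the observed classes — *below* a skewed majority-class
  baseline. The in-silico degradation experiment shows exactly this: at
  π = 1/classes and β = 0.6, VSM accuracy sits near 1/classes while MC
  sits near β. A prior-sensitive score would close that gap but would
  no longer be the scale-invariant cosine model implemented here. In
  practice this means the method should only be deployed on word types
  that pass the selection filters, where features do carry signal.
* Per-word-type models see only their own word's contexts; rare types
  fall to the sequence tagger (out of scope here) by design.
* The `.a2` writer merges adjacent same-class tokens into one trigger,
  so label sequences with two adjacent *distinct* triggers of the same
  class do not round-trip as two annotations (they re-read as one).
* MeSH features are document-level and thus identical for all instances
  in a document; they help only across documents.

## Problem sizes used in the bundled experiments

The test suite and acceptance script run entirely on generated corpora:
the recovery and degradation experiments use the default 1200-sentence
configuration over five (respectively two) seeds; the entropy-response
experiment uses 480-sentence corpora over three seeds and
π ∈ {0.5, 0.75, 1.0}; classifier/oracle agreement uses 500 randomized
micro-problems of at most 10 features, 4 classes and 30 training
vectors; the randomization-test calibration uses 200 null pairs of 100
instances at 999 rounds each. These sizes were chosen to make sampling
noise small relative to the asserted margins while keeping the whole
suite fast enough to run habitually.
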
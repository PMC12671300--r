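---
title: "Clustering verbal fluency transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering verbal fluency transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencer)
```

## The problem

A verbal fluency task (VFT) asks a person to produce as many words as
possible in 60 seconds, from a semantic category (semantic VFT, e.g.
"animals") or starting with a letter (phonematic VFT, e.g. "S").
Production is bursty: related words arrive in clusters, and transitions
between clusters — switches — are thought to reflect executive search,
while cluster size reflects lexical-semantic store. This package scores
transcripts three ways: two traditional manual-protocol methods made
deterministic, and an embedding-based semantic-relatedness method that is
language-agnostic and quantitative.

Throughout, the shared counting conventions are:

* a **cluster's size** is its word count minus 1 (a singleton has size 0);
* the **mean cluster size** averages over all clusters, singletons
  included;
* **switches** = number of clusters (singletons included) − 1;
* the **total word count** is the number of words *after* removing rule
  violations, whereas clustering itself runs on the *full* produced
  sequence — violations are not excluded from cluster characteristics.

These conventions give the exact identity
`mean_cluster_size = n_tokens / (switches + 1) − 1`, which the test suite
checks on every clustering it builds.

## The three clustering methods

All three methods reduce to the same primitive: a Boolean *join* decision
for each adjacent word pair, with maximal joined runs forming clusters
(`clusters_from_joins()`). This uniform sequential-pair definition is a
deliberate design choice; see "Chaining versus whole-cluster membership"
below.

**List-based (semantic task).** Two consecutive words join when they
occur on at least one common thematic list. Words may belong to several
lists (*parrot* is both a pet and a bird), so membership is a set
intersection, not a partition lookup.

**Rule-based (phonematic task).** Two consecutive words join when they
satisfy at least one of four rules: same first two letters; rhyme; exactly
one differing vowel sound; homonymy indicated by the speaker. Rules 2 and
3 are phonetic in nature; the default backend is a transparent grapheme
heuristic (below) and the backend is pluggable.

**Relatedness (both tasks).** Words are embedded by word2vec; the
relatedness of a pair is the cosine of their vectors; consecutive words
join when their relatedness is *strictly greater* than a fixed threshold
θ. Defaults are θ = 0.40 for the semantic task — the grid-search optimum
against category-list supervision — and θ = 0.30 for the phonematic task,
lowered because phonematically cued sequences are semantically sparser and
a stricter threshold would fragment nearly everything. The strict
inequality matters at the boundary: a cosine of exactly θ does not join,
and since cosines are ≤ 1, θ ≥ 1 always yields all singletons.

## The embedding model

The trainer implements skip-gram and CBOW with negative sampling. It is
written for auditability and determinism rather than throughput: a single
thread, one 64-bit linear-congruential generator seeded by the caller, and
updates applied in corpus order, so a given corpus, configuration, and
seed reproduce vectors bit for bit. Multi-worker asynchronous training —
the usual source of non-reproducibility in embedding toolkits — is
deliberately absent.

Tunable parameters, with defaults:

| parameter | default | role |
|---|---|---|
| `dimensions` | 500 | embedding dimensionality; grid values 200/500/1000 |
| `window` | 10 | one-sided context width in words; grid values 4/10 |
| `algorithm` | `skipgram` | training objective (`cbow` alternative) |
| `min_count` | 5 | minimum corpus frequency to enter the vocabulary |
| `epochs` | 5 | passes over the corpus |
| `negative` | 5 | negative samples per positive pair |
| `learning_rate` | 0.025 / 0.05 | initial rate (skip-gram / CBOW), linearly decayed |

`min_count` and `epochs` follow common word2vec practice; both are
recorded in the model metadata. Vocabulary order is frequency-descending
with lexicographic tie-break, so it is deterministic too. Subsampling of
frequent words is not implemented: on the corpus sizes this package
targets for testing it would mostly add another stochastic knob.

Word lookup normalizes the query (Unicode NFC, trim, lower-case; umlauts
preserved) and tries the exact form, then a first-letter-capitalized
variant. The fallback exists because naturally cased corpora (German
especially) store nouns capitalized while transcripts are normalized to
lower case. Pairs with an out-of-vocabulary word are marked OOV: they
never join a cluster and are *excluded* from the mean sequential
relatedness rather than scored as 0, which would silently drag the mean
down; OOV pair counts are reported alongside.

## Hyperparameter grid search

The grid search avoids fitting hyperparameters on participant data: it
draws random word pairs from the category lexicon, labels each pair by
whether the words share a list, trains one model per lattice point
(3 dimensions × 2 windows × 2 algorithms = 12 combinations), and sweeps
θ over 0, 0.01, …, 1.00 (101 points), classifying a pair as same-list
when its cosine exceeds θ.

The selection metric is balanced accuracy. Uniform random pair sampling
from realistic lexicons yields many more different-list than same-list
pairs, and plain accuracy would then reward the degenerate
"never-same-list" classifier; balanced accuracy weights both classes
equally. Accuracy and F1 remain selectable.

Tie-breaking: when several θ values score identically (typical for
separable scores, where a whole plateau is perfect), the *central* θ of
the arg-max set is returned. The midpoint maximizes the margin to both
plateau edges, the same logic as a maximum-margin separator; returning
the first arg-max would sit the threshold directly on the class boundary.
Among equally scoring hyperparameter combinations, the first in lattice
order wins.

## The grapheme phonetizer

True rhyme and vowel-sound comparisons need pronunciation; building a
phonetic transcriber is out of scope, so the default backend is a
deterministic grapheme heuristic over vowel runs (maximal runs of
`a e i o u ä ö ü y`):

* **rhyme**: identical suffix from the onset of each word's final vowel
  run (*sand*/*stand* → both "and");
* **one vowel difference**: identical consonant-run skeletons and equal
  vowel-run counts with exactly one differing vowel run
  (*sat*/*seat* → `s·a·t` vs `s·ea·t`).

The heuristic is intentionally transparent — every decision is
reconstructible from spelling — and exact to test. Its known coarseness:
it treats spelling as pronunciation, so words with a shared final vowel
letter (e.g. a trailing *-e*) count as rhymes, and irregular
orthographies will misfire. The backend can be replaced wholesale for
true phonetics. Homonym detection is annotation-driven by design: it
requires both the speaker's indication (a `homonym_indicated` token flag)
and an explicit homonym table; no automatic sense detection is attempted.

## Quality control and error rate

A transcript is excluded when more than 25% of its tokens carry violation
flags (strictly greater: exactly 25% is retained), when it is empty, or
when no word onset falls within the first 10 seconds. "Within" is read as
`onset_s < 10.0` — an onset at exactly 10 s excludes. When onsets are
absent the 10-second rule is skipped with a message rather than guessed.
Repetitions are detected automatically from normalized-form recurrence;
same-stem and proper-name detection require external resources (a stem
map, a name list) and are disabled — not approximated — without them,
mirroring manual-annotation practice. Non-cue-initial words in phonematic
transcripts are flagged as task violations by default (configurable off),
which is the natural reading of the task instructions.

Recognition error is the word-level Levenshtein distance between the
automatic and the corrected word list — insertions, deletions, and
substitutions at unit cost on normalized forms — divided by the corrected
list's length. The reported operation decomposition comes from one
minimal-cost alignment; the decomposition is not always unique but the
total distance is. An empty corrected list is a hard error (the
normalization divides by its length).

## Association statistics

Pearson correlation is the default association between cluster
characteristics and test scores; Spearman serves ordinal items; the
Mann-Whitney U test compares groups with non-normal scores. The
implementations delegate to R's `cor.test()` and `wilcox.test()` —
Spearman p-values use the t approximation, Mann-Whitney is exact for two
tie-free groups of ≤ 8 and normal-approximated with tie correction
otherwise — while the test suite checks both against independent
brute-force computations (raw-sum Pearson, explicit midranks, O(nm) pair
enumeration for U). P-values are reported unadjusted, matching common
reporting practice in this literature; a Benjamini–Hochberg option
exists but is off by default.

The correlation network keeps edges with p < α (α = 0.05 default) and
then applies the display conventions of a validation network: no
test–test edges, no test nodes without a metric link, and
metric–metric edges retained but unlabelled.

## What the synthetic data does and does not show

`gen_toy_corpus()` emulates the one property relatedness training needs:
theme-mates co-occur in sentences. It does not emulate Zipfian word
frequencies, syntax, polysemy, or corpus scale, so passing tests
demonstrate that the machinery (training → cosine → threshold →
clustering → metrics) is correct, not that any particular θ transfers to
natural corpora — thresholds for real use should come from the grid
search on the user's own corpus and lexicon. `gen_transcript()` plants
known cluster spans by drawing each cluster from one category with
adjacent clusters from different categories; with disjoint categories,
list-based recovery is exact by construction, which is what makes it a
usable ground truth. Injected violations are repetitions of earlier
words, the one violation type detectable without external resources.
`corrupt_asr()` applies word-level substitutions, insertions, and
deletions i.i.d.; real recognizer errors are acoustically correlated and
burstier.

Problem sizes used in the tests and the acceptance script — toy corpora
of roughly 1,200–2,000 sentences, 20–30 dimensional embeddings, 25–40
planted transcripts, oracle checks on ≥ 500 random small instances per
operation — were chosen as the smallest sizes at which the studied
effects (theme separation, boundary recovery, monotonicity) are stable
across seeds.

## Degenerate inputs and numerical conventions

* Empty transcript: QC excludes with reason `empty`; violation fraction
  is defined as 0; mean cluster size is reported absent (`NA`), not 0,
  to keep summaries honest.
* Zero-norm vectors make the cosine undefined and raise an error rather
  than returning 0; trained models cannot produce them.
* `sample_supervision_pairs()` samples unordered pairs without
  replacement and errors when asked for more pairs than exist; class
  balance falls where it may by default ("random pairs" taken
  literally), with an optional balanced mode.
* Sample standard deviations (n − 1) in summaries, matching standard
  neuropsychological reporting.
* All generators and the trainer are pure functions of (spec, seed);
  reruns are byte-identical, and the pipeline writes a manifest recording
  configuration, seed, and a model checksum.

## Open design choices, resolved

**Chaining versus whole-cluster membership.** "Consecutive words sharing
a list" is ambiguous between pairwise chaining (each adjacent pair shares
*some* list) and whole-cluster membership (all words share *one* list):
`dog → parrot → eagle` chains through pet and bird but has no single
common list. The package defaults to chaining for both traditional
methods, for internal consistency with the relatedness method's
sequential-pair definition; `whole_cluster_common_list = TRUE` selects
the stricter reading, implemented as a running intersection that must
stay non-empty.

**10-second onset source.** The 10-second rule is evaluated on word
onsets when present; whether detected-but-untranscribed speech should
count cannot be decided from a word list, so absent onsets skip the rule
explicitly.

**Violation pairs in mean sequential relatedness.** Sequential
relatedness is computed over *all* adjacent pairs, including those
involving violation words, consistent with violations remaining in the
clustered sequence.

**Census of multiply-matched pairs.** A joined pair matching several
phonematic rules is counted under each rule; on corpora where the rules
fire disjointly (the common case) the counts partition the joined pairs.

## Known limitations

* The grapheme phonetizer is orthography-bound (see above).
* Embedding training is single-threaded by design; for corpora of
  Wikipedia scale, expect training to be the slow step, or import
  vectors trained elsewhere via the word2vec text format.
* Cosine relatedness is static per word form: homonyms collapse to one
  vector, and inflected variants are distinct vocabulary entries unless
  the corpus or a stem map handles them.
* Thresholds are fixed per task, not adapted per participant; that is a
  property of the method, retained deliberately.
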
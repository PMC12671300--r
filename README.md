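# fluencer

Automated cluster analysis of verbal fluency task (VFT) transcripts.

In a verbal fluency task a person produces as many words as possible in 60
seconds, either from a semantic category ("animals") or starting with a
given letter ("S"). People do not produce these words evenly: they come in
*clusters* of related words, separated by *switches*. Cluster size tracks
language function; switching tracks executive function. Scoring clusters by
hand is slow, subjective, and language-bound. `fluencer` implements the
automated alternatives for researchers working on digital cognitive
biomarkers:

- **Traditional clustering** — list-based clustering of semantic fluency
  (consecutive words sharing a thematic list, e.g. *parrot* ∈ {pet, bird})
  and Troyer-style rule-based clustering of letter fluency (same first two
  letters, rhymes, one-vowel differences, speaker-indicated homonyms).
- **Semantic-relatedness clustering** — the embedding-based method at the
  package's core. Words are embedded with word2vec (skip-gram or CBOW,
  trained in-package with a deterministic single-threaded trainer, or
  loaded from standard word2vec text files). The relatedness of words
  *w₁, w₂* is the cosine of their vectors, cos θ = (v₁·v₂)/(‖v₁‖‖v₂‖), and
  a cluster is a maximal run of consecutive words whose sequential pair
  relatedness exceeds a fixed threshold (0.40 for the semantic task, 0.30
  for the phonematic task).
- **Hyperparameter grid search** — dimensions {200, 500, 1000} × window
  {4, 10} × {CBOW, skip-gram}, with the threshold swept over
  0, 0.01, …, 1.00, supervised by random word pairs labelled by shared
  category-list membership (balanced accuracy by default).
- **Transcript quality control** — violation marking (repetitions,
  same-stem words, proper names, cue mismatches), exclusion of transcripts
  with >25% violations or no word in the first 10 seconds, and word-level
  normalized Levenshtein error rates for speech-recognition output.
- **Cluster characteristics and association statistics** — total word
  count (violations removed), mean cluster size (words − 1, singletons
  included), switches (clusters − 1), mean sequential relatedness;
  Pearson/Spearman/Mann-Whitney wrappers and correlation-network edge
  export for validating characteristics against neuropsychological scores.
- **Synthetic data** — theme-structured toy corpora, transcripts with
  planted cluster structure and violations, ASR corruption, and score
  tables, so the entire pipeline is testable offline.

Everything is tibble-in, tibble-out and pipe-friendly; results have
`autoplot()`, `tidy()`, and `glance()` methods where that helps.

## Worked example

```r
library(fluencer)

# a letter-fluency sequence, clustered by the four phonematic rules
cl <- cluster_rule_based(c("simple", "simulate", "silly", "tiger"))
cl
#> <vf_clustering: rule_based, 4 tokens, 2 clusters, 1 switches>
#> # A tibble: 2 × 5
#>   cluster start   end n_words  size
#>     <int> <int> <int>   <int> <int>
#> 1       1     1     3       3     2
#> 2       2     4     4       1     0
```

"simple/simulate/silly" share their first two letters, so they form one
cluster of three words (size 2); "tiger" is a singleton (size 0); one
switch separates them.

Train a toy relatedness model and cluster a semantic sequence:

```r
corpus <- gen_toy_corpus(sentences_per_theme = 600, seed = 1)
model <- train_embeddings(corpus, embedding_config(
  dimensions = 30, window = 4, algorithm = "skipgram",
  min_count = 1, epochs = 5, seed = 1))

words <- c("dog", "cat", "parrot", "lion", "zebra")
relatedness(model, "dog", "lion")$score
#> [1] 0.04929488
cluster_relatedness(words, model, theta = 0.40)
#> <vf_clustering: relatedness, 5 tokens, 2 clusters, 1 switches>
```

The pet words chain into one cluster (sequential cosines above 0.40), the
African animals into another; the boundary pair scores near 0 and breaks
the run.

Quality control and metrics flow through tibbles:

```r
tokens <- vf_tokens(c("hund", "katze", "hund", "maus"),
                    transcript_id = "p01", onset_s = c(1.8, 6.2, 20, 41)) |>
  mark_violations()
qc_transcripts(tokens)
#> # A tibble: 1 × 6
#>   transcript_id n_tokens n_violations violation_fraction excluded reasons
#>   <chr>            <int>        <int>              <dbl> <lgl>    <chr>
#> 1 p01                  4            1               0.25 FALSE    ""
cluster_metrics(tokens, cluster_rule_based(tokens))
```

The repeated "hund" is flagged as a violation; at exactly 25% the
transcript is retained (the exclusion rule is strictly greater than 25%).
The violation stays in the clustered sequence but is removed from the
total word count.

## A note on real corpora

The bundled toy corpus generator stands in for large natural corpora
(e.g. a Wikipedia dump) so that tests run offline in seconds. For real
analyses, train on a natural corpus (plain text, one sentence per line,
whitespace-tokenized) via `train_embeddings()` or load a published
word2vec text-format model with `read_word2vec()`; vocabulary lookup
falls back to first-letter-capitalized variants so German noun
capitalization in natural corpora is handled transparently.
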
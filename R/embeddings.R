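#' Embedding training configuration
#'
#' Hyperparameters of the word2vec model underlying the semantic
#' relatedness method. The defaults are the tuned values for fluency
#' analysis — 500 dimensions, window 10, skip-gram — selected by a grid
#' search over dimensions {200, 500, 1000}, windows {4, 10}, and the two
#' training objectives ([vf_default_grid()]). `min_count` and `epochs`
#' follow common word2vec practice and are recorded in the model
#' metadata.
#'
#' @param dimensions Embedding dimensionality (default 500).
#' @param window One-sided context window in words (default 10).
#' @param algorithm `"skipgram"` or `"cbow"`.
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param learning_rate Initial learning rate; defaults to 0.025 for
#'   skip-gram and 0.05 for CBOW.
#' @param seed Integer seed; training is single-threaded and
#'   bit-reproducible given the seed.
#' @return A list of class `vf_embedding_config`.
#' @export
embedding_config <- function(dimensions = 500, window = 10,
                             algorithm = c("skipgram", "cbow"),
                             min_count = 5, epochs = 5, negative = 5,
                             learning_rate = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(dimensions >= 1, window >= 1, min_count >= 1, epochs >= 1,
            negative >= 0)
  learning_rate <- learning_rate %||% if (algorithm == "skipgram") 0.025 else 0.05
  structure(
    list(
      dimensions = as.integer(dimensions), window = as.integer(window),
      algorithm = algorithm, min_count = as.integer(min_count),
      epochs = as.integer(epochs), negative = as.integer(negative),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "vf_embedding_config"
  )
}

#' Train word embeddings on a sentence corpus
#'
#' Trains a word2vec model (skip-gram or continuous bag-of-words, with
#' negative sampling) on a plain-text corpus, one sentence per element,
#' whitespace-tokenized. Words with corpus frequency below
#' `config$min_count` are dropped from the vocabulary. Training is
#' single-threaded and deterministic under `config$seed`; two runs with
#' the same corpus, configuration, and seed produce identical vectors.
#'
#' @param corpus Character vector of sentences, or a path to a plain-text
#'   file with one sentence per line.
#' @param config An [embedding_config()].
#' @return A `vf_embedding`: list with `vectors` (matrix, one named row
#'   per vocabulary word), `counts`, and `config`.
#' @examples
#' corp <- rep(c("dog cat dog hamster", "lion zebra lion giraffe"), 50)
#' model <- train_embeddings(corp, embedding_config(dimensions = 10,
#'   window = 2, min_count = 1, epochs = 2, seed = 42))
#' relatedness(model, "dog", "cat")
#' @export
train_embeddings <- function(corpus, config = embedding_config()) {
  if (length(corpus) == 1 && !grepl("\\s", corpus) && file.exists(corpus)) {
    corpus <- readLines(corpus, encoding = "UTF-8")
  }
  tokens <- stringi::stri_split_regex(corpus, "\\s+", omit_empty = TRUE)
  tokens <- tokens[lengths(tokens) > 0]
  if (length(tokens) == 0) abort("Corpus is empty: no sentences with words.")
  freq <- table(unlist(tokens))
  keep <- freq[freq >= config$min_count]
  if (length(keep) == 0) {
    abort("No word reaches min_count; lower `min_count` or enlarge the corpus.")
  }
  # deterministic vocabulary order: frequency-descending, ties lexicographic
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  vocab <- names(keep)[ord]
  counts <- as.numeric(keep)[ord]
  index <- stats::setNames(seq_along(vocab), vocab)
  sentences <- lapply(tokens, function(s) {
    idx <- index[s]
    as.integer(idx[!is.na(idx)]) - 1L
  })
  sentences <- sentences[lengths(sentences) > 0]
  if (length(sentences) == 0) abort("Corpus is empty after vocabulary filtering.")
  vec <- .w2v_train(
    sentences, length(vocab), counts,
    config$dimensions, config$window, config$algorithm == "skipgram",
    config$negative, config$epochs, config$learning_rate, config$seed
  )
  rownames(vec) <- vocab
  new_embedding(vec, counts = stats::setNames(counts, vocab), config = config)
}

new_embedding <- function(vectors, counts = NULL, config = NULL) {
  structure(
    list(vectors = vectors, counts = counts, config = config),
    class = "vf_embedding"
  )
}

#' Wrap a vector matrix as an embedding model
#'
#' Builds a `vf_embedding` from an existing matrix of word vectors (one
#' named row per word), e.g. hand-constructed synthetic embeddings or
#' vectors produced elsewhere.
#'
#' @param vectors Numeric matrix with rownames giving the vocabulary.
#' @param config Optional [embedding_config()] metadata.
#' @return A `vf_embedding`.
#' @export
embedding_model <- function(vectors, config = NULL) {
  if (is.null(rownames(vectors))) abort("`vectors` must have word rownames.")
  new_embedding(as.matrix(vectors), config = config)
}

#' @export
print.vf_embedding <- function(x, ...) {
  cat(sprintf("<vf_embedding: %d words x %d dims>\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

# exact normalized match, then capitalized-variant fallback, then NA
lookup_row <- function(model, word) {
  vocab <- rownames(model$vectors)
  i <- match(word, vocab)
  if (is.na(i)) i <- match(capitalize_first(word), vocab)
  i
}

cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("Cosine undefined for a zero-norm vector.")
  sum(x * y) / (nx * ny)
}

#' Semantic relatedness of word pairs
#'
#' The semantic relatedness of two words is the cosine between their
#' embedding vectors, in `[-1, 1]`. Lookup tries the normalized form,
#' then a first-letter-capitalized variant (German nouns are capitalized
#' in natural training corpora); pairs with an out-of-vocabulary word get
#' `score = NA` and `oov = TRUE`. Symmetric in the two words.
#'
#' @param model A `vf_embedding`.
#' @param w1,w2 Character vectors of words (recycled to equal length).
#' @return Tibble with columns `w1`, `w2`, `score`, `oov`.
#' @export
relatedness <- function(model, w1, w2) {
  w1 <- vf_normalize(w1); w2 <- vf_normalize(w2)
  n <- max(length(w1), length(w2))
  w1 <- rep_len(w1, n); w2 <- rep_len(w2, n)
  score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- lookup_row(model, w1[k]); j <- lookup_row(model, w2[k])
    if (!is.na(i) && !is.na(j)) {
      score[k] <- cosine(model$vectors[i, ], model$vectors[j, ])
    }
  }
  tibble(w1 = w1, w2 = w2, score = score, oov = is.na(score))
}

#' Relatedness of each sequential word pair in a transcript
#'
#' Scores the sequence of adjacent word pairs (word 1–word 2, word
#' 2–word 3, ...) produced in a fluency task. The mean of the defined
#' (non-OOV) scores is the mean sequential semantic relatedness reported
#' by [cluster_metrics()].
#'
#' @param model A `vf_embedding`.
#' @param words Character vector of at least two produced words, or a
#'   single-transcript `vf_tokens` tibble.
#' @return Tibble of `length(words) - 1` rows: `position` (index of the
#'   pair's first word), `w1`, `w2`, `score`, `oov`.
#' @export
sequential_relatedness <- function(model, words) {
  if (is.data.frame(words)) words <- words$normalized
  n <- length(words)
  if (n < 2) abort("Need at least 2 words to form sequential pairs.")
  out <- relatedness(model, words[-n], words[-1])
  dplyr::mutate(out, position = dplyr::row_number(), .before = 1)
}

#' Threshold configuration for relatedness clustering
#'
#' Fixed cosine thresholds define cluster membership: 0.40 for the
#' semantic task (the grid-search optimum against category-list
#' supervision) and 0.30 for the phonematic task (lowered for reasonably
#' sensitive cluster identification).
#'
#' @param task `"semantic"` or `"phonematic"`, selecting the default.
#' @param theta Explicit threshold in `[0, 1]`, overriding the default.
#' @return Numeric threshold.
#' @export
default_theta <- function(task = c("semantic", "phonematic"), theta = NULL) {
  if (!is.null(theta)) {
    stopifnot(theta >= 0, theta <= 1)
    return(theta)
  }
  task <- match.arg(task)
  if (task == "semantic") 0.40 else 0.30
}

#' Relatedness clustering of a fluency sequence
#'
#' Chains consecutive words whose pairwise semantic relatedness is
#' strictly greater than the threshold into clusters; maximal such runs
#' form clusters and all other words are singletons. Pairs with an
#' out-of-vocabulary word never join (their scores are excluded, not
#' scored as zero).
#'
#' @param words Character vector of produced words, or a
#'   single-transcript `vf_tokens` tibble.
#' @param model A `vf_embedding`.
#' @param theta Relatedness threshold; defaults per task via
#'   [default_theta()] (0.40 semantic).
#' @param task Task used for the default threshold.
#' @return A `vf_clustering` tagged `"relatedness"`, with attribute
#'   `scores` (the sequential-relatedness tibble).
#' @export
cluster_relatedness <- function(words, model, theta = NULL,
                                task = c("semantic", "phonematic")) {
  theta <- default_theta(match.arg(task), theta)
  if (is.data.frame(words)) words <- words$normalized
  n <- length(words)
  if (n < 2) {
    out <- clusters_from_joins(logical(0), method = "relatedness", n_tokens = n)
    attr(out, "scores") <- NULL
    return(out)
  }
  scores <- sequential_relatedness(model, words)
  join <- !scores$oov & scores$score > theta
  out <- clusters_from_joins(join, method = "relatedness", n_tokens = n)
  attr(out, "scores") <- scores
  attr(out, "theta") <- theta
  out
}

#' Read or write word2vec text format
#'
#' The standard word2vec text format: a header line `"V d"` (vocabulary
#' size and dimensionality), then one `"word v1 ... vd"` line per word.
#' Gzip-compressed files are handled transparently. Round trips are
#' lossless to the written float precision (8 significant digits).
#'
#' @param path File path (`.gz` allowed).
#' @return `read_word2vec()` returns a `vf_embedding`.
#' @export
read_word2vec <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, encoding = "UTF-8")
  if (length(lines) == 0) abort("Empty embedding file.")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) abort("Line 1: header must be 'vocab_size dims'.")
  v <- as.integer(header[1]); d <- as.integer(header[2])
  if (length(lines) - 1L != v) {
    abort(sprintf("Header declares %d words but file has %d rows.",
                  v, length(lines) - 1L))
  }
  mat <- matrix(NA_real_, v, d)
  words <- character(v)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      abort(sprintf("Line %d: expected %d values after the word, found %d.",
                    i + 1L, d, length(parts) - 1L))
    }
    words[i] <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) abort(sprintf("Line %d: non-numeric vector entry.", i + 1L))
    mat[i, ] <- vals
  }
  rownames(mat) <- words
  new_embedding(mat)
}

#' @rdname read_word2vec
#' @param model A `vf_embedding`.
#' @export
write_word2vec <- function(model, path) {
  mat <- model$vectors
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(
      rownames(mat)[i], paste(sprintf("%.8g", mat[i, ]), collapse = " ")
    ), con)
  }
  invisible(path)
}
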
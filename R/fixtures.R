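#' Built-in toy themes
#'
#' Two disjoint animal themes in English or German, small enough to
#' train toy embedding models in seconds. The German variant exercises
#' the umlaut-preserving normalization path without any external corpus.
#'
#' @param language `"en"` or `"de"`.
#' @return Named list of character vectors (theme -> words).
#' @export
vf_toy_themes <- function(language = c("en", "de")) {
  language <- match.arg(language)
  if (language == "en") {
    list(
      pets = c("dog", "cat", "hamster", "rabbit", "parrot", "goldfish",
               "pony", "kitten", "puppy", "canary"),
      africa = c("lion", "elephant", "giraffe", "zebra", "rhino", "hippo",
                 "cheetah", "antelope", "buffalo", "hyena")
    )
  } else {
    list(
      haustiere = c("hund", "katze", "hamster", "kaninchen", "wellensittich",
                    "goldfisch", "pony", "maus", "meerschweinchen", "kanarienvogel"),
      afrika = c("löwe", "elefant", "giraffe", "zebra", "nashorn",
                 "flusspferd", "gepard", "antilope", "büffel", "hyäne")
    )
  }
}

#' Toy category lexicon from themes
#'
#' Turns a theme list into a category lexicon (one category per theme;
#' categories disjoint unless the themes overlap), suitable for
#' list-based clustering and grid-search supervision on synthetic data.
#'
#' @param themes Named list of word vectors (default English toy themes).
#' @return A `vf_lexicon`.
#' @export
vf_toy_lexicon <- function(themes = vf_toy_themes()) {
  vf_lexicon(unlist(themes, use.names = FALSE),
             rep(names(themes), lengths(themes)))
}

#' Generate a toy training corpus with theme structure
#'
#' Emulates the essential property a relatedness model needs from a
#' large natural corpus: words of one theme co-occur in sentences.
#' Each sentence draws its tokens from a single home theme; each token
#' independently defects to another theme with probability
#' `cross_theme_rate`. Deterministic given the seed.
#'
#' @param themes Named list (length >= 2) of disjoint word vectors.
#' @param sentences_per_theme Sentences generated per theme (default 500).
#' @param sentence_length Tokens per sentence (default 8).
#' @param cross_theme_rate Per-token probability of a cross-theme word
#'   (default 0).
#' @param seed Integer seed.
#' @return Character vector of sentences (whitespace-joined tokens).
#' @examples
#' corp <- gen_toy_corpus(sentences_per_theme = 5, seed = 1)
#' @export
gen_toy_corpus <- function(themes = vf_toy_themes(), sentences_per_theme = 500,
                           sentence_length = 8, cross_theme_rate = 0,
                           seed = 1L) {
  stopifnot(length(themes) >= 1, cross_theme_rate >= 0, cross_theme_rate <= 1)
  if (any(lengths(themes) == 0)) abort("Every theme needs at least one word.")
  withr::with_seed(seed, {
    sentences <- character(0)
    for (th in names(themes)) {
      others <- unlist(themes[setdiff(names(themes), th)], use.names = FALSE)
      for (s in seq_len(sentences_per_theme)) {
        toks <- sample(themes[[th]], sentence_length, replace = TRUE)
        if (cross_theme_rate > 0 && length(others) > 0) {
          defect <- stats::runif(sentence_length) < cross_theme_rate
          if (any(defect)) {
            toks[defect] <- sample(others, sum(defect), replace = TRUE)
          }
        }
        sentences <- c(sentences, paste(toks, collapse = " "))
      }
    }
    sentences
  })
}

#' Generate a transcript with planted cluster structure
#'
#' Builds a fluency transcript realizing the requested cluster sizes:
#' cluster `k` draws `cluster_sizes[k]` distinct words from one category
#' of the lexicon, consecutive clusters from different categories, so
#' with disjoint categories list-based clustering recovers the planted
#' spans exactly. Optionally injects rule violations (repetitions of
#' earlier words, appended inside clusters and flagged in the ground
#' truth). Word onsets are evenly spaced from 1 s. Deterministic given
#' the seed.
#'
#' @param cluster_sizes Integer vector of words per cluster (all >= 1).
#' @param lexicon A `vf_lexicon` supplying vocabulary per category
#'   (default toy lexicon).
#' @param violation_rate Per-token probability of converting a planted
#'   word slot into a repetition violation (default 0).
#' @param seed Integer seed.
#' @param transcript_id,task,cue Transcript metadata.
#' @return List with `tokens` (a `vf_tokens` tibble, flags set on
#'   injected violations) and `truth` (the planted `vf_clustering`).
#' @examples
#' gen_transcript(c(3, 1, 2), seed = 7)$truth
#' @export
gen_transcript <- function(cluster_sizes, lexicon = vf_toy_lexicon(),
                           violation_rate = 0, seed = 1L,
                           transcript_id = "sim1", task = "semantic",
                           cue = "animals") {
  stopifnot(all(cluster_sizes >= 1), violation_rate >= 0, violation_rate <= 1)
  cats <- unique(lexicon$category)
  if (length(cats) < 2 && length(cluster_sizes) > 1) {
    abort("Need at least 2 categories to alternate clusters.")
  }
  withr::with_seed(seed, {
    words <- character(0)
    truth_ids <- integer(0)
    prev_cat <- NULL
    for (k in seq_along(cluster_sizes)) {
      pool_cats <- setdiff(cats, prev_cat)
      cat_k <- sample(pool_cats, 1)
      vocab <- lexicon$word[lexicon$category == cat_k]
      need <- cluster_sizes[k]
      if (length(vocab) < need) {
        abort(sprintf("Category '%s' has %d words; cluster needs %d.",
                      cat_k, length(vocab), need))
      }
      words <- c(words, sample(vocab, need))
      truth_ids <- c(truth_ids, rep(k, need))
      prev_cat <- cat_k
    }
    flags <- rep(list(character()), length(words))
    if (violation_rate > 0 && length(words) > 1) {
      for (i in 2:length(words)) {
        if (stats::runif(1) < violation_rate) {
          j <- sample(i - 1L, 1)
          words[i] <- words[j]
          flags[[i]] <- "repetition"
        }
      }
    }
    onsets <- seq(1, by = 58 / max(length(words), 1), length.out = length(words))
    tokens <- vf_tokens(words, transcript_id = transcript_id, task = task,
                        cue = cue, onset_s = onsets, flags = flags)
    truth <- clusters_from_joins(diff(truth_ids) == 0, method = "planted",
                                 n_tokens = length(words))
    list(tokens = tokens, truth = truth)
  })
}

#' Corrupt a word list with simulated recognition errors
#'
#' Emulates the word-level errors of automatic speech recognition that
#' manual correction later repairs: each word is independently hit with
#' probability `rate`; a hit applies one of the enabled operations
#' (substitution by a random letter string, insertion of a spurious word
#' after it, or deletion). Deterministic given the seed.
#'
#' @param words Character vector (the correct word list).
#' @param rate Per-word error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param ops Enabled operations, subset of
#'   `c("substitution", "insertion", "deletion")`.
#' @return Corrupted character vector.
#' @examples
#' corrupt_asr(c("hund", "katze", "maus"), rate = 1, seed = 1,
#'             ops = "substitution")
#' @export
corrupt_asr <- function(words, rate, seed = 1L,
                        ops = c("substitution", "insertion", "deletion")) {
  stopifnot(rate >= 0, rate <= 1)
  ops <- match.arg(ops, several.ok = TRUE)
  garble <- function() {
    paste(sample(letters, 6, replace = TRUE), collapse = "")
  }
  withr::with_seed(seed, {
    out <- character(0)
    for (w in words) {
      if (stats::runif(1) < rate) {
        op <- if (length(ops) == 1) ops else sample(ops, 1)
        if (op == "substitution") {
          out <- c(out, garble())
        } else if (op == "insertion") {
          out <- c(out, w, garble())
        }  # deletion: drop the word
      } else {
        out <- c(out, w)
      }
    }
    out
  })
}

#' Generate a synthetic neuropsychological score table
#'
#' Draws per-participant scores for a set of named instruments, each
#' optionally linearly coupled to a supplied driver variable (so planted
#' correlation structure can be recovered by the association layer),
#' plus Gaussian noise. Deterministic given the seed.
#'
#' @param participant_id Character vector of participant ids.
#' @param tests Named list: test name -> list with `mean`, `sd`, and
#'   optionally `driver` (numeric vector parallel to participants) and
#'   `slope`.
#' @param seed Integer seed.
#' @return Wide tibble: `participant_id` plus one numeric column per
#'   test.
#' @export
gen_score_table <- function(participant_id,
                            tests = list(
                              MoCA = list(mean = 26, sd = 3),
                              FAB = list(mean = 15, sd = 2),
                              TMT_B = list(mean = 90, sd = 30)
                            ),
                            seed = 1L) {
  n <- length(participant_id)
  withr::with_seed(seed, {
    out <- tibble(participant_id = as.character(participant_id))
    for (nm in names(tests)) {
      spec <- tests[[nm]]
      base <- stats::rnorm(n, spec$mean, spec$sd)
      if (!is.null(spec$driver)) {
        base <- base + (spec$slope %||% 1) * spec$driver
      }
      out[[nm]] <- base
    }
    out
  })
}
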
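#' Category lexicons
#'
#' A category lexicon maps words to thematic word lists (e.g. "pet",
#' "bird"); it drives the traditional list-based clustering of semantic
#' fluency and supervises the embedding grid search. A word may belong to
#' several lists — `parrot` is both a pet and a bird. The in-memory
#' representation is a long tibble with columns `word` (normalized) and
#' `category`, one row per membership.
#'
#' @param words Character vector of words.
#' @param categories Character vector of category labels, parallel to
#'   `words` (recycled if length 1).
#' @return A tibble of class `vf_lexicon` with columns `word`, `category`.
#' @examples
#' vf_lexicon(c("parrot", "parrot", "dog"), c("pet", "bird", "pet"))
#' @export
vf_lexicon <- function(words = character(), categories = character()) {
  if (length(categories) == 1 && length(words) > 1) {
    categories <- rep(categories, length(words))
  }
  if (length(words) != length(categories)) {
    abort("`words` and `categories` must have equal length.")
  }
  out <- dplyr::distinct(tibble(
    word = vf_normalize(words), category = as.character(categories)
  ))
  if (any(!nzchar(out$word)) || any(is.na(out$category) | !nzchar(out$category))) {
    abort("Lexicon entries must have non-empty word and category.")
  }
  class(out) <- c("vf_lexicon", class(tibble()))
  out
}

#' Read or write a category lexicon
#'
#' CSV schema: columns `word,category`, one row per membership (rows for
#' the same word union their categories). JSON schema: an object mapping
#' each word to a non-empty array of category labels. Words are
#' normalized on load; round trips are lossless up to normalization.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension by
#'   default.
#' @return `read_lexicon()` returns a `vf_lexicon` tibble.
#' @export
read_lexicon <- function(path, format = NULL) {
  format <- format %||% infer_format(path, c("csv", "json"))
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("word", "category") %in% names(df))) {
      abort("Lexicon CSV must have columns 'word' and 'category'.")
    }
    vf_lexicon(df$word, df$category)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (length(obj) == 0) return(vf_lexicon())
    lens <- lengths(obj)
    if (any(lens == 0)) {
      abort(sprintf(
        "Lexicon entry '%s' has zero categories.", names(obj)[lens == 0][1]
      ))
    }
    vf_lexicon(rep(names(obj), lens), unlist(obj, use.names = FALSE))
  }
}

#' @rdname read_lexicon
#' @param lexicon A `vf_lexicon` tibble.
#' @export
write_lexicon <- function(lexicon, path, format = NULL) {
  format <- format %||% infer_format(path, c("csv", "json"))
  if (format == "csv") {
    readr::write_csv(lexicon, path)
  } else {
    obj <- split(lexicon$category, lexicon$word)
    jsonlite::write_json(obj, path)
  }
  invisible(path)
}

word_categories <- function(lexicon, word) {
  lexicon$category[lexicon$word == word]
}

#' Categories shared by two words
#'
#' Returns the intersection of the two words' category sets; an
#' out-of-lexicon word contributes the empty set. Symmetric in its word
#' arguments.
#'
#' @param lexicon A `vf_lexicon` tibble.
#' @param w1,w2 Words (normalized on use).
#' @return Character vector of shared category labels (possibly empty).
#' @examples
#' lex <- vf_lexicon(c("parrot", "parrot", "dog"), c("pet", "bird", "pet"))
#' common_categories(lex, "parrot", "dog")
#' @export
common_categories <- function(lexicon, w1, w2) {
  intersect(
    word_categories(lexicon, vf_normalize(w1)),
    word_categories(lexicon, vf_normalize(w2))
  )
}

#' Sample supervision pairs from a lexicon
#'
#' Draws random unordered pairs of distinct lexicon words and labels each
#' pair by whether the two words share at least one category list. These
#' labelled pairs supervise the embedding hyperparameter grid search. By
#' default pairs are drawn uniformly without replacement (so class counts
#' fall where they may); `balanced = TRUE` draws equal numbers of
#' same-list and different-list pairs when both classes are large enough.
#'
#' @param lexicon A `vf_lexicon` with at least two distinct words.
#' @param n_pairs Number of pairs to draw; must not exceed the number of
#'   distinct unordered pairs (or the balanced-mode capacity).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param balanced Draw equally many positive and negative pairs.
#' @return Tibble with columns `w1`, `w2`, `same_list` (logical).
#' @export
sample_supervision_pairs <- function(lexicon, n_pairs, seed = 1L,
                                     balanced = FALSE) {
  words <- sort(unique(lexicon$word))
  v <- length(words)
  if (v < 2) abort("Lexicon must contain at least 2 distinct words.")
  total <- choose(v, 2)
  if (n_pairs > total) {
    abort(sprintf("n_pairs (%d) exceeds the %d distinct pairs available.",
                  n_pairs, total))
  }
  cat_sets <- split(lexicon$category, lexicon$word)[words]
  all_pairs <- utils::combn(v, 2)
  same <- vapply(seq_len(ncol(all_pairs)), function(k) {
    length(intersect(cat_sets[[all_pairs[1, k]]], cat_sets[[all_pairs[2, k]]])) > 0
  }, logical(1))
  idx <- withr::with_seed(seed, {
    if (balanced) {
      pos <- which(same); neg <- which(!same)
      half <- n_pairs %/% 2
      if (length(pos) < half || length(neg) < (n_pairs - half)) {
        abort("Not enough pairs in each class for balanced sampling.")
      }
      c(sample(pos, half), sample(neg, n_pairs - half))
    } else {
      sample(ncol(all_pairs), n_pairs)
    }
  })
  tibble(
    w1 = words[all_pairs[1, idx]],
    w2 = words[all_pairs[2, idx]],
    same_list = same[idx]
  )
}
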
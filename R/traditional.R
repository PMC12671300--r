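#' Phonematic clustering rule configuration
#'
#' Four rules decide whether two consecutively produced words belong to
#' one phonematic cluster: (1) the words start with the same two letters
#' ("summer", "sunday"); (2) the words rhyme ("sand", "stand"); (3) the
#' words differ in exactly one vowel sound ("sat", "seat"); (4) the words
#' are homonyms, when indicated by the speaker ("some", "sum"). Rules 2
#' and 3 are evaluated by a pluggable phonetizer; the default is a
#' transparent grapheme heuristic (see [rule_match()]).
#'
#' @param first_two_letters,rhyme,one_vowel_difference,homonym Enable the
#'   corresponding rule.
#' @return A list of class `vf_rules` with the enabled rule names.
#' @export
vf_rules <- function(first_two_letters = TRUE, rhyme = TRUE,
                     one_vowel_difference = TRUE, homonym = TRUE) {
  enabled <- c(
    if (first_two_letters) "first_two_letters",
    if (rhyme) "rhyme",
    if (one_vowel_difference) "one_vowel_difference",
    if (homonym) "homonym"
  )
  if (length(enabled) == 0) abort("At least one phonematic rule must be enabled.")
  structure(list(enabled = enabled), class = "vf_rules")
}

vowel_class <- "[aeiouäöüy]"

# split a word into maximal vowel/consonant runs; returns a tibble with
# run text and is_vowel flag, in order
grapheme_runs <- function(w) {
  if (!nzchar(w)) return(tibble(run = character(), is_vowel = logical()))
  runs <- stringi::stri_extract_all_regex(
    w, paste0(vowel_class, "+|[^aeiouäöüy]+")
  )[[1]]
  tibble(run = runs, is_vowel = stringi::stri_detect_regex(runs, vowel_class))
}

# suffix from the onset of the final vowel run (empty when no vowel)
rhyme_suffix <- function(w) {
  runs <- grapheme_runs(w)
  vi <- which(runs$is_vowel)
  if (length(vi) == 0) return(NA_character_)
  start <- sum(nchar(runs$run[seq_len(max(vi) - 1L)])) + 1L
  substr(w, start, nchar(w))
}

grapheme_rhyme <- function(w1, w2) {
  s1 <- rhyme_suffix(w1); s2 <- rhyme_suffix(w2)
  !is.na(s1) && !is.na(s2) && s1 == s2
}

grapheme_one_vowel_difference <- function(w1, w2) {
  r1 <- grapheme_runs(w1); r2 <- grapheme_runs(w2)
  if (nrow(r1) != nrow(r2)) return(FALSE)
  if (nrow(r1) == 0) return(FALSE)
  if (!identical(r1$is_vowel, r2$is_vowel)) return(FALSE)
  cons_equal <- all(r1$run[!r1$is_vowel] == r2$run[!r2$is_vowel])
  if (!cons_equal) return(FALSE)
  sum(r1$run[r1$is_vowel] != r2$run[r2$is_vowel]) == 1
}

#' Match phonematic clustering rules on a word pair
#'
#' Evaluates the enabled phonematic rules on a pair of normalized words
#' and returns every rule the pair satisfies. Rule 1 compares the first
#' two characters (words shorter than two characters never match). Rules
#' 2 and 3 use a grapheme heuristic standing in for true phonetics:
#' vowel groups are maximal runs of `a e i o u ä ö ü y`; two words rhyme
#' when they share the suffix starting at their final vowel group; they
#' differ in one vowel sound when their consonant-run skeletons are
#' identical and exactly one vowel group differs. Rule 4 (homonyms) is
#' annotation-driven: it fires only when a homonym table is supplied that
#' maps both words to the same pronunciation key, and — at the transcript
#' level — both tokens carry the `homonym_indicated` flag.
#'
#' @param w1,w2 Words (normalized on use).
#' @param rules A [vf_rules()] configuration.
#' @param homonyms Optional named character vector mapping words to
#'   pronunciation keys (e.g. `c(some = "sVm", sum = "sVm")`).
#' @param homonym_indicated Logical: were both tokens flagged as
#'   speaker-indicated homonyms? Defaults to `TRUE` for standalone word
#'   pairs; [cluster_rule_based()] passes the transcript annotation.
#' @return Character vector of matched rule names (possibly empty).
#' @examples
#' rule_match("summer", "sunday")
#' rule_match("sand", "stand")
#' rule_match("sat", "seat")
#' @export
rule_match <- function(w1, w2, rules = vf_rules(), homonyms = NULL,
                       homonym_indicated = TRUE) {
  w1 <- vf_normalize(w1); w2 <- vf_normalize(w2)
  matched <- character()
  if ("first_two_letters" %in% rules$enabled &&
      nchar(w1) >= 2 && nchar(w2) >= 2 &&
      substr(w1, 1, 2) == substr(w2, 1, 2)) {
    matched <- c(matched, "first_two_letters")
  }
  if ("rhyme" %in% rules$enabled && grapheme_rhyme(w1, w2)) {
    matched <- c(matched, "rhyme")
  }
  if ("one_vowel_difference" %in% rules$enabled &&
      grapheme_one_vowel_difference(w1, w2)) {
    matched <- c(matched, "one_vowel_difference")
  }
  if ("homonym" %in% rules$enabled && homonym_indicated && !is.null(homonyms)) {
    k1 <- homonyms[w1]; k2 <- homonyms[w2]
    if (!is.na(k1) && !is.na(k2) && k1 == k2) {
      matched <- c(matched, "homonym")
    }
  }
  matched
}

#' Rule-based clustering of a phonematic fluency sequence
#'
#' Consecutive words that satisfy at least one common phonematic rule are
#' chained into one cluster; maximal runs form the clusters and all other
#' words are singletons. Rule violations stay in the clustered sequence —
#' they are removed only from the total word count, at the metrics layer.
#'
#' @param words Character vector of produced words in order, or a
#'   `vf_tokens` tibble for a single transcript (then
#'   `homonym_indicated` flags are honoured).
#' @inheritParams rule_match
#' @return A `vf_clustering` with attribute `pair_rules`: a list, one
#'   entry per adjacent pair, of the rules that joined it (empty when not
#'   joined).
#' @examples
#' cluster_rule_based(c("simple", "simulate", "silly"))
#' @export
cluster_rule_based <- function(words, rules = vf_rules(), homonyms = NULL) {
  hom_flags <- NULL
  if (is.data.frame(words)) {
    stopifnot(length(unique(words$transcript_id)) <= 1)
    hom_flags <- vapply(words$flags, function(f) "homonym_indicated" %in% f, logical(1))
    words <- words$normalized
  }
  w <- vf_normalize(words)
  n <- length(w)
  pair_rules <- vector("list", max(n - 1L, 0L))
  join <- logical(max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    hom_ok <- if (is.null(hom_flags)) TRUE else hom_flags[i] && hom_flags[i + 1]
    pr <- rule_match(w[i], w[i + 1], rules, homonyms, homonym_indicated = hom_ok)
    pair_rules[[i]] <- pr
    join[i] <- length(pr) > 0
  }
  out <- clusters_from_joins(join, method = "rule_based", n_tokens = n)
  attr(out, "pair_rules") <- pair_rules
  out
}

#' List-based clustering of a semantic fluency sequence
#'
#' Consecutive words that occur on at least one common category list join
#' one cluster. The default joins by adjacent-pair chaining (word `i`
#' joins word `i+1` when the two share a list), mirroring the sequential
#' word-pair definition of the relatedness method;
#' `whole_cluster_common_list = TRUE` selects the stricter reading in
#' which every word of a cluster must share a common list with all words
#' already in it (the running intersection must stay non-empty).
#'
#' @param words Character vector of produced words in order, or a
#'   single-transcript `vf_tokens` tibble.
#' @param lexicon A `vf_lexicon`.
#' @param whole_cluster_common_list Use the running-intersection reading.
#' @return A `vf_clustering` tagged `"list_based"`.
#' @examples
#' lex <- vf_lexicon(c("dog", "parrot", "parrot", "eagle"),
#'                   c("pet", "pet", "bird", "bird"))
#' cluster_list_based(c("dog", "parrot", "eagle"), lex)
#' @export
cluster_list_based <- function(words, lexicon,
                               whole_cluster_common_list = FALSE) {
  if (is.data.frame(words)) {
    stopifnot(length(unique(words$transcript_id)) <= 1)
    words <- words$normalized
  }
  w <- vf_normalize(words)
  n <- length(w)
  cats <- lapply(w, function(x) word_categories(lexicon, x))
  if (!whole_cluster_common_list) {
    join <- vapply(seq_len(max(n - 1L, 0L)), function(i) {
      length(intersect(cats[[i]], cats[[i + 1]])) > 0
    }, logical(1))
    return(clusters_from_joins(join, method = "list_based", n_tokens = n))
  }
  # stricter reading: extend while the cluster-wide intersection survives
  join <- logical(max(n - 1L, 0L))
  if (n > 0) {
    running <- cats[[1]]
    for (i in seq_len(n - 1L)) {
      nxt <- intersect(running, cats[[i + 1]])
      if (length(nxt) > 0) {
        join[i] <- TRUE
        running <- nxt
      } else {
        running <- cats[[i + 1]]
      }
    }
  }
  clusters_from_joins(join, method = "list_based", n_tokens = n)
}

#' Census of phonematic rule usage across a corpus
#'
#' Counts, over a set of rule-based clusterings, how many joined adjacent
#' word pairs each rule accounts for. A pair matching several rules is
#' counted under each; on corpora where rules fire disjointly the counts
#' partition the joined pairs.
#'
#' @param clusterings A list of `vf_clustering` objects produced by
#'   [cluster_rule_based()] (their `pair_rules` attribute is required).
#' @return Tibble with columns `rule`, `n_pairs`, covering all four rules.
#' @export
rule_usage_census <- function(clusterings) {
  if (inherits(clusterings, "vf_clustering")) clusterings <- list(clusterings)
  all_rules <- c("first_two_letters", "rhyme", "one_vowel_difference", "homonym")
  counts <- stats::setNames(integer(length(all_rules)), all_rules)
  for (cl in clusterings) {
    pr <- attr(cl, "pair_rules")
    if (is.null(pr)) {
      abort("Clustering lacks per-pair rule records; use cluster_rule_based().")
    }
    for (rules_i in pr) {
      for (r in rules_i) counts[r] <- counts[r] + 1L
    }
  }
  tibble(rule = all_rules, n_pairs = as.integer(counts))
}
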
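# Independent brute-force oracles. Deliberately written with different
# algorithms/code paths than the package implementations they check.

# word-level Levenshtein by plain recursion (feasible for lists <= ~6)
oracle_levenshtein <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  sub <- oracle_levenshtein(a[-1], b[-1]) + (a[1] != b[1])
  del <- oracle_levenshtein(a[-1], b) + 1
  ins <- oracle_levenshtein(a, b[-1]) + 1
  min(sub, del, ins)
}

# adjacency-chaining clustering as an explicit left-to-right scan that
# builds cluster id vectors directly from a pair predicate
oracle_chain_assignments <- function(words, pair_joins) {
  n <- length(words)
  if (n == 0) return(integer(0))
  ids <- integer(n)
  ids[1] <- 1L
  for (i in seq_len(n - 1)) {
    ids[i + 1] <- if (pair_joins(i)) ids[i] else ids[i] + 1L
  }
  ids
}

# first-two-letter rule by character indexing (independent of substr use)
oracle_first2 <- function(w1, w2) {
  c1 <- strsplit(w1, "")[[1]]
  c2 <- strsplit(w2, "")[[1]]
  length(c1) >= 2 && length(c2) >= 2 && all(c1[1:2] == c2[1:2])
}

# rhyme by scanning characters from the right for the last vowel start
oracle_rhyme <- function(w1, w2) {
  vowels <- c("a", "e", "i", "o", "u", "ä", "ö", "ü", "y")
  suffix <- function(w) {
    ch <- strsplit(w, "")[[1]]
    if (length(ch) == 0) return(NA_character_)
    last_v <- max(c(0, which(ch %in% vowels)))
    if (last_v == 0) return(NA_character_)
    first_of_run <- last_v
    while (first_of_run > 1 && ch[first_of_run - 1] %in% vowels) {
      first_of_run <- first_of_run - 1
    }
    paste(ch[first_of_run:length(ch)], collapse = "")
  }
  s1 <- suffix(w1); s2 <- suffix(w2)
  !is.na(s1) && !is.na(s2) && s1 == s2
}

# one-vowel-group difference by run-length encoding over characters
oracle_one_vowel <- function(w1, w2) {
  vowels <- c("a", "e", "i", "o", "u", "ä", "ö", "ü", "y")
  rle_runs <- function(w) {
    ch <- strsplit(w, "")[[1]]
    if (length(ch) == 0) return(list(txt = character(), v = logical()))
    isv <- ch %in% vowels
    r <- rle(isv)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    list(
      txt = mapply(function(s, e) paste(ch[s:e], collapse = ""), starts, ends),
      v = r$values
    )
  }
  r1 <- rle_runs(w1); r2 <- rle_runs(w2)
  if (length(r1$v) == 0 || length(r1$v) != length(r2$v)) return(FALSE)
  if (!identical(r1$v, r2$v)) return(FALSE)
  if (!all(r1$txt[!r1$v] == r2$txt[!r2$v])) return(FALSE)
  sum(r1$txt[r1$v] != r2$txt[r2$v]) == 1
}

# Pearson by the raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# midranks computed by explicit position averaging
oracle_midrank <- function(x) {
  sapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  })
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Mann-Whitney U for group a by O(nm) pair enumeration with half-ties
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

random_word <- function(len = NULL, alphabet = letters[1:6]) {
  len <- len %||% sample(2:6, 1)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
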
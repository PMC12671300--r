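#' Flags that count as task-rule violations
#'
#' Repetitions, same-stem words, and proper names are disallowed by the
#' task instructions; a cue-initial mismatch in the letter-fluency task is
#' treated as a violation of the task as well. The `homonym_indicated`
#' annotation is *not* a violation: it is a manual marker that a produced
#' word was indicated as a homonym by the speaker.
#'
#' @format Character vector of flag names.
#' @export
vf_violation_flags <- c("repetition", "same_stem", "proper_name", "cue_mismatch")

all_known_flags <- c(vf_violation_flags, "homonym_indicated")

#' Build a transcript token table
#'
#' The package represents verbal-fluency transcripts as a long tibble with
#' one row per produced word, so a corpus of transcripts is a single data
#' frame that flows through `dplyr`. Columns: `transcript_id`, `task`
#' (`"semantic"` or `"phonematic"`), `cue` (category name or initial
#' letter), `duration_s`, `source` (`"asr"` or `"manual"`), `position`
#' (1-based within transcript), `surface`, `normalized`, `onset_s`
#' (seconds from task start, `NA` when unknown), and `flags` (list column
#' of character vectors).
#'
#' @param surface Character vector of produced words, in production order.
#' @param transcript_id Identifier for this transcript.
#' @param task `"semantic"` or `"phonematic"`.
#' @param cue Category name (semantic) or initial letter (phonematic).
#' @param duration_s Recording duration in seconds (default 60).
#' @param source `"manual"` (corrected) or `"asr"` (automatic).
#' @param onset_s Optional numeric vector of word onsets in seconds;
#'   must be non-negative and non-decreasing where present.
#' @param flags Optional list of character vectors of pre-set annotations
#'   (e.g. manual `same_stem` or `homonym_indicated` marks).
#' @return A tibble of class `vf_tokens`.
#' @examples
#' vf_tokens(c("hund", "katze", "maus"), transcript_id = "p01")
#' @export
vf_tokens <- function(surface, transcript_id = "t1",
                      task = c("semantic", "phonematic"),
                      cue = NULL, duration_s = 60, source = c("manual", "asr"),
                      onset_s = NULL, flags = NULL) {
  task <- match.arg(task)
  source <- match.arg(source)
  surface <- as.character(surface)
  n <- length(surface)
  cue <- cue %||% if (task == "semantic") "animals" else "s"
  if (is.null(onset_s)) onset_s <- rep(NA_real_, n)
  if (length(onset_s) != n) abort("`onset_s` must have one value per word.")
  if (is.null(flags)) flags <- rep(list(character()), n)
  if (!is.list(flags) || length(flags) != n) {
    abort("`flags` must be a list with one character vector per word.")
  }
  flags <- lapply(flags, as.character)
  out <- tibble(
    transcript_id = as.character(transcript_id),
    task = task, cue = as.character(cue),
    duration_s = as.numeric(duration_s), source = source,
    position = seq_len(n), surface = surface,
    normalized = vf_normalize(surface),
    onset_s = as.numeric(onset_s), flags = flags
  )
  validate_tokens(out)
  class(out) <- c("vf_tokens", class(tibble()))
  out
}

validate_tokens <- function(tokens, where = NULL) {
  loc <- if (is.null(where)) "" else paste0(" in ", where)
  if (any(!is.na(tokens$onset_s) & tokens$onset_s < 0)) {
    bad <- which(!is.na(tokens$onset_s) & tokens$onset_s < 0)[1]
    abort(sprintf("Negative onset_s at row %d%s.", bad, loc))
  }
  if (any(!nzchar(tokens$normalized) & nzchar(tokens$surface))) {
    abort(sprintf("Normalization produced an empty form%s.", loc))
  }
  split_onsets <- split(tokens$onset_s, tokens$transcript_id)
  for (id in names(split_onsets)) {
    on <- split_onsets[[id]][!is.na(split_onsets[[id]])]
    if (length(on) > 1 && any(diff(on) < 0)) {
      abort(sprintf("onset_s must be non-decreasing within transcript '%s'%s.", id, loc))
    }
  }
  invisible(tokens)
}

has_violation <- function(flags) {
  vapply(flags, function(f) any(f %in% vf_violation_flags), logical(1))
}

#' Mark rule violations in transcript tokens
#'
#' Populates the `flags` column with automatically detectable violations:
#' exact repetitions (a later token with an identical normalized form),
#' same-stem words (only when a word-to-stem map is supplied; the later
#' token of a stem-sharing pair is flagged), proper names (from a supplied
#' name set), and — for phonematic transcripts — words that do not start
#' with the cue letter. Pre-existing flags are preserved (manual
#' annotation remains the pathway for stems and names when no lexicon is
#' available).
#'
#' @param tokens A `vf_tokens` tibble (may hold many transcripts).
#' @param stems Optional named character vector mapping normalized words
#'   to stems; absence disables same-stem detection.
#' @param proper_names Optional character vector of proper names
#'   (normalized on use); absence disables proper-name detection.
#' @param check_cue Flag non-cue-initial words in phonematic transcripts
#'   as `cue_mismatch` violations (default `TRUE`; set `FALSE` for the
#'   permissive reading).
#' @return The token tibble with updated `flags`.
#' @examples
#' tr <- vf_tokens(c("hund", "katze", "hund"))
#' mark_violations(tr)$flags
#' @export
mark_violations <- function(tokens, stems = NULL, proper_names = NULL,
                            check_cue = TRUE) {
  if (!is.null(proper_names)) proper_names <- vf_normalize(proper_names)
  if (!is.null(stems) && is.null(names(stems))) {
    abort("`stems` must be a named character vector (word -> stem).")
  }
  dplyr::group_modify(
    dplyr::group_by(tokens, .data$transcript_id),
    function(df, key) mark_violations_one(df, stems, proper_names, check_cue)
  ) |>
    dplyr::ungroup() |>
    dplyr::relocate("transcript_id") |>
    preserve_tokens_class()
}

mark_violations_one <- function(df, stems, proper_names, check_cue) {
  w <- df$normalized
  n <- length(w)
  flags <- df$flags
  if (n == 0) return(df)
  rep_flag <- duplicated(w)
  stem_flag <- rep(FALSE, n)
  if (!is.null(stems)) {
    st <- unname(stems[w])
    seen <- character()
    for (i in seq_len(n)) {
      if (!is.na(st[i]) && st[i] %in% seen && !rep_flag[i]) stem_flag[i] <- TRUE
      if (!is.na(st[i])) seen <- c(seen, st[i])
    }
  }
  name_flag <- if (!is.null(proper_names)) w %in% proper_names else rep(FALSE, n)
  cue_flag <- rep(FALSE, n)
  if (check_cue && df$task[1] == "phonematic") {
    cue_letter <- vf_normalize(substr(df$cue[1], 1L, 1L))
    cue_flag <- substr(w, 1L, 1L) != cue_letter
  }
  for (i in seq_len(n)) {
    add <- c(
      if (rep_flag[i]) "repetition",
      if (stem_flag[i]) "same_stem",
      if (name_flag[i]) "proper_name",
      if (cue_flag[i]) "cue_mismatch"
    )
    flags[[i]] <- union(flags[[i]], add)
  }
  df$flags <- flags
  df
}

preserve_tokens_class <- function(x) {
  class(x) <- unique(c("vf_tokens", class(tibble())))
  x
}

#' Quality control for transcripts
#'
#' Applies the exclusion rules used before any clustering: a transcript is
#' excluded when more than 25% of its tokens carry a violation flag
#' (strictly greater, so exactly 25% is retained), when no word onset
#' falls within the first 10 seconds (`onset_s < 10`; skipped with a
#' message when onsets are absent), or when it is empty.
#'
#' @param tokens A `vf_tokens` tibble with violations already marked.
#' @param first10_rule Apply the 10-second rule (default `TRUE`).
#' @param quiet Suppress the message emitted when the 10-second rule is
#'   skipped for transcripts without onsets.
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `n_tokens`, `n_violations`, `violation_fraction`, `excluded`, and
#'   `reasons` (semicolon-joined; empty string when retained).
#' @examples
#' tr <- mark_violations(vf_tokens(c("hund", "katze", "hund", "maus")))
#' qc_transcripts(tr)
#' @export
qc_transcripts <- function(tokens, first10_rule = TRUE, quiet = FALSE) {
  if (nrow(tokens) == 0) {
    # an empty token table is one empty transcript: excluded, reason empty
    return(tibble(
      transcript_id = NA_character_, n_tokens = 0L, n_violations = 0L,
      violation_fraction = 0, excluded = TRUE, reasons = "empty"
    ))
  }
  ids <- unique(tokens$transcript_id)
  rows <- lapply(ids, function(id) {
    df <- tokens[tokens$transcript_id == id, ]
    n <- nrow(df)
    nv <- sum(has_violation(df$flags))
    frac <- if (n == 0) 0 else nv / n
    reasons <- character()
    if (n == 0) reasons <- c(reasons, "empty")
    if (n > 0 && frac > 0.25) reasons <- c(reasons, "violation_rate_gt_25pct")
    if (n > 0 && first10_rule) {
      onsets <- df$onset_s
      if (all(is.na(onsets))) {
        if (!quiet) {
          inform(sprintf(
            "Transcript '%s' has no onsets; 10-second rule skipped.", id
          ))
        }
      } else if (!any(onsets < 10.0, na.rm = TRUE)) {
        reasons <- c(reasons, "no_word_in_first_10s")
      }
    }
    tibble(
      transcript_id = id, n_tokens = n, n_violations = nv,
      violation_fraction = frac,
      excluded = length(reasons) > 0,
      reasons = paste(reasons, collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}

#' Word-level error rate between an automatic and a corrected transcript
#'
#' Computes the word-level Levenshtein distance between the automatically
#' recognized word list and the manually corrected word list — the minimal
#' number of word insertions, deletions, and substitutions turning the
#' automatic list into the correct one — and normalizes it by the length
#' of the correct list. Words are compared on their normalized forms.
#' The reported operation counts come from one minimal-cost alignment
#' (the decomposition need not be unique; the total always is).
#'
#' @param auto Character vector: automatic (ASR) word list.
#' @param correct Character vector: corrected word list; must be non-empty.
#' @return A one-row tibble: `insertions`, `deletions`, `substitutions`,
#'   `distance`, `normalized`.
#' @examples
#' word_error_rate(c("katze", "maus"), c("katze", "hund", "maus"))
#' @export
word_error_rate <- function(auto, correct) {
  if (length(correct) == 0) {
    abort("`correct` must be non-empty (normalization divides by its length).")
  }
  a <- vf_normalize(auto)
  b <- vf_normalize(correct)
  n <- length(a)
  m <- length(b)
  # DP over prefixes: d[i+1, j+1] = distance(a[1:i], b[1:j])
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0L:n
  d[1L, ] <- 0L:m
  if (n > 0 && m > 0) {
    for (i in 1:n) {
      for (j in 1:m) {
        sub_cost <- if (a[i] == b[j]) 0L else 1L
        d[i + 1L, j + 1L] <- min(
          d[i, j + 1L] + 1L,      # delete a[i]
          d[i + 1L, j] + 1L,      # insert b[j]
          d[i, j] + sub_cost      # match/substitute
        )
      }
    }
  }
  # backtrace one optimal alignment for operation counts
  ins <- del <- sub <- 0L
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && d[i + 1L, j + 1L] == d[i, j] + (a[i] != b[j])) {
      if (a[i] != b[j]) sub <- sub + 1L
      i <- i - 1L; j <- j - 1L
    } else if (j > 0 && d[i + 1L, j + 1L] == d[i + 1L, j] + 1L) {
      ins <- ins + 1L; j <- j - 1L
    } else {
      del <- del + 1L; i <- i - 1L
    }
  }
  dist <- d[n + 1L, m + 1L]
  tibble(
    insertions = ins, deletions = del, substitutions = sub,
    distance = as.integer(dist), normalized = dist / m
  )
}
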
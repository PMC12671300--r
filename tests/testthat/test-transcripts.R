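test_that("normalization trims, lowercases, and preserves umlauts", {
  expect_equal(vf_normalize(c("  Hund ", "LÖWE", "Straße")),
               c("hund", "löwe", "straße"))
  expect_false(vf_normalize("löwe") == vf_normalize("lowe"))
})

test_that("violation marking detects repetitions, stems, names, cue mismatches", {
  tr <- mark_violations(vf_tokens(c("hund", "katze", "hund")))
  expect_equal(tr$flags, list(character(), character(), "repetition"))

  stems <- c(sonne = "sonn", sonnig = "sonn")
  tr2 <- mark_violations(vf_tokens(c("sonne", "sonnig")), stems = stems)
  expect_equal(tr2$flags[[2]], "same_stem")
  # without a stem map the detector is off
  tr2b <- mark_violations(vf_tokens(c("sonne", "sonnig")))
  expect_equal(tr2b$flags[[2]], character())

  # valid produced words carry no flags
  tr3 <- mark_violations(vf_tokens(c("salat", "sellerie", "salami"),
                                   task = "phonematic", cue = "s"))
  expect_true(all(lengths(tr3$flags) == 0))

  tr4 <- mark_violations(vf_tokens(c("sonne", "berlin"),
                                   task = "phonematic", cue = "S"),
                         proper_names = c("Berlin"))
  expect_setequal(tr4$flags[[2]], c("proper_name", "cue_mismatch"))
  tr4b <- mark_violations(vf_tokens(c("sonne", "berlin"),
                                    task = "phonematic", cue = "S"),
                          check_cue = FALSE)
  expect_equal(tr4b$flags[[2]], character())

  # pre-existing manual flags survive
  tr5 <- mark_violations(vf_tokens(c("some", "sum"), task = "phonematic",
                                   cue = "s",
                                   flags = list("homonym_indicated",
                                                "homonym_indicated")))
  expect_true(all(vapply(tr5$flags, function(f)
    "homonym_indicated" %in% f, logical(1))))
})

test_that("QC applies the >25% rule strictly and the 10-second rule", {
  mk <- function(n, n_flagged, first_onset = 1) {
    flags <- c(rep(list("repetition"), n_flagged),
               rep(list(character()), n - n_flagged))
    vf_tokens(sprintf("w%02d", seq_len(n)), onset_s = seq(first_onset, by = 1,
                                                          length.out = n),
              flags = flags[order(seq_len(n))])
  }
  over <- qc_transcripts(mk(10, 3))
  expect_true(over$excluded)
  expect_equal(over$reasons, "violation_rate_gt_25pct")
  expect_equal(over$violation_fraction, 0.3)

  at_boundary <- qc_transcripts(mk(8, 2))   # exactly 25%
  expect_false(at_boundary$excluded)

  ok <- qc_transcripts(mk(5, 0, first_onset = 2.1))
  expect_false(ok$excluded)

  late <- qc_transcripts(mk(5, 0, first_onset = 10.5))
  expect_true(late$excluded)
  expect_equal(late$reasons, "no_word_in_first_10s")

  # boundary: onset exactly 10.0 is not within the first 10 seconds
  at10 <- qc_transcripts(mk(5, 0, first_onset = 10.0))
  expect_true(at10$excluded)

  empty <- qc_transcripts(vf_tokens(character()))
  expect_true(empty$excluded)
  expect_equal(empty$reasons, "empty")
  expect_equal(empty$violation_fraction, 0)

  # no onsets: the rule is skipped (with a message), not fired
  no_onset <- vf_tokens(c("a1", "b2", "c3"))
  expect_message(res <- qc_transcripts(no_onset), "skipped")
  expect_false(res$excluded)
})

test_that("QC is idempotent, ignores surfaces, and all-flagged always excludes", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(1:12, 1)
      flags <- lapply(seq_len(n), function(i) {
        if (stats::runif(1) < 0.3) sample(vf_violation_flags, 1) else character()
      })
      tr <- vf_tokens(replicate(n, random_word()), onset_s = sort(runif(n, 0, 30)),
                      flags = flags)
      q1 <- qc_transcripts(tr, quiet = TRUE)
      q2 <- qc_transcripts(tr, quiet = TRUE)
      expect_identical(q1, q2)
      # renaming surfaces must not change QC
      tr_renamed <- tr
      tr_renamed$surface <- paste0("x", seq_len(n))
      tr_renamed$normalized <- tr_renamed$surface
      expect_equal(qc_transcripts(tr_renamed, quiet = TRUE)[-1],
                   q1[-1])
    }
  })
  all_flagged <- vf_tokens(c("a1", "b2"), flags = list("repetition", "proper_name"))
  q <- qc_transcripts(all_flagged)
  expect_equal(q$violation_fraction, 1.0)
  expect_true(q$excluded)
})

test_that("word error rate matches hand-worked and degenerate cases", {
  same <- word_error_rate(c("katze", "hund"), c("katze", "hund"))
  expect_equal(same$distance, 0L)
  expect_equal(same$normalized, 0)

  none <- word_error_rate(character(), c("a", "b", "c"))
  expect_equal(none$distance, 3L)
  expect_equal(none$normalized, 1.0)
  expect_equal(none$insertions, 3L)

  one <- word_error_rate(c("katze", "maus"), c("katze", "hund", "maus"))
  expect_equal(one$distance, 1L)
  expect_equal(one$normalized, 1 / 3)
  expect_equal(one$insertions, 1L)

  expect_error(word_error_rate(c("a"), character()), "non-empty")
})

test_that("word error rate equals the recursive oracle and is metric-like", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      a <- replicate(sample(1:6, 1), random_word(alphabet = letters[1:3]))
      b <- replicate(sample(1:6, 1), random_word(alphabet = letters[1:3]))
      c_ <- replicate(sample(1:6, 1), random_word(alphabet = letters[1:3]))
      res <- word_error_rate(a, b)
      expect_equal(res$distance, oracle_levenshtein(a, b))
      expect_equal(res$insertions + res$deletions + res$substitutions,
                   res$distance)
      # symmetry up to swapping insertions and deletions
      rev <- word_error_rate(b, a)
      expect_equal(rev$distance, res$distance)
      expect_equal(rev$insertions, res$deletions)
      expect_equal(rev$deletions, res$insertions)
      # triangle inequality
      expect_lte(res$distance,
                 word_error_rate(a, c_)$distance +
                   word_error_rate(c_, b)$distance)
    }
  })
})

test_that("transcripts round-trip through JSONL and CSV", {
  tr <- dplyr::bind_rows(
    vf_tokens(c("hund", "katze", "hund"), transcript_id = "p1",
              onset_s = c(1.2, 3.4, 50), flags = list(character(),
                                                      character(),
                                                      "repetition")),
    vf_tokens(c("sonne", "salat"), transcript_id = "p2", task = "phonematic",
              cue = "s", source = "asr")
  )
  for (ext in c("jsonl", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_transcripts(tr, f)
    back <- read_transcripts(f)
    expect_equal(as.data.frame(back), as.data.frame(tr))
  }
  # cross-format equality
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_transcripts(tr, f1); write_transcripts(tr, f2)
  expect_equal(as.data.frame(read_transcripts(f1)),
               as.data.frame(read_transcripts(f2)))
})

test_that("malformed transcript files fail with line information", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"transcript_id":"a","task":"semantic","cue":"animals","tokens":[{"surface":"dog"}]}',
    '{"transcript_id":"b","task":"semantic","cue":"animals","tokens":[{"surface":"cat","onset_s":-2}]}'
  ), f)
  expect_error(read_transcripts(f), "Line 2.*onset_s")

  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"task":"semantic","cue":"animals","tokens":[]}', f2)
  expect_error(read_transcripts(f2), "transcript_id")

  # non-monotone onsets violate the data model
  expect_error(vf_tokens(c("a1", "b2"), onset_s = c(5, 2)), "non-decreasing")
})
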
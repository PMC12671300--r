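test_that("phonematic rules match their canonical word pairs", {
  expect_equal(rule_match("summer", "sunday"), "first_two_letters")
  expect_true("rhyme" %in% rule_match("sand", "stand"))
  expect_true("one_vowel_difference" %in% rule_match("sat", "seat"))
  # identical words trivially share the first two letters
  expect_true("first_two_letters" %in% rule_match("wolf", "wolf"))
  # words shorter than two characters never match rule 1
  expect_false("first_two_letters" %in% rule_match("a", "ab"))
  # disabled rules never fire
  cfg <- vf_rules(first_two_letters = TRUE, rhyme = FALSE,
                  one_vowel_difference = FALSE, homonym = FALSE)
  expect_equal(rule_match("sand", "stand", cfg), character(0))
  expect_error(vf_rules(FALSE, FALSE, FALSE, FALSE), "At least one")
})

test_that("homonym rule is annotation-driven", {
  hom <- c(some = "sVm", sum = "sVm")
  expect_true("homonym" %in% rule_match("some", "sum", homonyms = hom))
  # without a homonym table the rule cannot fire
  expect_false("homonym" %in% rule_match("some", "sum"))
  # without speaker indication the rule cannot fire
  expect_false("homonym" %in%
                 rule_match("some", "sum", homonyms = hom,
                            homonym_indicated = FALSE))
  # and the flag gating flows from transcript annotations
  tr <- vf_tokens(c("some", "sum"), task = "phonematic", cue = "s",
                  flags = list("homonym_indicated", character()))
  cl <- cluster_rule_based(tr, homonyms = hom)
  expect_equal(nrow(cl), 2)  # only one token flagged: no join
})

test_that("rule-based clustering chains adjacent matches", {
  cl <- cluster_rule_based(c("simple", "simulate", "silly"))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 2)

  single <- cluster_rule_based("wolf")
  expect_equal(single$size, 0)

  mixed <- cluster_rule_based(c("summer", "sat", "seat", "tiger"))
  expect_equal(cluster_assignments(mixed), c(1, 2, 2, 3))

  empty <- cluster_rule_based(character())
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_tokens"), 0)
})

test_that("rule-1-only clustering equals a brute-force prefix-bigram scan", {
  cfg <- vf_rules(TRUE, FALSE, FALSE, FALSE)
  withr::with_seed(7, {
    for (rep in 1:50) {
      words <- replicate(sample(1:10, 1), random_word(alphabet = letters[1:4]))
      got <- cluster_assignments(cluster_rule_based(words, cfg))
      want <- oracle_chain_assignments(words, function(i) {
        oracle_first2(words[i], words[i + 1])
      })
      expect_equal(got, want)
    }
  })
})

test_that("grapheme rhyme and vowel rules agree with character-level oracles", {
  withr::with_seed(8, {
    for (rep in 1:200) {
      w1 <- random_word(alphabet = c("s", "t", "n", "a", "e", "i"))
      w2 <- if (runif(1) < 0.5) {
        # perturb w1 to make near-misses likely
        ch <- strsplit(w1, "")[[1]]
        ch[sample(length(ch), 1)] <- sample(c("a", "e", "t"), 1)
        paste(ch, collapse = "")
      } else {
        random_word(alphabet = c("s", "t", "n", "a", "e", "i"))
      }
      m <- rule_match(w1, w2)
      expect_equal("rhyme" %in% m, oracle_rhyme(w1, w2),
                   info = paste(w1, w2))
      expect_equal("one_vowel_difference" %in% m, oracle_one_vowel(w1, w2),
                   info = paste(w1, w2))
    }
  })
})

test_that("list-based clustering joins words sharing a list", {
  lex <- vf_lexicon(c("dog", "parrot", "parrot", "eagle"),
                    c("pet", "pet", "bird", "bird"))
  cl <- cluster_list_based(c("dog", "parrot"), lex)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 1)

  # chaining joins dog-parrot (pet) and parrot-eagle (bird) into one run
  chain <- cluster_list_based(c("dog", "parrot", "eagle"), lex)
  expect_equal(nrow(chain), 1)
  expect_equal(chain$size, 2)

  # the stricter whole-cluster reading splits that run
  strict <- cluster_list_based(c("dog", "parrot", "eagle"), lex,
                               whole_cluster_common_list = TRUE)
  expect_equal(cluster_assignments(strict), c(1, 1, 2))

  # pairwise-disjoint categories -> all singletons
  disj <- vf_lexicon(c("a", "b", "c"), c("x", "y", "z"))
  singles <- cluster_list_based(c("a", "b", "c"), disj)
  expect_equal(nrow(singles), 3)
  expect_true(all(singles$size == 0))

  # everything on one list -> one cluster
  one <- vf_lexicon(c("a", "b", "c"), "only")
  expect_equal(nrow(cluster_list_based(c("a", "b", "c"), one)), 1)

  expect_equal(nrow(cluster_list_based(character(), lex)), 0)
})

test_that("list-based clustering equals an explicit adjacency scan on random input", {
  withr::with_seed(9, {
    vocab <- paste0("w", 1:12)
    for (rep in 1:50) {
      lex <- vf_lexicon(sample(vocab, 18, replace = TRUE),
                        sample(c("c1", "c2", "c3", "c4"), 18, replace = TRUE))
      words <- sample(vocab, sample(2:10, 1), replace = TRUE)
      got <- cluster_assignments(cluster_list_based(words, lex))
      want <- oracle_chain_assignments(words, function(i) {
        length(common_categories(lex, words[i], words[i + 1])) > 0
      })
      expect_equal(got, want)
    }
  })
})

test_that("rule usage census counts joined pairs per rule", {
  # fixture with three first-two-letter-only pairs and one rhyme-only pair
  cls <- list(
    cluster_rule_based(c("summer", "sunday")),
    cluster_rule_based(c("tiger", "tiny")),
    cluster_rule_based(c("wolf", "word")),
    cluster_rule_based(c("mand", "stand"))
  )
  census <- rule_usage_census(cls)
  counts <- stats::setNames(census$n_pairs, census$rule)
  expect_equal(unname(counts["first_two_letters"]), 3L)
  expect_equal(unname(counts["rhyme"]), 1L)
  expect_equal(unname(counts["one_vowel_difference"]), 0L)
  expect_equal(unname(counts["homonym"]), 0L)

  # no matching pairs -> all zero
  none <- rule_usage_census(cluster_rule_based(c("dog", "elk")))
  expect_true(all(none$n_pairs == 0))

  # when matched rules are disjoint, counts sum to the joined pair count
  joined <- sum(vapply(cls, function(cl) {
    sum(lengths(attr(cl, "pair_rules")) > 0)
  }, numeric(1)))
  expect_equal(sum(census$n_pairs), joined)
})

test_that("clusterings always cover the sequence contiguously", {
  withr::with_seed(10, {
    for (rep in 1:40) {
      n <- sample(0:15, 1)
      join <- if (n > 1) runif(n - 1) < 0.5 else logical(0)
      cl <- clusters_from_joins(join, n_tokens = n)
      expect_equal(sum(cl$size + 1), n)
      if (n > 0) {
        expect_equal(cl$start[1], 1)
        expect_equal(cl$end[nrow(cl)], n)
        if (nrow(cl) > 1) {
          expect_equal(cl$start[-1], cl$end[-nrow(cl)] + 1)
        }
      }
    }
  })
})
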
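# tiny hand-built model used throughout
hand_model <- function() {
  m <- rbind(
    a = c(1, 0), b = c(0, 1), c = c(1, 1),
    Katze = c(0.5, 0.5)
  )
  embedding_model(m)
}

test_that("relatedness is the cosine, symmetric, with OOV marking", {
  m <- hand_model()
  expect_equal(relatedness(m, "a", "a")$score, 1.0)
  expect_equal(relatedness(m, "a", "b")$score, 0.0)
  expect_equal(relatedness(m, "a", "c")$score, 1 / sqrt(2))
  expect_equal(relatedness(m, "a", "c")$score, 0.70710678, tolerance = 1e-8)
  expect_equal(relatedness(m, "c", "a")$score, relatedness(m, "a", "c")$score)
  oov <- relatedness(m, "a", "zebra")
  expect_true(oov$oov)
  expect_true(is.na(oov$score))
  # capitalized-variant fallback for corpus-cased vocabularies
  expect_false(relatedness(m, "katze", "a")$oov)
  # zero-norm vectors are an error, not a silent zero
  z <- embedding_model(rbind(zero = c(0, 0), a = c(1, 0)))
  expect_error(relatedness(z, "zero", "a"), "zero-norm")
})

test_that("sequential relatedness scores adjacent pairs with positional OOV bookkeeping", {
  m <- hand_model()
  s <- sequential_relatedness(m, c("a", "c", "b"))
  expect_equal(nrow(s), 2)
  expect_equal(s$score, c(1 / sqrt(2), 1 / sqrt(2)))

  same <- sequential_relatedness(m, rep("a", 5))
  expect_equal(same$score, rep(1, 4))

  mixed <- sequential_relatedness(m, c("a", "zebra", "b"))
  expect_equal(mixed$oov, c(TRUE, TRUE))
  expect_error(sequential_relatedness(m, "a"), "at least 2")
})

test_that("threshold clustering joins strictly above theta and breaks on OOV", {
  # scores 0.6, 0.2, 0.5 at theta 0.40 -> [w1 w2] [w3 w4]
  scores <- c(0.6, 0.2, 0.5)
  cl <- clusters_from_joins(scores > 0.40, method = "relatedness")
  expect_equal(cluster_assignments(cl), c(1, 1, 2, 2))
  expect_equal(nrow(cl) - 1, 1)  # one switch

  # via the full path: vectors engineered to those cosines
  ang <- function(a) c(cos(a), sin(a))
  a1 <- 0; a2 <- acos(0.6); a3 <- a2 + acos(0.2); a4 <- a3 - acos(0.5)
  m2 <- embedding_model(rbind(v1 = ang(a1), v2 = ang(a2), v3 = ang(a3),
                              v4 = ang(a4)))
  cl2 <- cluster_relatedness(c("v1", "v2", "v3", "v4"), m2, theta = 0.40)
  expect_equal(cluster_assignments(cl2), c(1, 1, 2, 2))

  # strictness: a score exactly at theta does not join (cosine of a word
  # with itself is exactly 1, never > 1)
  cl_eq <- cluster_relatedness(c("v1", "v1"), m2, theta = 1)
  expect_equal(nrow(cl_eq), 2)

  # OOV pairs never join
  cl_oov <- cluster_relatedness(c("v1", "nope", "v2"), m2, theta = 0)
  expect_equal(nrow(cl_oov), 3)
  expect_equal(sum(attr(cl_oov, "scores")$oov), 2)

  # default thresholds per task
  expect_equal(default_theta("semantic"), 0.40)
  expect_equal(default_theta("phonematic"), 0.30)
})

test_that("clusters are monotone in theta: switches up, mean size down", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(3:20, 1)
      scores <- runif(n - 1)
      prev_switches <- -1
      prev_mean <- Inf
      for (th in seq(0, 1, by = 0.05)) {
        cl <- clusters_from_joins(scores > th, n_tokens = n)
        k <- nrow(cl)
        switches <- k - 1
        mean_size <- n / k - 1
        expect_gte(switches, prev_switches)
        expect_lte(mean_size, prev_mean + 1e-12)
        prev_switches <- switches
        prev_mean <- mean_size
      }
      # theta = 0 with positive scores: one cluster; theta >= 1: singletons
      expect_equal(nrow(clusters_from_joins(scores > 0, n_tokens = n)), 1)
      expect_equal(nrow(clusters_from_joins(scores > 1, n_tokens = n)), n)
    }
  })
})

test_that("training fills the vocabulary, respects dims, and is reproducible", {
  corp <- c("dog cat dog cat hamster", "cat dog hamster dog cat",
            "lion zebra lion zebra lion")
  cfg <- embedding_config(dimensions = 8, window = 2, min_count = 1,
                          epochs = 2, seed = 5)
  m <- train_embeddings(corp, cfg)
  expect_setequal(rownames(m$vectors),
                  c("dog", "cat", "hamster", "lion", "zebra"))
  expect_equal(ncol(m$vectors), 8)
  m2 <- train_embeddings(corp, cfg)
  expect_identical(m$vectors, m2$vectors)
  # min_count filters rare words
  m3 <- train_embeddings(corp, embedding_config(dimensions = 4, window = 2,
                                                min_count = 4, epochs = 1,
                                                seed = 1))
  expect_false("hamster" %in% rownames(m3$vectors))
  expect_error(train_embeddings(character(), cfg), "empty")
  expect_error(train_embeddings("   ", cfg), "empty")
})

test_that("trained embeddings separate two toy themes", {
  corp <- gen_toy_corpus(sentences_per_theme = 250, sentence_length = 6,
                         seed = 31)
  m <- train_embeddings(corp, embedding_config(
    dimensions = 20, window = 3, algorithm = "skipgram",
    min_count = 1, epochs = 3, seed = 31
  ))
  themes <- vf_toy_themes()
  within <- relatedness(m, "dog", setdiff(themes$pets, "dog"))$score
  cross <- relatedness(m, "dog", themes$africa)$score
  expect_gt(mean(within), mean(cross))
})

test_that("word2vec text format round-trips and flags malformed rows", {
  m <- hand_model()
  f <- withr::local_tempfile(fileext = ".vec")
  write_word2vec(m, f)
  back <- read_word2vec(f)
  expect_equal(back$vectors, m$vectors, tolerance = 1e-7)
  # gz round trip
  fz <- withr::local_tempfile(fileext = ".vec.gz")
  write_word2vec(m, fz)
  expect_equal(read_word2vec(fz)$vectors, m$vectors, tolerance = 1e-7)

  bad <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("2 3", "a 0.1 0.2 0.3", "b 0.1 0.2"), bad)
  expect_error(read_word2vec(bad), "Line 3")
  bad2 <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 2", "a 0.1 0.2"), bad2)
  expect_error(read_word2vec(bad2), "declares 3")
})
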
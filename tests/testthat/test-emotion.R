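lex <- emotion_lexicon()
mods <- modifier_lexicon()

test_that("the packaged lexicon covers the 16 categories with provenance", {
  expect_setequal(unique(lex$category), emotion_categories())
  expect_true(all(lex$provenance %in% c("seed", "expanded-accepted")))
  expect_true(all(table(lex$category) > 0))
  # terms can legitimately appear under several categories
  expect_true("leery" %in% lex$term[lex$category == "Interested"] &&
                "leery" %in% lex$term[lex$category == "Confused"])
})

test_that("emotion vectors follow the proportion rule with modifiers", {
  v <- compute_emotion_vector(tokenize("i am happy")$tokens, lex, mods)
  expect_equal(unname(v["Happy"]), 1 / 3)
  expect_equal(sum(v), 1 / 3)

  v2 <- compute_emotion_vector(c("very", "happy", "but", "not", "happy"),
                               lex, mods)
  expect_equal(unname(v2["Happy"]), 0.3)
})

test_that("order of lexicon rows does not change scores", {
  set.seed(2)
  shuffled <- lex[sample(nrow(lex)), ]
  tk <- tokenize("feeling very happy but kind of tired and not sad")$tokens
  expect_equal(compute_emotion_vector(tk, lex, mods),
               compute_emotion_vector(tk, shuffled, mods))
})

test_that("aggregate_emotions averages vectors and composites", {
  scores <- score_emotions(make_posts(c("i am happy today ok",  # Happy 0.2
                                        "happy happy here now also",
                                        "nothing at all")))
  agg <- aggregate_emotions(scores)
  expect_equal(agg$Happy, mean(scores$Happy))
  expect_equal(agg$positive, mean(rowMeans(scores[, c(
    "Happy", "Good", "Alive", "Love", "Positive", "Open", "Interested",
    "Strong")])))
  # empty group: no row, not zero
  empty <- aggregate_emotions(scores[0, ])
  expect_equal(nrow(empty), 1L)  # ungrouped mean over zero rows
  grouped <- aggregate_emotions(dplyr::mutate(scores[0, ], g = character()),
                                by = "g")
  expect_equal(nrow(grouped), 0L)
})

test_that("expand_lexicon matches the exhaustive oracle on a toy embedding", {
  set.seed(11)
  terms <- c("good", "fine", "well", "bad", "awful", "meh")
  m <- matrix(rnorm(12), nrow = 6, dimnames = list(terms, NULL))
  emb <- structure(list(terms = terms, vectors = m, dim = 2L, params = list()),
                   class = "osg_embedding")
  seed_lex <- tibble::tibble(category = "Good", term = "good",
                             provenance = "seed")
  rep2 <- expand_lexicon(seed_lex, emb, k = 2)
  oracle <- oracle_nearest(m, "good", 2)
  expect_equal(rep2$candidate, oracle$term)
  expect_equal(rep2$similarity, oracle$similarity, tolerance = 1e-12)
  expect_true(all(diff(rep2$similarity) <= 1e-12))
  expect_true(all(is.na(rep2$accepted)))
  # k >= |vocab| - 1 returns everything, sorted
  rep_all <- expand_lexicon(seed_lex, emb, k = 10)
  expect_setequal(rep_all$candidate, setdiff(terms, "good"))
  # out-of-vocabulary seeds are skipped with a warning
  expect_warning(
    rep_oov <- expand_lexicon(
      tibble::tibble(category = "Good", term = "unseen", provenance = "seed"),
      emb, k = 2),
    "skipped")
  expect_equal(nrow(rep_oov), 0L)
})

test_that("apply_review merges accepted candidates and demands coverage", {
  report <- tibble::tibble(category = c("Happy", "Sad"),
                           seed_term = c("happy", "sad"),
                           candidate = c("chuffed2", "joyful"),
                           similarity = c(0.9, 0.8), rank = c(1L, 1L),
                           accepted = NA)
  decisions <- tibble::tibble(category = c("Happy", "Sad"),
                              candidate = c("chuffed2", "joyful"),
                              accept = c(TRUE, FALSE))
  merged <- apply_review(report, decisions, lexicon = lex)
  expect_true("chuffed2" %in% merged$term[merged$category == "Happy"])
  expect_false("joyful" %in% merged$term[merged$category == "Sad"])
  expect_equal(
    merged$provenance[merged$term == "chuffed2"], "expanded-accepted")
  # missing decisions are fatal and name the gap
  expect_error(apply_review(report, decisions[1, ], lexicon = lex),
               class = "osgminer_review_incomplete")
  # empty report leaves the lexicon unchanged
  empty <- report[0, ]
  expect_equal(nrow(apply_review(empty, decisions[0, ], lexicon = lex)),
               nrow(lex))
})

test_that("word2vec text format round-trips", {
  set.seed(3)
  emb <- structure(list(terms = c("alpha", "beta_phrase"),
                        vectors = matrix(rnorm(6), nrow = 2,
                                         dimnames = list(c("alpha",
                                                           "beta_phrase"),
                                                         NULL)),
                        dim = 3L, params = list()),
                   class = "osg_embedding")
  f <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(emb, f)
  back <- read_word2vec(f)
  expect_equal(back$terms, emb$terms)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-12)
  expect_equal(back$dim, 3L)
})
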
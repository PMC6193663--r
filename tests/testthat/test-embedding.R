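test_that("training is reproducible and shapes are honoured", {
  sents <- simulate_embedding_corpus(800, seed = 5)
  e1 <- train_embedding(sents, dim = 12, epochs = 2, seed = 7)
  e2 <- train_embedding(sents, dim = 12, epochs = 2, seed = 7)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_embedding(sents, dim = 12, epochs = 2, seed = 8)
  expect_false(identical(e1$vectors, e3$vectors))

  tiny <- train_embedding(list(c("a", "b", "a", "b", "c", "a", "b")),
                          dim = 2, min_count = 1, seed = 1)
  expect_equal(ncol(tiny$vectors), 2L)
  expect_true(all(is.finite(tiny$vectors)))
})

test_that("empty corpora are rejected", {
  expect_error(train_embedding(list()), class = "osgminer_empty_corpus")
  expect_error(train_embedding(character()), class = "osgminer_empty_corpus")
})

test_that("planted synonym partners become nearest neighbours", {
  sents <- simulate_embedding_corpus(4000, seed = 2)
  emb <- train_embedding(sents, dim = 30, epochs = 3, seed = 2)
  expect_true("happy" %in% nearest_terms(emb, "glad", 5)$term)
  expect_true("awful" %in% nearest_terms(emb, "terrible", 5)$term)
})

test_that("frequent bigrams can be joined into phrase tokens", {
  sents <- c(rep(list(c("deeply", "saddened", "by", "it")), 30),
             rep(list(c("other", "words", "entirely")), 30))
  joined <- train_embedding(sents, dim = 4, min_count = 2,
                            phrase_threshold = 0.1, seed = 1)
  expect_true("deeply_saddened" %in% joined$terms)
})

test_that("nearest_terms errors on out-of-vocabulary queries", {
  emb <- train_embedding(list(c("x", "y", "x", "y")), dim = 2,
                         min_count = 1, seed = 1)
  expect_error(nearest_terms(emb, "zebra", 2), class = "osgminer_oov")
})
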
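test_that("read_posts ingests well-formed JSONL and rejects bad records", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  lines <- c(
    '{"post_id":"a1","patient_id":"p1","thread_id":"t1","forum":"f","timestamp":"2009-05-01T10:00:00Z","text":"hello"}',
    '{"post_id":"a2","patient_id":"p1","thread_id":"t1","forum":"f","timestamp":"2009-05-02T10:00:00Z","text":"curly \\u2018quotes\\u2019"}',
    '{"post_id":"a3","patient_id":"p2","thread_id":"t2","forum":"f","timestamp":"not-a-date","text":"bad"}',
    '{"post_id":"a4","patient_id":"p2","thread_id":"t2","forum":"f","timestamp":"2009-06-01T08:30:00Z","text":""}',
    '{"post_id":"a5","patient_id":"p2","thread_id":"t2","forum":"f","timestamp":"2009-06-02T08:30:00Z"}'
  )
  writeLines(lines, f)
  posts <- read_posts(f)
  expect_equal(nrow(posts), 3L)
  rej <- corpus_rejects(posts)
  expect_equal(rej$line, c(3L, 5L))
  expect_match(rej$reason[1], "timestamp")
  expect_match(rej$reason[2], "missing field")
  expect_error(read_posts(file.path(tempdir(), "does-not-exist.jsonl")),
               class = "osgminer_io")
})

test_that("empty file gives an empty corpus with a warning", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), f)
  expect_warning(posts <- read_posts(f), "empty")
  expect_equal(nrow(posts), 0L)
})

test_that("write_posts/read_posts round-trips field for field", {
  posts <- make_posts(c("plain text", "unicode ‘curly’ é",
                        ""), patient_id = c("p1", "p2", "p1"))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(posts, f)
  back <- read_posts(f)
  attr(back, "rejects") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(posts))
  expect_equal(nrow(corpus_rejects(read_posts(f))), 0L)
  # empty corpus round-trip
  empty <- posts[0, ]
  write_posts(empty, f)
  expect_warning(back2 <- read_posts(f), "empty")
  expect_equal(nrow(back2), 0L)
})

test_that("collocation groups and orders posts, conserving the corpus", {
  posts <- make_posts(rep("x", 5), patient_id = c("b", "a", "b", "a", "b"))
  posts$timestamp <- as.POSIXct("2009-01-01", tz = "UTC") +
    c(500, 400, 100, 300, 200)
  threads <- collocate_by_patient(posts[sample(5), ])
  expect_setequal(threads$post_id, posts$post_id)
  expect_equal(nrow(threads), nrow(posts))
  for (pid in c("a", "b")) {
    sub <- threads[threads$patient_id == pid, ]
    expect_true(all(diff(as.numeric(sub$timestamp)) >= 0))
    expect_equal(sub$post_seq, seq_len(nrow(sub)))
  }
})

test_that("equal timestamps are broken by lexicographic post_id", {
  posts <- make_posts(c("x", "y"), patient_id = "p")
  posts$timestamp <- rep(as.POSIXct("2009-01-01", tz = "UTC"), 2)
  posts$post_id <- c("zz", "aa")
  threads <- collocate_by_patient(posts)
  expect_equal(threads$post_id, c("aa", "zz"))
})

test_that("tokenize lower-cases, strips URLs and partitions sentences", {
  tk <- tokenize("I am Happy.")
  expect_equal(tk$tokens, c("i", "am", "happy"))
  expect_equal(tokenize("see http://x.y/z now")$tokens, c("see", "now"))
  empty <- tokenize("")
  expect_equal(empty$tokens, character())
  expect_equal(nrow(empty$sentences), 0L)

  multi <- tokenize("First one here. Second one! A third?")
  expect_equal(nrow(multi$sentences), 3L)
  expect_equal(multi$sentences$start[1], 1L)
  expect_equal(multi$sentences$end[nrow(multi$sentences)],
               length(multi$tokens))
  # ranges partition the token sequence
  expect_equal(multi$sentences$start[-1], multi$sentences$end[-3] + 1L)
})

test_that("tokenization is idempotent on already-normalized text", {
  texts <- c("i am happy", "the psa came back fine today",
             "we talked it over on sunday")
  for (tx in texts) {
    once <- tokenize(tx)$tokens
    again <- tokenize(paste(once, collapse = " "))$tokens
    expect_identical(once, again)
  }
})
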
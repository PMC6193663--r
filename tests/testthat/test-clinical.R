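test_that("extract_gleason handles the narrative dialects", {
  expect_equal(extract_gleason("Gleason 7")$total, 7L)
  g <- extract_gleason("GS3+3")
  expect_equal(g$primary, 3L)
  expect_equal(g$secondary, 3L)
  expect_equal(g$total, 6L)
  expect_equal(extract_gleason("gleason score of 7")$total, 7L)
  expect_equal(extract_gleason("GS 9")$total, 9L)
  expect_equal(extract_gleason("Gleason 3+4 this time")$total, 7L)
  expect_equal(nrow(extract_gleason("my glasses broke")), 0L)
  # invalid arithmetic is rejected
  expect_equal(nrow(extract_gleason("gleason 9+9")), 0L)
  expect_equal(nrow(extract_gleason("gleason 1")), 0L)
  expect_equal(nrow(extract_gleason("gleason 42")), 0L)
})

test_that("gleason component mentions satisfy the additivity invariant", {
  for (p in 1:5) for (s in 1:5) {
    g <- extract_gleason(sprintf("gs%d+%d", p, s))
    expect_equal(g$total, g$primary + g$secondary)
    expect_true(all(g$total >= 2 & g$total <= 10))
  }
})

test_that("extract_psa handles phrasings and keeps text order", {
  expect_equal(extract_psa("my psa was 4.5")$value, 4.5)
  expect_equal(extract_psa("PSA of 4.5")$value, 4.5)
  expect_equal(extract_psa("PSA=4.5")$value, 4.5)
  expect_equal(extract_psa("PSA level 4.5")$value, 4.5)
  expect_equal(extract_psa("PSA rose from 10.2 to 15.1")$value, c(10.2, 15.1))
  expect_equal(nrow(extract_psa("PSA test scheduled")), 0L)
  expect_warning(out <- extract_psa("psa was 123456"), "implausible")
  expect_equal(nrow(out), 0L)
})

test_that("extract_age applies self-reference and unit rules", {
  expect_equal(extract_age("I am 62 and just diagnosed"), 62L)
  expect_equal(extract_age("62 yo, new here"), 62L)
  expect_equal(extract_age("62 y/o and counting"), 62L)
  expect_equal(extract_age("I'm 71 years old"), 71L)
  expect_equal(extract_age("age 55 here"), 55L)
  expect_true(is.na(extract_age("my father is 85")))
  expect_true(is.na(extract_age("my father is 85 years old")))
  expect_true(is.na(extract_age("been waiting 62 days")))
  expect_true(is.na(extract_age("I am 62 days post op")))
  expect_true(is.na(extract_age("I am 110"))) # outside 18..100
  expect_true(is.na(extract_age("")))
  # first self-referential mention wins
  expect_equal(extract_age("I am 62. My friend is 70 years old."), 62L)
})

test_that("build_clinical_profile composes extractors with timestamps", {
  posts <- make_posts(c("the biopsy said Gleason 7.",
                        "psa was 4.5 at the last check."),
                      patient_id = "p1")
  prof <- build_clinical_profile(posts)
  expect_equal(prof$first_gleason_total, 7L)
  expect_equal(prof$max_psa, 4.5)
  expect_equal(prof$n_psa_mentions, 1L)

  mentions <- clinical_mentions(posts)
  expect_equal(mentions$kind, c("gleason", "psa"))
  expect_equal(mentions$timestamp, posts$timestamp)
})

test_that("clinical profile handles empty threads and age conflicts", {
  quiet <- make_posts(c("nothing medical here", "just chatting"))
  prof <- build_clinical_profile(quiet)
  expect_true(is.na(prof$age))
  expect_true(is.na(prof$first_gleason_total))
  expect_equal(prof$n_psa_mentions, 0L)

  conflicted <- make_posts(c("I am 62 now.", "I am 63 now."))
  expect_message(prof2 <- build_clinical_profile(conflicted), "conflict")
  expect_equal(prof2$age, 62L)
  expect_true(prof2$age_conflict)
})

test_that("age bands use upper-inclusive edges", {
  expect_equal(as.character(age_band(c(39, 40, 41, 50, 51, 60, 61, 70, 71))),
               c("<40", "<40", "41-50", "41-50", "51-60", "51-60",
                 "61-70", "61-70", ">70"))
})
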
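thesaurus <- side_effect_thesaurus()

test_that("side-effect extraction maps consumer terms to categories", {
  out <- extract_side_effects("still dealing with leakage at night")
  expect_equal(out$category, "urinary")
  expect_equal(out$term, "leakage")

  out2 <- extract_side_effects("developed a hernia and clots")
  expect_equal(out2$category, c("other", "other"))
  expect_equal(out2$term, c("hernia", "clots"))

  expect_equal(nrow(extract_side_effects("feeling fine today")), 0L)
})

test_that("longest multi-word terms win over their sub-terms", {
  out <- extract_side_effects("some rectal bleeding this week")
  expect_equal(out$category, "bowel")
  expect_equal(out$term, "rectal bleeding")
  # bare "bleeding" still maps to other
  out2 <- extract_side_effects("a bit of bleeding this week")
  expect_equal(out2$category, "other")
})

test_that("relative_month is exact month arithmetic and antisymmetric", {
  expect_equal(relative_month("2009-05", "2009-07"), 2L)
  expect_equal(relative_month("2009-05", "2009-02"), -3L)
  expect_equal(relative_month("2009-05", "2008-12"), -5L)
  expect_false(in_window(relative_month("2009-05", "2008-12")))
  expect_true(in_window(-3L) && in_window(12L))
  expect_false(in_window(13L))
  # antisymmetry over random month pairs
  set.seed(4)
  for (i in 1:50) {
    a <- sprintf("%04d-%02d", sample(1998:2020, 1), sample(12, 1))
    b <- sprintf("%04d-%02d", sample(1998:2020, 1), sample(12, 1))
    expect_equal(relative_month(a, b), -relative_month(b, a))
  }
})

test_that("timelines bucket posts and count dropped events", {
  # posts at t0, t1, t2 and t15 (out of window)
  months <- c("2009-05", "2009-06", "2009-07", "2010-08")
  posts <- make_posts(rep("dealing with leakage since the treatment.", 4))
  posts$timestamp <- as.POSIXct(paste0(months, "-15 12:00:00"), tz = "UTC")
  assess <- tibble::tibble(patient_id = "pA", t0_month = "2009-05")
  mentions <- extract_side_effects(posts)
  tl <- build_timelines(posts, assess, mentions)
  expect_equal(sum(tl$n_posts), 3L)
  expect_equal(tl$n_posts[tl$rel_month %in% 0:2], rep(1L, 3))
  dropped <- timeline_dropped(tl)
  expect_equal(dropped$dropped_posts, 1L)
  expect_equal(dropped$dropped_mentions, 1L)
  # conservation: in-window + dropped = totals
  expect_equal(sum(tl$n_posts) + dropped$dropped_posts, nrow(posts))
  expect_equal(sum(tl$urinary) + dropped$dropped_mentions, nrow(mentions))
  # window is complete per patient
  expect_equal(tl$rel_month, -3:12)
})

test_that("patients without t0 are refused", {
  posts <- make_posts("hello")
  assess <- tibble::tibble(patient_id = "pA", t0_month = NA_character_)
  expect_error(build_timelines(posts, assess), class = "osgminer_missing_t0")
})

test_that("pre-treatment-only patients fill only early buckets", {
  posts <- make_posts(c("a note", "another note"))
  posts$timestamp <- as.POSIXct(c("2009-02-10", "2009-03-10"), tz = "UTC")
  assess <- tibble::tibble(patient_id = "pA", t0_month = "2009-05")
  tl <- build_timelines(posts, assess)
  expect_equal(sum(tl$n_posts[tl$rel_month < 0]), 2L)
  expect_equal(sum(tl$n_posts[tl$rel_month >= 0]), 0L)
})

test_that("event conservation holds on generated cohorts", {
  sim <- generate_corpus(simulation_config(n_patients = 25, seed = 3,
                                           out_of_window_rate = 0.4))
  res <- suppressMessages(run_pipeline(sim$posts))
  tl <- res$timelines
  dropped <- timeline_dropped(tl)
  inc_ids <- res$included$patient_id
  total_posts <- sum(sim$posts$patient_id %in% inc_ids)
  expect_equal(sum(tl$n_posts) + sum(dropped$dropped_posts), total_posts)
})
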
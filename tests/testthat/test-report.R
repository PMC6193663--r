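test_that("post roles follow the reply/pattern/question rules", {
  posts <- make_posts(
    c("what should I do about my PSA?",                      # opener, question
      "you should ask your doctor about the margins",        # reply, advice
      "I had the same thing last spring."),                  # reply, sharing
    thread_id = "th1", step_days = 1)
  roles <- classify_post_role(posts)
  expect_equal(roles$role, c("seeking-or-sharing", "advice",
                             "seeking-or-sharing"))
  expect_equal(roles$is_reply, c(FALSE, TRUE, TRUE))

  # question-dominated replies are not advice even with the pattern
  qposts <- make_posts(c("opener text here.",
                         "should you worry? is it your psa? maybe."),
                       thread_id = "th2", step_days = 1)
  qroles <- classify_post_role(qposts)
  expect_equal(qroles$role[2], "seeking-or-sharing")

  # empty post
  eposts <- make_posts(c("opener.", ""), thread_id = "th3", step_days = 1)
  expect_equal(classify_post_role(eposts)$role[2], "seeking-or-sharing")
})

test_that("group trajectories compute the documented arithmetic", {
  # 2 patients in one group, month 1: posts 3 and 1, advice 1 of 4
  texts <- c(rep("plain filler text here.", 3), "you should try a diary.")
  posts <- make_posts(texts, patient_id = c("p1", "p1", "p1", "p2"),
                      thread_id = c("t1", "t1", "t1", "t1"), step_days = 0)
  posts$timestamp <- as.POSIXct("2009-06-10 08:00:00", tz = "UTC") + 1:4 * 60
  included <- tibble::tibble(patient_id = c("p1", "p2"), group = "Autonomous",
                             treatment = "Surgery", t0_month = "2009-05")
  sent <- NULL
  scores <- score_emotions(posts)
  roles <- classify_post_role(posts)
  mentions <- extract_side_effects(posts)
  timelines <- build_timelines(posts, included, mentions, scores)
  traj <- build_group_trajectories(posts, included, timelines, scores, roles,
                                   groupby = "group")
  m1 <- traj[traj$rel_month == 1, ]
  expect_equal(m1$n_active_patients, 2L)
  expect_equal(m1$mean_posts_per_patient, 2)
  expect_equal(m1$advice_post_pct, 25)
  # empty months report zero active patients and missing means
  m5 <- traj[traj$rel_month == 5, ]
  expect_equal(m5$n_active_patients, 0L)
  expect_true(is.na(m5$mean_posts_per_patient))
  expect_error(
    build_group_trajectories(posts, included, timelines, scores, roles,
                             groupby = "nope"),
    class = "osgminer_bad_grouping")
})

test_that("chi-squared matches the closed form and guards margins", {
  t1 <- chi_squared_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  t2 <- chi_squared_test(tab)
  expect_equal(t2$statistic, oracle_chisq_2x2(tab))
  expect_equal(t2$statistic, 20 / 3)
  expect_equal(t2$df, 1)

  t3 <- chi_squared_test(matrix(c(5, 6, 7, 8, 9, 10), nrow = 2))
  expect_equal(t3$df, 2)

  expect_error(chi_squared_test(matrix(c(1, 2), 1)),
               class = "osgminer_bad_table")
  expect_error(chi_squared_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "osgminer_zero_margin")
})

test_that("t-test handles identical and degenerate samples per contract", {
  t0 <- two_sample_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 4)

  tc <- two_sample_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tc$statistic, 0)
  expect_equal(tc$p_value, 1)

  expect_error(two_sample_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               class = "osgminer_degenerate_t")

  # pooled Student df versus Welch
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  expect_equal(two_sample_t_test(a, b)$df, 7)
  tw <- two_sample_t_test(a, b, var_equal = FALSE)
  expect_lt(tw$df, 7)
  expect_match(tw$method, "Welch")
})

test_that("tidy and glance methods return broom-style rows", {
  tt <- two_sample_t_test(c(1, 2, 3), c(4, 5, 7))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("method", "statistic", "df", "p.value"))
  expect_equal(glance(tt), td)
})

test_that("trajectory and emotion plots build", {
  sim <- generate_corpus(simulation_config(n_patients = 12, seed = 2))
  res <- suppressMessages(run_pipeline(sim$posts))
  p1 <- plot_trajectories(res$trajectories, "advice_post_pct")
  expect_s3_class(p1, "ggplot")
  agg <- aggregate_emotions(res$scores)
  agg$group <- "all"
  expect_s3_class(plot_emotion_profile(agg), "ggplot")
  expect_s3_class(ggplot2::autoplot(res$trajectories), "ggplot")
})

test_that("export_report writes consistent CSVs and metadata", {
  sim <- generate_corpus(simulation_config(n_patients = 10, seed = 6))
  res <- suppressMessages(run_pipeline(sim$posts))
  out <- withr::local_tempdir()
  files <- export_report(res, out, seed = 6)
  expect_true(all(file.exists(files)))
  coh <- readr::read_csv(file.path(out, "cohort_summary.csv"),
                         show_col_types = FALSE)
  expect_true(all(c("section", "group", "key", "n") %in% names(coh)))
  expect_equal(sum(coh$n[coh$section == "group_size"]),
               nrow(res$included))
  traj <- readr::read_csv(file.path(out, "trajectories.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(traj),
               16L * dplyr::n_distinct(res$trajectories$group))
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_equal(meta$seed, 6L)
})
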
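test_that("generation is deterministic given config and seed", {
  cfg <- simulation_config(n_patients = 10, seed = 42)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$posts, s2$posts)
  expect_identical(s1$truth$patients, s2$truth$patients)
  s3 <- generate_corpus(simulation_config(n_patients = 10, seed = 43))
  expect_false(identical(s1$posts$text, s3$posts$text))
})

test_that("invalid configurations fail naming the field", {
  expect_error(simulation_config(n_patients = 0),
               class = "osgminer_bad_config")
  expect_error(simulation_config(group_mix = c(Paternalistic = 0.5,
                                               Autonomous = 0.5,
                                               Shared = 0.2,
                                               Unclassified = -0.2)),
               class = "osgminer_bad_config")
  expect_error(simulation_config(advice_prob = rep(1.5, 16)),
               regexp = "advice_prob")
})

test_that("group mix is realized as exact largest-remainder counts", {
  sim <- generate_corpus(simulation_config(n_patients = 300, seed = 1))
  counts <- table(sim$truth$patients$group)
  expect_equal(unname(counts[c("Paternalistic", "Autonomous", "Shared",
                               "Unclassified")]),
               c(21L, 126L, 84L, 69L), ignore_attr = TRUE)
})

test_that("single-group configurations plant only that template", {
  cfg <- simulation_config(n_patients = 8, seed = 5,
                           group_mix = c(Paternalistic = 0, Autonomous = 1,
                                         Shared = 0, Unclassified = 0))
  sim <- generate_corpus(cfg)
  m <- match_decision_sentences(sim$posts)
  expect_setequal(unique(m$template_type), "Autonomous")
  expect_setequal(unique(m$patient_id), sim$truth$patients$patient_id)
})

test_that("every planted item has a verbatim witness", {
  sim <- generate_corpus(simulation_config(n_patients = 30, seed = 9))
  expect_true(verify_realization(sim))
})

test_that("decoy noise does not fool the negation-guarded matcher", {
  cfg <- simulation_config(n_patients = 15, seed = 8, noise_decoy_prob = 1)
  sim <- generate_corpus(cfg)
  res <- suppressMessages(run_pipeline(sim$posts))
  rec <- score_recovery(sim, res)
  expect_equal(rec$summary$value[rec$summary$metric == "group_accuracy"], 1)
})

test_that("score_recovery refuses mismatched patient universes", {
  sim <- generate_corpus(simulation_config(n_patients = 6, seed = 2))
  res <- suppressMessages(run_pipeline(sim$posts))
  sim2 <- sim
  sim2$truth$patients$patient_id <- paste0("zz", sim2$truth$patients$patient_id)
  expect_error(score_recovery(sim2, res),
               class = "osgminer_universe_mismatch")
})

test_that("perfect recovery on a small noiseless cohort", {
  sim <- generate_corpus(simulation_config(n_patients = 25, seed = 12))
  res <- suppressMessages(run_pipeline(sim$posts))
  rec <- tidy(score_recovery(sim, res))
  exact <- c("group_accuracy", "treatment_accuracy", "t0_exact_rate",
             "factor_exact_rate", "age_recall", "age_precision",
             "gleason_recall", "gleason_precision", "psa_recall",
             "psa_precision", "advice_accuracy")
  expect_true(all(rec$value[rec$metric %in% exact] == 1))
})

test_that("the embedding corpus plants pair-specific contexts", {
  sents <- simulate_embedding_corpus(500, seed = 3)
  expect_length(sents, 500L)
  expect_true(all(lengths(sents) == 5L))
  words <- unlist(sents)
  expect_true(all(c("glad", "happy") %in% words))
  # context words never cross pairs
  ctx1 <- grepl("^ctx01_", words)
  pair1 <- words %in% c("glad", "happy")
  sent_id <- rep(seq_along(sents), lengths(sents))
  with_ctx1 <- unique(sent_id[ctx1])
  expect_true(all(vapply(sents[with_ctx1],
                         function(s) any(s %in% c("glad", "happy")),
                         logical(1))))
})
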
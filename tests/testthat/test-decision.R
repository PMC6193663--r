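lex <- decision_lexicon()

test_that("decision templates match the canonical sentence forms", {
  posts <- make_posts(c("I decided to go for surgery",
                        "my urologist recommended brachytherapy",
                        "surgery went well last week"))
  m <- match_decision_sentences(posts, lex)
  expect_equal(nrow(m), 2L)
  a <- m[m$post_id == "x001", ]
  expect_equal(a$template_type, "Autonomous")
  expect_equal(a$treatment, "Surgery")
  p <- m[m$post_id == "x002", ]
  expect_equal(p$template_type, "Paternalistic")
  expect_equal(p$treatment, "Radiation")
})

test_that("a sentence can yield both template types", {
  posts <- make_posts("my doctor recommended surgery but we opted for radiation")
  m <- match_decision_sentences(posts, lex)
  expect_setequal(m$template_type, c("Autonomous", "Paternalistic"))
})

test_that("negated decide/recommend constructions do not match", {
  posts <- make_posts(c("I have not decided on surgery",
                        "my doctor never recommended radiation",
                        "we never settled on brachytherapy"))
  m <- match_decision_sentences(posts, lex)
  expect_equal(nrow(m), 0L)
})

test_that("multi-word terms match as contiguous runs, order is enforced", {
  posts <- make_posts(c("we took the option of watch and wait",
                        "surgery is what i eventually decided on",  # order violated
                        "i went for the da vinci robot"))
  m <- match_decision_sentences(posts, lex)
  expect_equal(m$post_id, c("x001", "x003"))
  expect_equal(m$treatment[m$post_id == "x001"], "Surveillance")
  expect_equal(m$treatment[m$post_id == "x003"], "Surgery")
})

test_that("classify_patient_group is a pure function of types present", {
  expect_equal(classify_patient_group("Autonomous"), "Autonomous")
  expect_equal(classify_patient_group("Paternalistic"), "Paternalistic")
  expect_equal(classify_patient_group(c("Autonomous", "Paternalistic")),
               "Shared")
  expect_equal(classify_patient_group(character()), "Unclassified")
  # order- and duplication-independence
  set.seed(1)
  for (i in 1:20) {
    types <- sample(c("Autonomous", "Paternalistic"),
                    sample(0:6, 1), replace = TRUE)
    expect_equal(classify_patient_group(types),
                 classify_patient_group(rev(sort(types))))
    expect_equal(classify_patient_group(types),
                 classify_patient_group(unique(types)))
  }
})

test_that("anchor_decision_time takes the earliest matched post's month", {
  posts <- make_posts(c("I decided on surgery", "I opted for surgery again"),
                      start = "2009-05-10 09:00:00", step_days = 95)
  m <- match_decision_sentences(posts, lex)
  expect_equal(nrow(m), 2L)
  expect_equal(anchor_decision_time(m)$t0_month, "2009-05")
})

test_that("factor mining respects the post window", {
  texts <- c("I decided on surgery.",
             "his experience with these cases mattered to us.",  # +1 post
             "nothing here.",
             "insurance covered most of the fees.")              # +3 posts
  posts <- make_posts(texts, patient_id = "p1")
  m <- match_decision_sentences(posts, lex)
  f1 <- mine_decision_factors(posts, m, window = 1L)
  expect_equal(f1$factor, "doctor experience")
  f3 <- mine_decision_factors(posts, m, window = 3L)
  expect_setequal(f3$factor, c("doctor experience", "financial concerns"))
  f0 <- mine_decision_factors(posts, m, window = 0L)
  expect_equal(nrow(f0), 0L)
})

test_that("assess_decisions flags treatment conflicts without reclassifying", {
  posts <- make_posts(c("I decided on surgery", "I went for radiation later"))
  expect_message(a <- assess_decisions(posts), "conflict")
  expect_equal(a$group, "Autonomous")
  expect_equal(a$treatment, "Surgery")  # earliest match wins
  expect_true(a$treatment_conflict)
})

test_that("adding posts never removes factors or collapses Shared", {
  base <- c("I decided on surgery.",
            "my doctor recommended surgery too.",
            "his experience with these cases mattered to us.")
  posts0 <- make_posts(base)
  a0 <- assess_decisions(posts0)
  extra <- make_posts(c(base, "the weather has been mild this week.",
                        "I opted for surgery in the end."))
  a1 <- assess_decisions(extra)
  expect_equal(a0$group, "Shared")
  expect_equal(a1$group, "Shared")
  expect_true(all(a0$factors[[1]] %in% a1$factors[[1]]))
})

test_that("inclusion filter counts classifiable patients", {
  texts <- c("I decided on surgery", "my doc advised radiation",
             "hello there", "nothing medical", "yet more chatter",
             "still nothing", "quiet one", "another quiet one",
             "chit chat", "last one")
  posts <- make_posts(texts, patient_id = sprintf("p%02d", 1:10))
  a <- assess_decisions(posts)
  inc <- apply_inclusion_criteria(a)
  s <- inclusion_summary(inc)
  expect_equal(s$n_total, 10L)
  expect_equal(s$n_included, 2L)
  expect_equal(s$pct_included, 20)
  # degenerate cases
  empty <- apply_inclusion_criteria(a[0, ])
  expect_equal(inclusion_summary(empty)$n_total, 0L)
  all_in <- apply_inclusion_criteria(a[a$group != "Unclassified", ])
  expect_equal(inclusion_summary(all_in)$pct_included, 100)
})
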
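#' Run the full patient-journey pipeline
#'
#' Executes every stage over a corpus: tokenization, decision-template
#' matching and assessment, inclusion filtering, clinical extraction,
#' side-effect mention extraction, per-post emotion scoring, post-role
#' classification, per-patient timelines, group trajectories and the
#' standard between-group tests.
#'
#' @param posts A corpus tibble (see [read_posts()]).
#' @param decision_lex A [decision_lexicon()].
#' @param factor_catalog A [decision_factor_catalog()].
#' @param thesaurus A [side_effect_thesaurus()].
#' @param emo_lexicon An [emotion_lexicon()].
#' @param modifiers A [modifier_lexicon()].
#' @param groupby Grouping for the trajectory table.
#' @param factor_window Post window for factor mining.
#' @return An `osg_pipeline` list: `assessments`, `included`, `clinical`,
#'   `mentions`, `scores`, `roles`, `timelines`, `trajectories`, `tests`,
#'   `factor_prevalence`, `meta`.
#' @export
run_pipeline <- function(posts,
                         decision_lex = decision_lexicon(),
                         factor_catalog = decision_factor_catalog(),
                         thesaurus = side_effect_thesaurus(),
                         emo_lexicon = emotion_lexicon(),
                         modifiers = modifier_lexicon(),
                         groupby = "group",
                         factor_window = 1L) {
  validate_corpus(posts)
  sent <- tokenize_posts(posts)

  assessments <- assess_decisions(posts, decision_lex, factor_catalog,
                                  factor_window = factor_window,
                                  tokens = sent)
  included <- apply_inclusion_criteria(assessments)
  clinical <- build_clinical_profile(posts)
  mentions <- extract_side_effects(posts, thesaurus, tokens = sent)
  scores <- score_emotions(posts, emo_lexicon, modifiers, tokens = sent)
  roles <- classify_post_role(posts, decision_lex, tokens = sent)
  timelines <- build_timelines(posts, included, mentions, scores)
  trajectories <- build_group_trajectories(posts, included, timelines,
                                           scores, roles, groupby = groupby,
                                           clinical = clinical)
  tests <- group_comparison_tests(included, clinical, scores, posts)

  factor_prevalence <- included |>
    dplyr::select("patient_id", "group", "factors") |>
    tidyr::unnest_longer("factors", values_to = "factor") |>
    dplyr::filter(!is.na(.data$factor)) |>
    dplyr::count(.data$group, .data$factor) |>
    dplyr::left_join(dplyr::count(included, .data$group, name = "n_patients"),
                     by = "group") |>
    dplyr::mutate(pct = 100 * .data$n / .data$n_patients)

  structure(list(assessments = assessments, included = included,
                 clinical = clinical, mentions = mentions, scores = scores,
                 roles = roles, timelines = timelines,
                 trajectories = trajectories, tests = tests,
                 factor_prevalence = factor_prevalence,
                 meta = list(n_posts = nrow(posts),
                             n_patients = dplyr::n_distinct(posts$patient_id),
                             groupby = groupby,
                             inclusion = inclusion_summary(included))),
            class = "osg_pipeline")
}

#' @export
print.osg_pipeline <- function(x, ...) {
  s <- x$meta$inclusion
  cat("<osg_pipeline> ", x$meta$n_posts, " posts, ", x$meta$n_patients,
      " patients; included ", s$n_included, "/", s$n_total, " (",
      format(s$pct_included, digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Glance at a pipeline run
#'
#' @param x An `osg_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble of run-level summaries.
#' @export
glance.osg_pipeline <- function(x, ...) {
  s <- x$meta$inclusion
  tibble(n_posts = x$meta$n_posts, n_patients = x$meta$n_patients,
         n_included = s$n_included, pct_included = s$pct_included,
         n_advice_posts = sum(x$roles$role == "advice"),
         n_side_effect_mentions = nrow(x$mentions))
}

#' Export a pipeline run as CSV report files
#'
#' Writes the aggregate report: `cohort_summary.csv` (group sizes, age-band,
#' Gleason and treatment composition), `trajectories.csv`, `factors.csv`,
#' `tests.csv`, `decisions.csv`, `timelines.csv`, and a `run_metadata.json`
#' sidecar (seed, config hash, package and R versions — no wall-clock
#' values, so identical runs export byte-identical files).
#'
#' @param result An `osg_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed to record in the metadata sidecar.
#' @return The written file paths, invisibly.
#' @export
export_report <- function(result, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  included <- result$included
  clinical <- result$clinical
  cohort <- dplyr::bind_rows(
    included |> dplyr::count(.data$group) |>
      dplyr::transmute(section = "group_size", group = .data$group,
                       key = "n_patients", n = .data$n),
    included |>
      dplyr::left_join(clinical[, c("patient_id", "age_band")],
                       by = "patient_id") |>
      dplyr::filter(!is.na(.data$age_band)) |>
      dplyr::count(.data$group, .data$age_band) |>
      dplyr::transmute(section = "age_band", group = .data$group,
                       key = as.character(.data$age_band), n = .data$n),
    included |>
      dplyr::left_join(clinical[, c("patient_id", "first_gleason_total")],
                       by = "patient_id") |>
      dplyr::filter(!is.na(.data$first_gleason_total)) |>
      dplyr::count(.data$group, .data$first_gleason_total) |>
      dplyr::transmute(section = "gleason_total", group = .data$group,
                       key = as.character(.data$first_gleason_total),
                       n = .data$n),
    included |> dplyr::count(.data$group, .data$treatment) |>
      dplyr::transmute(section = "treatment", group = .data$group,
                       key = .data$treatment, n = .data$n))

  decisions <- result$assessments |>
    dplyr::mutate(factors = vapply(.data$factors, paste, character(1),
                                   collapse = ";"))

  readr::write_csv(cohort, p("cohort_summary.csv"))
  readr::write_csv(result$trajectories, p("trajectories.csv"))
  readr::write_csv(result$factor_prevalence, p("factors.csv"))
  readr::write_csv(result$tests, p("tests.csv"))
  readr::write_csv(decisions, p("decisions.csv"))
  readr::write_csv(result$timelines, p("timelines.csv"))

  meta <- list(
    seed = seed,
    config_hash = rlang::hash(list(result$meta$groupby,
                                   result$meta$n_posts,
                                   result$meta$n_patients)),
    package_version = as.character(utils::packageVersion("osgminer")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(vapply(c("cohort_summary.csv", "trajectories.csv", "factors.csv",
                     "tests.csv", "decisions.csv", "timelines.csv",
                     "run_metadata.json"), p, character(1)))
}
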
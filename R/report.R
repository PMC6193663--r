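# Advice-post classification and group-level trajectory aggregation.

ADVICE_VERBS_EXTRA <- c("should", "try", "suggest", "suggested", "consider",
                        "ask")
SECOND_PERSON <- c("you", "your", "yours")
ADVICE_TOKEN_WINDOW <- 3L
QUESTION_FRACTION <- 0.5

#' Classify posts as advice vs seeking-or-sharing
#'
#' A post is an advice post when all three hold: it is a reply (not its
#' thread's first post by timestamp, ties broken by post_id); it contains a
#' second-person recommendation pattern (you/your within 3 tokens of a
#' recommend/should/try term); and it is not question-dominated (at most
#' half of its sentences end in "?"). Everything else is seeking-or-sharing.
#'
#' @param posts A corpus tibble.
#' @param lexicon A [decision_lexicon()] (its recommend terms seed the
#'   advice-verb set).
#' @param tokens Optionally, a precomputed sentence table (internal use).
#' @return A tibble `post_id`, `role` (`"advice"`/`"seeking-or-sharing"`),
#'   `is_reply`, `question_fraction`.
#' @export
classify_post_role <- function(posts, lexicon = decision_lexicon(),
                               tokens = NULL) {
  validate_corpus(posts)
  if (nrow(posts) == 0L) {
    return(tibble(post_id = character(), role = character(),
                  is_reply = logical(), question_fraction = numeric()))
  }
  first_posts <- posts |>
    dplyr::arrange(.data$thread_id, .data$timestamp, .data$post_id) |>
    dplyr::group_by(.data$thread_id) |>
    dplyr::slice(1L) |>
    dplyr::pull(.data$post_id)

  sent <- tokens %||% tokenize_posts(posts)
  qfrac <- sent |>
    dplyr::group_by(.data$post_id) |>
    dplyr::summarise(question_fraction = mean(.data$ends_q), .groups = "drop")

  verbs <- unique(c(lexicon$recommend[!grepl("\\s", lexicon$recommend)],
                    ADVICE_VERBS_EXTRA))
  toks <- post_token_table(sent)
  pattern <- toks |>
    dplyr::group_by(.data$post_id) |>
    dplyr::summarise(has_pattern = {
      yp <- .data$pos[.data$token %in% SECOND_PERSON]
      vp <- .data$pos[.data$token %in% verbs]
      length(yp) > 0L && length(vp) > 0L &&
        min(abs(outer(yp, vp, "-"))) <= ADVICE_TOKEN_WINDOW
    }, .groups = "drop")

  tibble(post_id = posts$post_id) |>
    dplyr::left_join(qfrac, by = "post_id") |>
    dplyr::left_join(pattern, by = "post_id") |>
    dplyr::mutate(
      question_fraction = dplyr::coalesce(.data$question_fraction, 0),
      has_pattern = dplyr::coalesce(.data$has_pattern, FALSE),
      is_reply = !.data$post_id %in% first_posts,
      role = ifelse(.data$is_reply & .data$has_pattern &
                      .data$question_fraction <= QUESTION_FRACTION,
                    "advice", "seeking-or-sharing")) |>
    dplyr::select("post_id", "role", "is_reply", "question_fraction")
}

TRAJECTORY_GROUPINGS <- c("group", "treatment", "age_band")

#' Build group-level monthly trajectories
#'
#' Aggregates included patients by decision group, treatment, or age band,
#' per relative month -3..12: number of active patients (>= 1 post that
#' month), mean posts per active patient, percentage of advice posts,
#' side-effect prevalence per category (percentage of the group's patients
#' with at least one mention that month), and mean positive/negative emotion
#' composites over the month's posts. Months with no posts report 0 active
#' patients and missing means.
#'
#' @param posts A corpus tibble.
#' @param included Included assessments ([apply_inclusion_criteria()]).
#' @param timelines Timelines from [build_timelines()].
#' @param scores Emotion scores from [score_emotions()].
#' @param roles Post roles from [classify_post_role()].
#' @param groupby One of `"group"`, `"treatment"`, `"age_band"`.
#' @param clinical Clinical profiles from [build_clinical_profile()]
#'   (required for `groupby = "age_band"`).
#' @param window Relative-month window.
#' @return A tibble with `grouping`, `group`, `rel_month`,
#'   `n_active_patients`, `mean_posts_per_patient`, `advice_post_pct`,
#'   `<category>_pct` for the four side-effect categories, and
#'   `positive_mean`/`negative_mean`; class `osg_trajectories`.
#' @export
build_group_trajectories <- function(posts, included, timelines, scores,
                                     roles, groupby = "group",
                                     clinical = NULL,
                                     window = TIMELINE_WINDOW) {
  if (!groupby %in% TRAJECTORY_GROUPINGS) {
    abort(paste0("unknown grouping key: ", groupby, " (expected one of ",
                 paste(TRAJECTORY_GROUPINGS, collapse = ", "), ")"),
          class = "osgminer_bad_grouping")
  }
  labels <- included[, c("patient_id", "group", "treatment")]
  if (groupby == "age_band") {
    if (is.null(clinical)) {
      abort("clinical profiles are required for age_band grouping",
            class = "osgminer_bad_grouping")
    }
    labels <- labels |>
      dplyr::left_join(clinical[, c("patient_id", "age_band")],
                       by = "patient_id")
    labels$.group <- as.character(labels$age_band)
  } else {
    labels$.group <- labels[[groupby]]
  }
  labels <- labels |> dplyr::filter(!is.na(.data$.group))
  group_sizes <- labels |> dplyr::count(.data$.group, name = "n_patients")

  anchors <- included[, c("patient_id", "t0_month")]
  rel_posts <- posts |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::mutate(rel_month = relative_month(.data$t0_month,
                                             post_month(.data$timestamp))) |>
    dplyr::filter(in_window(.data$rel_month, window)) |>
    dplyr::left_join(labels[, c("patient_id", ".group")], by = "patient_id") |>
    dplyr::filter(!is.na(.data$.group)) |>
    dplyr::left_join(roles[, c("post_id", "role")], by = "post_id") |>
    dplyr::left_join(scores[, c("post_id", "positive", "negative")],
                     by = "post_id")

  activity <- rel_posts |>
    dplyr::group_by(.data$.group, .data$rel_month) |>
    dplyr::summarise(
      n_active_patients = dplyr::n_distinct(.data$patient_id),
      mean_posts_per_patient = dplyr::n() / dplyr::n_distinct(.data$patient_id),
      advice_post_pct = 100 * mean(.data$role == "advice", na.rm = TRUE),
      positive_mean = mean(.data$positive, na.rm = TRUE),
      negative_mean = mean(.data$negative, na.rm = TRUE),
      .groups = "drop")

  prevalence <- timelines |>
    dplyr::left_join(labels[, c("patient_id", ".group")], by = "patient_id") |>
    dplyr::filter(!is.na(.data$.group)) |>
    dplyr::group_by(.data$.group, .data$rel_month) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(SIDE_EFFECT_CATEGORIES),
                                   ~ sum(.x > 0L)),
                     .groups = "drop") |>
    dplyr::left_join(group_sizes, by = ".group") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(SIDE_EFFECT_CATEGORIES),
                                ~ 100 * .x / .data$n_patients,
                                .names = "{.col}_pct")) |>
    dplyr::select(".group", "rel_month",
                  dplyr::all_of(paste0(SIDE_EFFECT_CATEGORIES, "_pct")))

  grid <- tidyr::expand_grid(.group = sort(unique(labels$.group)),
                             rel_month = seq(window[1], window[2]))
  out <- grid |>
    dplyr::left_join(activity, by = c(".group", "rel_month")) |>
    dplyr::left_join(prevalence, by = c(".group", "rel_month")) |>
    dplyr::mutate(
      n_active_patients = dplyr::coalesce(.data$n_active_patients, 0L),
      dplyr::across(dplyr::ends_with("_pct"), ~ dplyr::coalesce(.x, 0))) |>
    dplyr::rename(group = ".group") |>
    dplyr::mutate(grouping = groupby, .before = 1)
  class(out) <- c("osg_trajectories", class(out))
  attr(out, "group_sizes") <- group_sizes
  out
}

#' Group comparison tests
#'
#' The standard between-group comparisons: chi-squared tests of group
#' against treatment mix and age-band mix (categorical), and pairwise
#' two-sided t-tests of patient-level mean positive/negative emotion
#' composites between decision groups. Raw p-values are reported by default,
#' with optional Benjamini-Hochberg adjustment.
#'
#' @param included Included assessments.
#' @param clinical Clinical profiles.
#' @param scores Emotion scores joined per post.
#' @param posts A corpus tibble (to map posts to patients).
#' @param adjust Apply Benjamini-Hochberg correction to the t-test p-values.
#' @return A tibble with `comparison`, `method`, `statistic`, `df`,
#'   `p.value`.
#' @export
group_comparison_tests <- function(included, clinical, scores, posts,
                                   adjust = FALSE) {
  rows <- list()
  safe_chisq <- function(tab, label) {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(NULL)
    t <- chi_squared_test(tab)
    dplyr::mutate(tidy(t), comparison = label, .before = 1)
  }
  rows$treat <- safe_chisq(table(included$group, included$treatment),
                           "decision group x treatment")
  joined <- included |>
    dplyr::left_join(clinical[, c("patient_id", "age_band")], by = "patient_id")
  if (any(!is.na(joined$age_band))) {
    rows$age <- safe_chisq(table(joined$group, joined$age_band),
                           "decision group x age band")
  }

  patient_means <- scores |>
    dplyr::left_join(posts[, c("post_id", "patient_id")], by = "post_id") |>
    dplyr::inner_join(included[, c("patient_id", "group")], by = "patient_id") |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(positive = mean(.data$positive),
                     negative = mean(.data$negative), .groups = "drop")
  groups <- sort(unique(patient_means$group))
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      for (comp in c("positive", "negative")) {
        a <- patient_means[[comp]][patient_means$group == pr[1]]
        b <- patient_means[[comp]][patient_means$group == pr[2]]
        if (length(a) < 2L || length(b) < 2L) next
        t <- tryCatch(two_sample_t_test(a, b),
                      osgminer_degenerate_t = function(e) NULL)
        if (is.null(t)) next
        rows[[paste(pr[1], pr[2], comp)]] <- dplyr::mutate(
          tidy(t),
          comparison = paste0(comp, " emotion: ", pr[1], " vs ", pr[2]),
          .before = 1)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(comparison = character(), method = character(),
                  statistic = numeric(), df = numeric(), p.value = numeric()))
  }
  if (adjust) {
    is_t <- grepl("t-test", out$method)
    out$p.value[is_t] <- stats::p.adjust(out$p.value[is_t], method = "BH")
  }
  out
}
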
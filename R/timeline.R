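TIMELINE_WINDOW <- c(-3L, 12L)

#' Extract side-effect mentions
#'
#' Matches side-effect thesaurus terms over each post's token stream with
#' greedy longest-first multi-word matching (so "rectal bleeding" wins over
#' "bleeding" when both could apply), case-insensitively. Each matched token
#' span contributes one mention; a token consumed by a longer match cannot
#' be matched again.
#'
#' @param posts A corpus tibble, or a character vector of texts (then
#'   `post_id` is the element index as character).
#' @param thesaurus A [side_effect_thesaurus()].
#' @param tokens Optionally, a precomputed sentence table (internal use).
#' @return A tibble `post_id`, `patient_id`, `timestamp` (when available),
#'   `category`, `term`, in text order within each post.
#' @export
extract_side_effects <- function(posts, thesaurus = side_effect_thesaurus(),
                                 tokens = NULL) {
  if (is.character(posts)) {
    posts <- tibble(post_id = as.character(seq_along(posts)),
                    patient_id = NA_character_, thread_id = NA_character_,
                    forum = NA_character_,
                    timestamp = as.POSIXct("2000-01-01", tz = "UTC"),
                    text = posts)
  }
  validate_corpus(posts)
  sent <- tokens %||% tokenize_posts(posts)
  labels <- rep(names(thesaurus), lengths(thesaurus))
  terms <- unlist(thesaurus, use.names = FALSE)
  term_tokens <- split_terms(terms)

  toks <- post_token_table(sent)
  if (nrow(toks) == 0L) {
    return(tibble(post_id = character(), patient_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  category = character(), term = character()))
  }
  hits <- lapply(split(toks$token, toks$post_id), function(tk) {
    runs <- find_term_runs(tk, term_tokens, paste(labels, terms, sep = "\t"))
    greedy_longest_first(runs)
  })
  out <- tibble(post_id = rep(names(hits), vapply(hits, nrow, integer(1))),
                label = unlist(lapply(hits, function(h) h$label),
                               use.names = FALSE) %||% character())
  if (nrow(out) == 0L) {
    return(tibble(post_id = character(), patient_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  category = character(), term = character()))
  }
  out |>
    tidyr::separate_wider_delim("label", "\t", names = c("category", "term")) |>
    dplyr::left_join(posts[, c("post_id", "patient_id", "timestamp")],
                     by = "post_id") |>
    dplyr::select("post_id", "patient_id", "timestamp", "category", "term") |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$post_id)
}

# Resolve overlapping term runs: longer matches first, then leftmost;
# accepted spans consume their tokens.
greedy_longest_first <- function(runs) {
  if (nrow(runs) == 0L) return(runs)
  runs <- runs[order(-(runs$end - runs$start), runs$start), , drop = FALSE]
  taken <- integer(0)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    span <- runs$start[i]:runs$end[i]
    if (!any(span %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, span)
    }
  }
  out <- runs[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Treatment-relative month difference
#'
#' Whole-month difference between an event month and the anchor month t0,
#' so the anchor itself is month 0. Values outside the analysis window
#' (-3..12 by default) are still returned; use [in_window()] to flag them.
#'
#' @param t0,event Calendar month labels, `"YYYY-MM"`.
#' @return Integer month difference `event - t0` (antisymmetric).
#' @examples
#' relative_month("2009-05", "2009-07")
#' @export
relative_month <- function(t0, event) {
  month_to_idx(event) - month_to_idx(t0)
}

#' @rdname relative_month
#' @param m Integer relative month(s).
#' @param window Inclusive window bounds.
#' @export
in_window <- function(m, window = TIMELINE_WINDOW) {
  !is.na(m) & m >= window[1] & m <= window[2]
}

#' Build per-patient event timelines
#'
#' Normalizes each included patient's posts, side-effect mentions and
#' per-post emotion vectors to months relative to the decision anchor t0
#' and buckets them monthly from t-3 to t+12. Posts outside the window are
#' counted as dropped, never silently discarded.
#'
#' @param posts A corpus tibble.
#' @param assessments Included assessments (rows of [assess_decisions()]
#'   with a non-missing `t0_month`; typically
#'   [apply_inclusion_criteria()] output).
#' @param mentions Side-effect mentions from [extract_side_effects()].
#' @param scores Optional per-post emotion scores from [score_emotions()].
#' @param window Inclusive relative-month window (default -3..12).
#' @return A tibble with one row per patient and relative month (the window
#'   is complete for every patient): `patient_id`, `rel_month`, `n_posts`,
#'   one mention-count column per side-effect category, and, when `scores`
#'   is given, `emotion_post_count` plus summed emotion columns
#'   (`em_<category>`) and `positive_sum`/`negative_sum` composites. The
#'   `"dropped"` attribute is a per-patient tibble of `dropped_posts` and
#'   `dropped_mentions` outside the window.
#' @export
build_timelines <- function(posts, assessments, mentions = NULL,
                            scores = NULL, window = TIMELINE_WINDOW) {
  validate_corpus(posts)
  if (any(is.na(assessments$t0_month))) {
    abort(paste0(
      "missing t0_month for patient(s): ",
      paste(assessments$patient_id[is.na(assessments$t0_month)], collapse = ", "),
      "; patients must pass the inclusion filter before timelines are built"),
      class = "osgminer_missing_t0")
  }
  anchors <- assessments[, c("patient_id", "t0_month")]
  rel_posts <- posts |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::mutate(rel_month = relative_month(.data$t0_month,
                                             post_month(.data$timestamp)))

  grid <- tidyr::expand_grid(patient_id = anchors$patient_id,
                             rel_month = seq(window[1], window[2]))
  n_posts <- rel_posts |>
    dplyr::filter(in_window(.data$rel_month, window)) |>
    dplyr::count(.data$patient_id, .data$rel_month, name = "n_posts")
  out <- grid |>
    dplyr::left_join(n_posts, by = c("patient_id", "rel_month")) |>
    dplyr::mutate(n_posts = dplyr::coalesce(.data$n_posts, 0L))

  dropped_posts <- rel_posts |>
    dplyr::filter(!in_window(.data$rel_month, window)) |>
    dplyr::count(.data$patient_id, name = "dropped_posts")
  dropped_mentions <- tibble(patient_id = character(), dropped_mentions = integer())

  if (!is.null(mentions) && nrow(mentions) > 0L) {
    rel_m <- mentions |>
      dplyr::inner_join(anchors, by = "patient_id") |>
      dplyr::mutate(rel_month = relative_month(.data$t0_month,
                                               post_month(.data$timestamp)))
    counts <- rel_m |>
      dplyr::filter(in_window(.data$rel_month, window)) |>
      dplyr::count(.data$patient_id, .data$rel_month, .data$category) |>
      tidyr::pivot_wider(names_from = "category", values_from = "n",
                         values_fill = 0L)
    dropped_mentions <- rel_m |>
      dplyr::filter(!in_window(.data$rel_month, window)) |>
      dplyr::count(.data$patient_id, name = "dropped_mentions")
    out <- out |> dplyr::left_join(counts, by = c("patient_id", "rel_month"))
  }
  for (cat in SIDE_EFFECT_CATEGORIES) {
    if (!cat %in% names(out)) out[[cat]] <- 0L
    out[[cat]] <- dplyr::coalesce(out[[cat]], 0L)
  }

  if (!is.null(scores)) {
    em_cols <- emotion_categories()
    rel_s <- scores |>
      dplyr::left_join(posts[, c("post_id", "patient_id", "timestamp")],
                       by = "post_id") |>
      dplyr::inner_join(anchors, by = "patient_id") |>
      dplyr::mutate(rel_month = relative_month(.data$t0_month,
                                               post_month(.data$timestamp))) |>
      dplyr::filter(in_window(.data$rel_month, window))
    sums <- rel_s |>
      dplyr::group_by(.data$patient_id, .data$rel_month) |>
      dplyr::summarise(emotion_post_count = dplyr::n(),
                       dplyr::across(dplyr::all_of(em_cols), sum,
                                     .names = "em_{.col}"),
                       .groups = "drop")
    out <- out |>
      dplyr::left_join(sums, by = c("patient_id", "rel_month")) |>
      dplyr::mutate(emotion_post_count =
                      dplyr::coalesce(.data$emotion_post_count, 0L),
                    dplyr::across(dplyr::starts_with("em_"),
                                  ~ dplyr::coalesce(.x, 0))) |>
      dplyr::mutate(
        positive_sum = rowSums(dplyr::pick(dplyr::all_of(
          paste0("em_", POSITIVE_EMOTIONS)))),
        negative_sum = rowSums(dplyr::pick(dplyr::all_of(
          paste0("em_", NEGATIVE_EMOTIONS)))))
  }

  out <- out |> dplyr::arrange(.data$patient_id, .data$rel_month)
  drop_tab <- tibble(patient_id = anchors$patient_id) |>
    dplyr::left_join(dropped_posts, by = "patient_id") |>
    dplyr::left_join(dropped_mentions, by = "patient_id") |>
    dplyr::mutate(dropped_posts = dplyr::coalesce(.data$dropped_posts, 0L),
                  dropped_mentions = dplyr::coalesce(.data$dropped_mentions, 0L))
  attr(out, "dropped") <- drop_tab
  out
}

#' @rdname build_timelines
#' @param timelines A timeline tibble.
#' @export
timeline_dropped <- function(timelines) {
  attr(timelines, "dropped") %||%
    tibble(patient_id = character(), dropped_posts = integer(),
           dropped_mentions = integer())
}
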
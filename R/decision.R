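# Sentence-level template matching for treatment decisions. A sentence
# matches the Autonomous template when it contains, in order, a first-person
# subject (i/we), a decide term and a treatment term, with any number of
# tokens in between; the Paternalistic template is clinician-role term, then
# recommend term, then treatment term. Multi-word terms match as contiguous
# token runs. A decide/recommend term with a negator in the three tokens
# before it does not fire ("i have not decided on surgery").

NEGATION_WINDOW <- 3L
FIRST_PERSON <- c("i", "we")

split_terms <- function(terms) {
  lapply(stringr::str_split(tolower(terms), "\\s+"), function(x) x[nzchar(x)])
}

# All start positions where any of the (token-split) terms occurs as a
# contiguous run in `tokens`. Returns a data frame of start/end/term.
find_term_runs <- function(tokens, term_tokens, term_labels = NULL) {
  n <- length(tokens)
  out <- list()
  for (k in seq_along(term_tokens)) {
    tt <- term_tokens[[k]]
    len <- length(tt)
    if (len == 0L || len > n) next
    starts <- which(tokens == tt[1])
    if (len > 1L) {
      starts <- starts[starts + len - 1L <= n]
      starts <- starts[vapply(starts, function(s) {
        all(tokens[s:(s + len - 1L)] == tt)
      }, logical(1))]
    }
    if (length(starts) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts, end = starts + len - 1L,
        label = if (is.null(term_labels)) NA_character_ else term_labels[[k]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), label = character()))
  }
  do.call(rbind, out)
}

is_negated <- function(tokens, start, negators, window = NEGATION_WINDOW) {
  lo <- max(1L, start - window)
  if (lo > start - 1L) return(FALSE)
  any(tokens[lo:(start - 1L)] %in% negators)
}

# Matches one template (subject runs -> verb runs -> treatment runs) inside
# one sentence; returns the lexicographically first valid triple or NULL.
match_template_one <- function(tokens, subj_runs, verb_runs, treat_runs,
                               negators) {
  if (nrow(subj_runs) == 0L || nrow(verb_runs) == 0L || nrow(treat_runs) == 0L) {
    return(NULL)
  }
  verb_runs <- verb_runs[order(verb_runs$start), , drop = FALSE]
  treat_runs <- treat_runs[order(treat_runs$start), , drop = FALSE]
  subj_starts <- sort(subj_runs$start)
  for (v in seq_len(nrow(verb_runs))) {
    vs <- verb_runs$start[v]
    ve <- verb_runs$end[v]
    if (is_negated(tokens, vs, negators)) next
    subj <- subj_starts[subj_starts < vs]
    if (length(subj) == 0L) next
    tr <- treat_runs[treat_runs$start > ve, , drop = FALSE]
    if (nrow(tr) == 0L) next
    return(list(subj_start = subj[1], verb_start = vs, verb_end = ve,
                treat_start = tr$start[1], treat_end = tr$end[1],
                treatment = tr$label[1]))
  }
  NULL
}

#' Match decision-template sentences across a corpus
#'
#' Scans every sentence of every post for the Autonomous template
#' (first-person subject, then a decide term, then a treatment term) and the
#' Paternalistic template (clinician-role term, then a recommend term, then
#' a treatment term). A sentence can yield both match types. Decide and
#' recommend terms preceded by a negator within three tokens do not match.
#'
#' @param posts A corpus tibble.
#' @param lexicon A [decision_lexicon()].
#' @param tokens Optionally, a precomputed sentence table (internal use).
#' @return A tibble with one row per (sentence, template type) match:
#'   `post_id`, `patient_id`, `timestamp`, `sent_idx`, `template_type`
#'   (`"Autonomous"`/`"Paternalistic"`), `treatment` (category), and the
#'   matched token spans (`subj_start`, `verb_start`, `verb_end`,
#'   `treat_start`, `treat_end`).
#' @export
match_decision_sentences <- function(posts, lexicon = decision_lexicon(),
                                     tokens = NULL) {
  validate_corpus(posts)
  validate_decision_lexicon(lexicon)
  sent <- tokens %||% tokenize_posts(posts)
  sent <- sent[lengths(sent$tokens) > 0L, , drop = FALSE]
  empty <- tibble(post_id = character(), patient_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  sent_idx = integer(), template_type = character(),
                  treatment = character(), subj_start = integer(),
                  verb_start = integer(), verb_end = integer(),
                  treat_start = integer(), treat_end = integer())
  if (nrow(sent) == 0L) return(empty)

  treat_terms <- unlist(lapply(names(lexicon$treatment), function(cat) {
    setNames(lexicon$treatment[[cat]], rep(cat, length(lexicon$treatment[[cat]])))
  }))
  treat_tokens <- split_terms(unname(treat_terms))
  treat_labels <- names(treat_terms)
  decide_tokens <- split_terms(lexicon$decide)
  recommend_tokens <- split_terms(lexicon$recommend)
  doctor_tokens <- split_terms(lexicon$doctor)
  negators <- modifier_lexicon()$negators

  # Cheap regex prefilter on space-joined sentence strings; only candidate
  # sentences go through positional matching.
  joined <- vapply(sent$tokens, paste, character(1), collapse = " ")
  alt <- function(terms) {
    paste0("\\b(?:", paste(stringr::str_replace_all(terms, "\\s+", " "),
                           collapse = "|"), ")\\b")
  }
  has_treat <- stringr::str_detect(joined, alt(unname(treat_terms)))
  has_dec <- stringr::str_detect(joined, alt(lexicon$decide))
  has_rec <- stringr::str_detect(joined, alt(lexicon$recommend))
  has_doc <- stringr::str_detect(joined, alt(lexicon$doctor))
  has_fp <- stringr::str_detect(joined, "\\b(?:i|we)\\b")
  cand_auto <- which(has_treat & has_dec & has_fp)
  cand_pat <- which(has_treat & has_rec & has_doc)

  make_rows <- function(idx, type, verb_tokens, subj_tokens, subj_labels) {
    rows <- lapply(idx, function(i) {
      tk <- sent$tokens[[i]]
      subj <- find_term_runs(tk, subj_tokens, subj_labels)
      verbs <- find_term_runs(tk, verb_tokens)
      treats <- find_term_runs(tk, treat_tokens, treat_labels)
      m <- match_template_one(tk, subj, verbs, treats, negators)
      if (is.null(m)) return(NULL)
      tibble(row = i, template_type = type, treatment = m$treatment,
             subj_start = m$subj_start, verb_start = m$verb_start,
             verb_end = m$verb_end, treat_start = m$treat_start,
             treat_end = m$treat_end)
    })
    dplyr::bind_rows(rows)
  }
  auto <- make_rows(cand_auto, "Autonomous", decide_tokens,
                    split_terms(FIRST_PERSON), FIRST_PERSON)
  pat <- make_rows(cand_pat, "Paternalistic", recommend_tokens,
                   doctor_tokens, lexicon$doctor)
  hits <- dplyr::bind_rows(auto, pat)
  if (nrow(hits) == 0L) return(empty)

  meta <- posts[, c("post_id", "patient_id", "timestamp")]
  hits |>
    dplyr::mutate(post_id = sent$post_id[.data$row],
                  sent_idx = sent$sent_idx[.data$row]) |>
    dplyr::left_join(meta, by = "post_id") |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$post_id,
                   .data$sent_idx, .data$template_type) |>
    dplyr::select("post_id", "patient_id", "timestamp", "sent_idx",
                  "template_type", "treatment", "subj_start", "verb_start",
                  "verb_end", "treat_start", "treat_end")
}

DECISION_GROUPS <- c("Paternalistic", "Autonomous", "Shared", "Unclassified")

#' Classify a patient's decision-making behaviour group
#'
#' A pure function of the set of template types present in the patient's
#' history: only Autonomous matches give the Autonomous group (decisions
#' driven by personal preference), only Paternalistic matches the
#' Paternalistic group (adhering to clinician recommendation), both types
#' anywhere in the history give Shared, and no matches give Unclassified.
#'
#' @param template_types Character vector of template types (any order, with
#'   or without duplicates), or a match tibble from
#'   [match_decision_sentences()].
#' @return One of `"Paternalistic"`, `"Autonomous"`, `"Shared"`,
#'   `"Unclassified"`.
#' @export
classify_patient_group <- function(template_types) {
  if (is.data.frame(template_types)) {
    template_types <- template_types$template_type
  }
  types <- unique(template_types)
  bad <- setdiff(types, c("Autonomous", "Paternalistic"))
  if (length(bad) > 0L) {
    abort(paste0("unknown template type: ", paste(bad, collapse = ", ")))
  }
  has_a <- "Autonomous" %in% types
  has_p <- "Paternalistic" %in% types
  if (has_a && has_p) "Shared"
  else if (has_a) "Autonomous"
  else if (has_p) "Paternalistic"
  else "Unclassified"
}

#' Anchor each patient's decision month
#'
#' The decision anchor t0 is the calendar month of the earliest post that
#' contains a decision-template match (a deterministic anchor rule).
#'
#' @param matches A match tibble from [match_decision_sentences()].
#' @return A tibble `patient_id`, `t0_month` (`"YYYY-MM"`).
#' @export
anchor_decision_time <- function(matches) {
  if (nrow(matches) == 0L) {
    return(tibble(patient_id = character(), t0_month = character()))
  }
  matches |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(t0_month = post_month(min(.data$timestamp)),
                     .groups = "drop")
}

#' Mine decision factors around decision posts
#'
#' A factor is attributed to a patient when any of its catalog terms occurs
#' (as a contiguous token run) in a post containing a decision match or
#' within `window` posts of one in the patient's chronological stream.
#'
#' @param posts A corpus tibble.
#' @param matches A match tibble from [match_decision_sentences()].
#' @param catalog A [decision_factor_catalog()].
#' @param window Non-negative integer number of posts either side of a
#'   decision post to search (default 1).
#' @param tokens Optionally, a precomputed sentence table (internal use).
#' @return A tibble `patient_id`, `factor`, one row per attributed factor.
#' @export
mine_decision_factors <- function(posts, matches,
                                  catalog = decision_factor_catalog(),
                                  window = 1L, tokens = NULL) {
  stopifnot(window >= 0L)
  empty <- tibble(patient_id = character(), factor = character())
  if (nrow(matches) == 0L) return(empty)
  threads <- collocate_by_patient(posts)
  decision_posts <- unique(matches$post_id)
  threads <- threads |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      dec <- df$post_seq[df$post_id %in% decision_posts]
      if (length(dec) == 0L) return(df[0, , drop = FALSE])
      near <- vapply(df$post_seq, function(s) any(abs(s - dec) <= window),
                     logical(1))
      df[near, , drop = FALSE]
    }) |>
    dplyr::ungroup()
  if (nrow(threads) == 0L) return(empty)

  sent <- tokens %||% tokenize_posts(posts)
  sent <- sent[sent$post_id %in% threads$post_id, , drop = FALSE]
  if (nrow(sent) == 0L) return(empty)
  toks <- post_token_table(sent)

  labels <- rep(names(catalog), lengths(catalog))
  term_tokens <- split_terms(unlist(catalog, use.names = FALSE))

  hits <- lapply(split(toks$token, toks$post_id), function(tk) {
    runs <- find_term_runs(tk, term_tokens, labels)
    unique(runs$label)
  })
  found <- tibble(post_id = rep(names(hits), lengths(hits)),
                  factor = unlist(hits, use.names = FALSE) %||% character())
  if (nrow(found) == 0L) return(empty)
  found |>
    dplyr::left_join(threads[, c("post_id", "patient_id")], by = "post_id") |>
    dplyr::distinct(.data$patient_id, .data$factor) |>
    dplyr::arrange(.data$patient_id, .data$factor)
}

#' Assess decision behaviour for every patient in a corpus
#'
#' Combines template matching, group classification, treatment resolution
#' (the treatment category of the earliest match; later conflicting
#' categories flag the patient instead of reclassifying), decision-month
#' anchoring and factor mining into one per-patient table.
#'
#' @inheritParams mine_decision_factors
#' @param lexicon A [decision_lexicon()].
#' @param factor_window Post window for factor mining.
#' @return A tibble with one row per patient: `patient_id`, `group`,
#'   `treatment`, `treatment_conflict`, `t0_month`, `factors` (list column
#'   of factor labels) and `n_matches`.
#' @export
assess_decisions <- function(posts, lexicon = decision_lexicon(),
                             catalog = decision_factor_catalog(),
                             factor_window = 1L, tokens = NULL) {
  validate_corpus(posts)
  sent <- tokens %||% tokenize_posts(posts)
  matches <- match_decision_sentences(posts, lexicon, tokens = sent)
  base <- tibble(patient_id = sort(unique(posts$patient_id)))

  per_patient <- matches |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$post_id,
                   .data$sent_idx, .data$verb_start) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      group = classify_patient_group(.data$template_type),
      treatment_conflict = dplyr::n_distinct(.data$treatment) > 1L,
      n_matches = dplyr::n(),
      treatment = dplyr::first(.data$treatment),
      .groups = "drop")
  if (any(per_patient$treatment_conflict)) {
    inform(paste0("conflicting treatment categories for patient(s): ",
                  paste(per_patient$patient_id[per_patient$treatment_conflict],
                        collapse = ", "),
                  " (earliest match used)"))
  }
  anchors <- anchor_decision_time(matches)
  factors <- mine_decision_factors(posts, matches, catalog,
                                   window = factor_window, tokens = sent)
  factor_col <- factors |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(factors = list(.data$factor), .groups = "drop")

  base |>
    dplyr::left_join(per_patient, by = "patient_id") |>
    dplyr::left_join(anchors, by = "patient_id") |>
    dplyr::left_join(factor_col, by = "patient_id") |>
    dplyr::mutate(
      group = dplyr::coalesce(.data$group, "Unclassified"),
      treatment_conflict = dplyr::coalesce(.data$treatment_conflict, FALSE),
      n_matches = dplyr::coalesce(.data$n_matches, 0L),
      factors = lapply(.data$factors, function(f) f %||% character())
    )
}

#' Apply the study inclusion filter
#'
#' A patient is included when their decision behaviour could be classified
#' (at least one template match) and the chosen treatment is resolvable.
#'
#' @param assessments A tibble from [assess_decisions()].
#' @return The included rows, with a `"summary"` attribute holding
#'   `n_total`, `n_included` and `pct_included` (see [inclusion_summary()]).
#' @export
apply_inclusion_criteria <- function(assessments) {
  included <- assessments |>
    dplyr::filter(.data$group != "Unclassified", !is.na(.data$treatment))
  n_total <- nrow(assessments)
  attr(included, "summary") <- tibble(
    n_total = n_total,
    n_included = nrow(included),
    pct_included = if (n_total == 0L) NA_real_ else 100 * nrow(included) / n_total
  )
  included
}

#' @rdname apply_inclusion_criteria
#' @param included The result of [apply_inclusion_criteria()].
#' @export
inclusion_summary <- function(included) {
  attr(included, "summary") %||%
    tibble(n_total = NA_integer_, n_included = nrow(included),
           pct_included = NA_real_)
}
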
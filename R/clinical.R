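# Deterministic pattern rules for self-disclosed clinical details. Each
# extractor works on raw (un-tokenized) text because the numerals and
# "3+4"-style arithmetic do not survive word tokenization.

GLEASON_PREFIX <- "\\b(?:gleason|gs)\\s*(?:score|grade)?\\s*(?:of|is|was|=|:)?\\s*"

#' Extract Gleason score mentions from free text
#'
#' Recognizes the common narrative dialects for Gleason grading:
#' `"Gleason 7"`, `"GS 7"`, `"GS3+3"`, `"Gleason 3+4"`,
#' `"gleason score of 7"`, case-insensitively with optional
#' "score"/"grade"/"of" fillers. Component mentions must have primary and
#' secondary pattern grades in 1..5 and totals must fall in 2..10; mentions
#' with invalid arithmetic are rejected.
#'
#' @param text A single character string.
#' @return A tibble with columns `primary`, `secondary` (NA for total-only
#'   mentions) and `total`, in text order; zero rows when nothing matches.
#' @examples
#' extract_gleason("biopsy came back GS3+3")
#' @export
extract_gleason <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- tibble(primary = integer(), secondary = integer(), total = integer())
  if (is.na(text) || !nzchar(text)) return(empty)

  sum_re <- paste0("(?i)", GLEASON_PREFIX, "([0-9])\\s*\\+\\s*([0-9])")
  tot_re <- paste0("(?i)", GLEASON_PREFIX, "([0-9]{1,2})\\b(?!\\s*\\+)")

  sums <- stringr::str_match_all(text, sum_re)[[1]]
  sum_pos <- stringr::str_locate_all(text, sum_re)[[1]][, 1]
  tots <- stringr::str_match_all(text, tot_re)[[1]]
  tot_pos <- stringr::str_locate_all(text, tot_re)[[1]][, 1]

  rows <- list()
  if (nrow(sums) > 0L) {
    p <- as.integer(sums[, 2]); s <- as.integer(sums[, 3])
    ok <- p >= 1L & p <= 5L & s >= 1L & s <= 5L & (p + s) >= 2L & (p + s) <= 10L
    rows[[1]] <- tibble(primary = p[ok], secondary = s[ok],
                        total = p[ok] + s[ok], .pos = sum_pos[ok])
  }
  if (nrow(tots) > 0L) {
    t <- as.integer(tots[, 2])
    ok <- t >= 2L & t <= 10L
    rows[[2]] <- tibble(primary = NA_integer_, secondary = NA_integer_,
                        total = t[ok], .pos = tot_pos[ok])
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out |> dplyr::arrange(.data$.pos) |> dplyr::select(-".pos")
}

PSA_GAP_WORD <- paste0(
  "(?:levels?|readings?|scores?|values?|results?|tests?|was|is|were|of|at|",
  "now|came|back|rose|dropped|fell|went|from|up|down|to|currently|about|",
  "around|my|a|the|=|:)")

PSA_CAP <- 10000

#' Extract PSA value mentions from free text
#'
#' Recognizes consumer phrasings such as `"PSA 4.5"`, `"psa was 4.5"`,
#' `"PSA of 4.5"`, `"PSA=4.5"`, `"PSA level 4.5"` and ranged statements like
#' `"PSA rose from 10.2 to 15.1"` (both values, in text order). Values above
#' 10,000 ng/mL are treated as unit errors and rejected (reported in the
#' `"rejected"` attribute, not silently dropped).
#'
#' @param text A single character string.
#' @return A tibble with column `value` (ng/mL), in text order.
#' @export
extract_psa <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- tibble(value = numeric())
  if (is.na(text) || !nzchar(text)) return(empty)
  re <- paste0("(?i)\\bpsa\\b\\s*(?:", PSA_GAP_WORD, "\\s*){0,5}",
               "([0-9]+(?:\\.[0-9]+)?)",
               "((?:\\s*(?:to|and|then|,)\\s*[0-9]+(?:\\.[0-9]+)?)*)")
  m <- stringr::str_match_all(text, re)[[1]]
  if (nrow(m) == 0L) return(empty)
  values <- unlist(lapply(seq_len(nrow(m)), function(i) {
    extra <- stringr::str_extract_all(m[i, 3], "[0-9]+(?:\\.[0-9]+)?")[[1]]
    as.numeric(c(m[i, 2], extra))
  }))
  out <- tibble(value = values)
  bad <- out$value > PSA_CAP
  if (any(bad)) {
    warn(paste0("rejected implausible PSA value(s) > ", PSA_CAP, " ng/mL: ",
                paste(out$value[bad], collapse = ", ")))
  }
  res <- out[!bad, , drop = FALSE]
  attr(res, "rejected") <- out$value[bad]
  res
}

AGE_UNIT_RE <- "(?i)\\b([0-9]{1,3})\\s*(?:yo|y/o|yrs?\\.?\\s*old|years?\\s*old)\\b"
AGE_SELF_RE <- paste0("(?i)\\bi\\s*(?:am|'m|’m)\\s+(?:a\\s+)?([0-9]{1,3})\\b",
                      "(?!\\s*(?:days?|weeks?|months?|%|percent|pounds?|lbs?|kg))")
AGE_LABEL_RE <- "(?i)\\bage\\s*(?:is|of|:)?\\s*([0-9]{1,3})\\b"
THIRD_PERSON_RE <- paste0(
  "(?i)\\b(?:he|she|his|her|father|mother|dad|mom|mum|brother|sister|son|",
  "daughter|husband|wife|uncle|aunt|grandfather|neighbour|neighbor|friend)\\b")

#' Extract a self-disclosed age from free text
#'
#' Recognizes `"I am 62"`, `"62 yo"`, `"62 y/o"`, `"62 years old"`,
#' `"age 62"`. Mentions whose local context refers to a third person ("my
#' father is 85") are discarded, as are values outside 18..100 and numbers
#' attached to non-age units ("62 days"). The first self-referential match
#' in text order wins.
#'
#' @param text A single character string.
#' @return An integer age, or `NA_integer_` when no self-disclosed age is
#'   found.
#' @export
extract_age <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(NA_integer_)
  cand <- list()
  for (spec in list(list(re = AGE_UNIT_RE, guard = TRUE),
                    list(re = AGE_SELF_RE, guard = FALSE),
                    list(re = AGE_LABEL_RE, guard = TRUE))) {
    pos <- stringr::str_locate_all(text, spec$re)[[1]]
    if (nrow(pos) == 0L) next
    vals <- stringr::str_match_all(text, spec$re)[[1]][, 2]
    for (i in seq_len(nrow(pos))) {
      start <- unname(pos[i, 1])
      if (spec$guard && third_person_context(text, start)) next
      cand[[length(cand) + 1L]] <- c(start = start, value = as.integer(vals[i]))
    }
  }
  if (length(cand) == 0L) return(NA_integer_)
  df <- do.call(rbind, cand)
  df <- df[order(df[, "start"]), , drop = FALSE]
  ok <- df[, "value"] >= 18L & df[, "value"] <= 100L
  if (!any(ok)) return(NA_integer_)
  as.integer(df[ok, "value"][1])
}

# Looks back from a match to the previous sentence boundary (at most 60
# characters) for a third-person referent.
third_person_context <- function(text, start) {
  from <- max(1L, start - 60L)
  ctx <- substr(text, from, max(from, start - 1L))
  ctx <- sub(".*[.!?]", "", ctx)
  grepl(THIRD_PERSON_RE, ctx, perl = TRUE)
}

AGE_BAND_LEVELS <- c("<40", "41-50", "51-60", "61-70", ">70")

#' Assign an age to the reporting age bands
#'
#' Band edges are inclusive on the upper end (41-50 means 41 <= age <= 50;
#' ages up to 40 fall in the `<40` band).
#'
#' @param age Integer vector of ages.
#' @return A factor with levels `<40`, `41-50`, `51-60`, `61-70`, `>70`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 40, 50, 60, 70, Inf), labels = AGE_BAND_LEVELS)
}

#' Extract clinical mentions from every post of a corpus
#'
#' Runs the Gleason, PSA and age extractors over each post and attaches the
#' post identity and timestamp, ordered within patient by time.
#'
#' @param posts A corpus tibble.
#' @return A tibble with columns `patient_id`, `post_id`, `timestamp`,
#'   `kind` (gleason/psa/age), `value` (total Gleason, PSA value, or age)
#'   and, for Gleason component mentions, `primary` and `secondary`.
#' @export
clinical_mentions <- function(posts) {
  validate_corpus(posts)
  pre <- grepl("(?i)\\b(?:gleason|gs)\\b", posts$text, perl = TRUE) |
    grepl("(?i)\\bpsa\\b", posts$text, perl = TRUE) |
    grepl("[0-9]", posts$text)
  rows <- lapply(which(pre), function(i) {
    g <- extract_gleason(posts$text[i])
    p <- extract_psa(posts$text[i])
    a <- extract_age(posts$text[i])
    out <- list()
    if (nrow(g) > 0L) {
      out$g <- tibble(kind = "gleason", value = as.numeric(g$total),
                      primary = g$primary, secondary = g$secondary)
    }
    if (nrow(p) > 0L) {
      out$p <- tibble(kind = "psa", value = p$value,
                      primary = NA_integer_, secondary = NA_integer_)
    }
    if (!is.na(a)) {
      out$a <- tibble(kind = "age", value = as.numeric(a),
                      primary = NA_integer_, secondary = NA_integer_)
    }
    if (length(out) == 0L) return(NULL)
    dplyr::bind_rows(out) |>
      dplyr::mutate(post_id = posts$post_id[i],
                    patient_id = posts$patient_id[i],
                    timestamp = posts$timestamp[i])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(patient_id = character(), post_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  kind = character(), value = numeric(),
                  primary = integer(), secondary = integer()))
  }
  out |>
    dplyr::select("patient_id", "post_id", "timestamp", "kind", "value",
                  "primary", "secondary") |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$post_id)
}

#' Per-patient clinical profile table
#'
#' Summarizes the clinical mentions of each patient: first self-disclosed
#' age (conflicting later disclosures are flagged, not used), derived age
#' band, first Gleason total (all mentions are retained in
#' [clinical_mentions()]; the first is used for grouping), and PSA summary.
#'
#' @param posts A corpus tibble.
#' @param mentions Optionally, a precomputed result of [clinical_mentions()].
#' @return A tibble with one row per patient present in `posts`: `patient_id`,
#'   `age`, `age_band`, `age_conflict`, `first_gleason_total`,
#'   `first_gleason_primary`, `first_gleason_secondary`, `max_psa`,
#'   `n_psa_mentions`, `n_gleason_mentions`.
#' @export
build_clinical_profile <- function(posts, mentions = NULL) {
  validate_corpus(posts)
  mentions <- mentions %||% clinical_mentions(posts)
  base <- tibble(patient_id = sort(unique(posts$patient_id)))

  ages <- mentions |>
    dplyr::filter(.data$kind == "age") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(age = as.integer(dplyr::first(.data$value)),
                     age_conflict = dplyr::n_distinct(.data$value) > 1L,
                     .groups = "drop")
  if (any(ages$age_conflict)) {
    inform(paste0("conflicting age disclosures for patient(s): ",
                  paste(ages$patient_id[ages$age_conflict], collapse = ", "),
                  " (first mention used)"))
  }
  gleason <- mentions |>
    dplyr::filter(.data$kind == "gleason") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_gleason_total = as.integer(dplyr::first(.data$value)),
                     first_gleason_primary = dplyr::first(.data$primary),
                     first_gleason_secondary = dplyr::first(.data$secondary),
                     n_gleason_mentions = dplyr::n(), .groups = "drop")
  psa <- mentions |>
    dplyr::filter(.data$kind == "psa") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(max_psa = if (dplyr::n() > 0) max(.data$value) else NA_real_,
                     n_psa_mentions = dplyr::n(),
                     .groups = "drop")

  base |>
    dplyr::left_join(ages, by = "patient_id") |>
    dplyr::left_join(gleason, by = "patient_id") |>
    dplyr::left_join(psa, by = "patient_id") |>
    dplyr::mutate(
      age_conflict = dplyr::coalesce(.data$age_conflict, FALSE),
      age_band = age_band(.data$age),
      n_gleason_mentions = dplyr::coalesce(.data$n_gleason_mentions, 0L),
      n_psa_mentions = dplyr::coalesce(.data$n_psa_mentions, 0L)
    ) |>
    dplyr::select("patient_id", "age", "age_band", "age_conflict",
                  "first_gleason_total", "first_gleason_primary",
                  "first_gleason_secondary", "max_psa", "n_psa_mentions",
                  "n_gleason_mentions")
}
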
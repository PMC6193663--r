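TREATMENT_CATEGORIES <- c("Surgery", "Radiation", "Surveillance")

#' Decision template lexicon
#'
#' Term sets used by the sentence-level decision templates: first-person
#' decide terms, clinician recommend terms, clinician role terms, and
#' treatment terms grouped into the three treatment categories (Surgery,
#' Radiation, Surveillance). The packaged default covers the standard
#' consumer phrasings ("decided", "opted", "went for", "recommended",
#' "urologist", "brachytherapy", ...). Custom lexicons are TSV files with
#' columns `role` and `term`, where `role` is one of `decide`, `recommend`,
#' `doctor`, or `treatment:<Category>`.
#'
#' @param path Optional path to a TSV file; the packaged lexicon is used
#'   when `NULL`.
#' @return A list with character vectors `decide`, `recommend`, `doctor` and
#'   a named list `treatment` keyed by category.
#' @export
decision_lexicon <- function(path = NULL) {
  df <- read_role_tsv(path %||% extdata_path("decision_terms.tsv"))
  lex <- list(
    decide = df$term[df$role == "decide"],
    recommend = df$term[df$role == "recommend"],
    doctor = df$term[df$role == "doctor"],
    treatment = lapply(setNames(TREATMENT_CATEGORIES, TREATMENT_CATEGORIES),
                       function(cat) df$term[df$role == paste0("treatment:", cat)])
  )
  validate_decision_lexicon(lex)
}

validate_decision_lexicon <- function(lex) {
  for (role in c("decide", "recommend", "doctor")) {
    if (length(lex[[role]]) == 0L) {
      abort(paste0("decision lexicon has no '", role, "' terms"),
            class = "osgminer_bad_lexicon")
    }
  }
  if (any(lengths(lex$treatment) == 0L)) {
    abort("decision lexicon has an empty treatment category",
          class = "osgminer_bad_lexicon")
  }
  overlap <- intersect(lex$decide, lex$recommend)
  if (length(overlap) > 0L) {
    abort(paste0("term(s) in both decide and recommend sets: ",
                 paste(overlap, collapse = ", ")),
          class = "osgminer_bad_lexicon")
  }
  lex
}

#' Decision factor catalog
#'
#' Maps decision-factor labels (doctor experience, side effects, best cancer
#' control, age, fast recovery, financial concerns, bowel symptoms,
#' radiation oncologist) to the consumer-health terms that signal them.
#'
#' @param path Optional TSV with columns `factor` and `term`.
#' @return A named list of character vectors, one per factor label.
#' @export
decision_factor_catalog <- function(path = NULL) {
  df <- read_role_tsv(path %||% extdata_path("decision_factors.tsv"),
                      key = "factor")
  split(df$term, factor(df$factor, levels = unique(df$factor)))
}

SIDE_EFFECT_CATEGORIES <- c("urinary", "sexual", "bowel", "other")

#' Side-effect thesaurus
#'
#' Consumer-language side-effect terms grouped into the four treatment
#' side-effect categories: urinary, sexual, bowel and other. Everyday
#' phrasings (leakage, drip, pads, ...) are used deliberately: patients
#' rarely use the clinical-ontology terms.
#'
#' @param path Optional TSV with columns `category` and `term`.
#' @return A named list of character vectors keyed by the four categories.
#' @export
side_effect_thesaurus <- function(path = NULL) {
  df <- read_role_tsv(path %||% extdata_path("side_effects.tsv"),
                      key = "category")
  bad <- setdiff(unique(df$category), SIDE_EFFECT_CATEGORIES)
  if (length(bad) > 0L) {
    abort(paste0("unknown side-effect category: ", paste(bad, collapse = ", ")),
          class = "osgminer_bad_lexicon")
  }
  if (anyDuplicated(df$term)) {
    abort("each side-effect term must map to exactly one category",
          class = "osgminer_bad_lexicon")
  }
  lapply(setNames(SIDE_EFFECT_CATEGORIES, SIDE_EFFECT_CATEGORIES),
         function(cat) df$term[df$category == cat])
}

POSITIVE_EMOTIONS <- c("Happy", "Good", "Alive", "Love",
                       "Positive", "Open", "Interested", "Strong")
NEGATIVE_EMOTIONS <- c("Sad", "Afraid", "Hurt", "Angry",
                       "Depressed", "Helpless", "Confused", "Indifferent")

#' The 16 emotion categories
#'
#' Eight positive (Happy, Good, Alive, Love, Positive, Open, Interested,
#' Strong) and eight negative (Sad, Afraid, Hurt, Angry, Depressed,
#' Helpless, Confused, Indifferent) emotion-wheel derived categories, in the
#' fixed order used by every 16-dimensional emotion vector in the package.
#'
#' @return A character vector of length 16.
#' @export
emotion_categories <- function() c(POSITIVE_EMOTIONS, NEGATIVE_EMOTIONS)

#' Emotion lexicon
#'
#' Terms (words and multi-word phrases) mapped to the 16 emotion categories,
#' each carrying a provenance flag: `seed` for the curated feeling-word
#' seeds, `expanded-accepted` for terms added after embedding-based
#' expansion and review. A term may appear under several categories and then
#' contributes to each.
#'
#' @param path Optional TSV with columns `category`, `term`, `provenance`.
#' @return A tibble with columns `category`, `term`, `provenance`.
#' @seealso [expand_lexicon()], [apply_review()], [compute_emotion_vector()]
#' @export
emotion_lexicon <- function(path = NULL) {
  df <- readr::read_tsv(path %||% extdata_path("emotion_seeds.tsv"),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  validate_emotion_lexicon(as_tibble(df))
}

validate_emotion_lexicon <- function(lexicon) {
  needed <- c("category", "term", "provenance")
  if (!all(needed %in% names(lexicon))) {
    abort("emotion lexicon needs columns category, term, provenance",
          class = "osgminer_bad_lexicon")
  }
  bad <- setdiff(unique(lexicon$category), emotion_categories())
  if (length(bad) > 0L) {
    abort(paste0("unknown emotion category: ", paste(bad, collapse = ", ")),
          class = "osgminer_bad_lexicon")
  }
  missing <- setdiff(emotion_categories(), unique(lexicon$category))
  if (length(missing) > 0L) {
    abort(paste0("emotion categories with no terms: ",
                 paste(missing, collapse = ", ")),
          class = "osgminer_bad_lexicon")
  }
  dplyr::distinct(lexicon, .data$category, .data$term, .keep_all = TRUE)
}

#' Intensity-modifier lexicon
#'
#' Booster, dampener and negator terms in the style of rule-based sentiment
#' intensity tools, with the multipliers applied per modifier found in the
#' window preceding an emotion term: each booster multiplies the match
#' weight by `booster_multiplier` (default 1.5), each dampener by
#' `dampener_multiplier` (default 0.5), and any negator zeroes it.
#'
#' @param path Optional TSV with columns `role` (booster/dampener/negator)
#'   and `term`.
#' @param booster_multiplier Multiplier per booster, > 1.
#' @param dampener_multiplier Multiplier per dampener, in (0, 1).
#' @return A list with `boosters`, `dampeners`, `negators` and the two
#'   multipliers.
#' @export
modifier_lexicon <- function(path = NULL, booster_multiplier = 1.5,
                             dampener_multiplier = 0.5) {
  stopifnot(booster_multiplier > 1, dampener_multiplier > 0,
            dampener_multiplier < 1)
  df <- read_role_tsv(path %||% extdata_path("modifiers.tsv"))
  lex <- list(
    boosters = df$term[df$role == "booster"],
    dampeners = df$term[df$role == "dampener"],
    negators = df$term[df$role == "negator"],
    booster_multiplier = booster_multiplier,
    dampener_multiplier = dampener_multiplier
  )
  all_terms <- c(lex$boosters, lex$dampeners, lex$negators)
  if (anyDuplicated(all_terms)) {
    abort("booster/dampener/negator sets must be pairwise disjoint",
          class = "osgminer_bad_lexicon")
  }
  lex
}
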
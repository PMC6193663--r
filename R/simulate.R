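# Seeded synthetic OSG corpus generator with planted ground truth. The
# generator's job is to emulate the structure of a prostate-cancer support
# forum at desk scale: per-patient post streams laid out over calendar
# months around a treatment decision, with planted decision-template
# sentences, clinical disclosures, side-effect schedules, emotion-term
# densities and advice-styled replies. Generation is noiseless by default
# (every planted item is realized verbatim in a supported dialect), so
# extraction is expected to recover the ground truth exactly; an optional
# decoy layer adds negated decision sentences for robustness checks.

SIM_MONTHS <- -3:12

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_corpus()]. The defaults
#' define the study conditions: 300 patients with decision-group mix
#' 7% Paternalistic / 42% Autonomous / 28% Shared / 23% Unclassified (the
#' Paternalistic group markedly smaller, the other two classifiable groups
#' comparable), posting activity peaking in the decision month, urinary
#' side-effect hazards declining after treatment while sexual ones persist,
#' negative emotion-term density declining and positive rising over
#' recovery, and advice behaviour increasing over the year after treatment.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the corpus is fully deterministic given it.
#' @param group_mix Named probabilities over the four decision groups,
#'   summing to 1. Realized as exact largest-remainder counts.
#' @param treatment_mix Named probabilities over Surgery, Radiation,
#'   Surveillance.
#' @param posting_rate Groups x months matrix of expected posts per patient
#'   per relative month (-3..12); every patient is guaranteed at least one
#'   post in month 0.
#' @param side_effect_hazard Categories x months matrix: probability that an
#'   included patient mentions the category that month. Realized as exact
#'   rounded counts assigned to randomly chosen included patients.
#' @param emotion_density 16 x months matrix of expected planted emotion
#'   terms per post, per category.
#' @param advice_prob Per-month probability that a reply is advice-styled.
#' @param disclosure_probs Named probabilities of age/gleason/psa
#'   self-disclosure in the patient's first post.
#' @param factor_weights Sampling weights over decision-factor labels.
#' @param factor_count_range Min/max planted factors per included patient.
#' @param thread_size Posts per discussion thread.
#' @param out_of_window_rate Expected posts per patient per month in months
#'   13-14 (outside the analysis window; 0 disables).
#' @param noise_decoy_prob Per-patient probability of planting a negated
#'   decision decoy sentence ("i have not decided on surgery").
#' @return A validated list of class `osg_sim_config`.
#' @export
simulation_config <- function(n_patients = 300L,
                              seed = 42L,
                              group_mix = c(Paternalistic = 0.07,
                                            Autonomous = 0.42,
                                            Shared = 0.28,
                                            Unclassified = 0.23),
                              treatment_mix = c(Surgery = 0.55,
                                                Radiation = 0.30,
                                                Surveillance = 0.15),
                              posting_rate = default_posting_rate(),
                              side_effect_hazard = default_side_effect_hazard(),
                              emotion_density = default_emotion_density(),
                              advice_prob = round(seq(0.05, 0.48,
                                                      length.out = 16L), 3),
                              disclosure_probs = c(age = 0.9, gleason = 0.85,
                                                   psa = 0.85),
                              factor_weights = c(`doctor experience` = 0.40,
                                                 `side effects` = 0.15,
                                                 `best cancer control` = 0.12,
                                                 age = 0.08,
                                                 `fast recovery` = 0.08,
                                                 `financial concerns` = 0.07,
                                                 `bowel symptoms` = 0.04,
                                                 `radiation oncologist` = 0.06),
                              factor_count_range = c(1L, 3L),
                              thread_size = 6L,
                              out_of_window_rate = 0,
                              noise_decoy_prob = 0) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              group_mix = group_mix, treatment_mix = treatment_mix,
              posting_rate = posting_rate,
              side_effect_hazard = side_effect_hazard,
              emotion_density = emotion_density, advice_prob = advice_prob,
              disclosure_probs = disclosure_probs,
              factor_weights = factor_weights,
              factor_count_range = as.integer(factor_count_range),
              thread_size = as.integer(thread_size),
              out_of_window_rate = out_of_window_rate,
              noise_decoy_prob = noise_decoy_prob)
  validate_sim_config(cfg)
}

default_posting_rate <- function() {
  m <- rbind(
    Paternalistic = c(0.7, 0.8, 1.0, 2.0, 1.2, 0.8, 0.6, 0.6, 0.6, 0.6,
                      0.6, 0.8, 1.0, 1.2, 1.2, 1.0),
    Autonomous = c(1.2, 1.5, 2.0, 3.0, 2.0, 1.5, 1.2, 1.0, 0.9, 0.8,
                   0.8, 0.7, 0.7, 0.6, 0.6, 0.6),
    Shared = c(1.2, 1.4, 1.6, 2.5, 1.8, 1.6, 1.6, 1.5, 1.5, 1.5,
               1.5, 1.5, 1.5, 1.5, 1.5, 1.5),
    Unclassified = c(0.8, 0.8, 1.0, 1.2, 1.0, 0.8, 0.7, 0.6, 0.6, 0.5,
                     0.5, 0.5, 0.5, 0.4, 0.4, 0.4))
  colnames(m) <- as.character(SIM_MONTHS)
  m
}

default_side_effect_hazard <- function() {
  m <- rbind(
    urinary = c(0.02, 0.02, 0.02, 0.05, 0.35, 0.30, 0.26, 0.22, 0.19, 0.16,
                0.14, 0.12, 0.11, 0.10, 0.10, 0.10),
    sexual = c(0.02, 0.02, 0.02, 0.05, 0.25, 0.25, 0.24, 0.24, 0.23, 0.23,
               0.22, 0.22, 0.22, 0.21, 0.21, 0.21),
    bowel = c(0.01, 0.01, 0.01, 0.02, 0.08, 0.08, 0.07, 0.07, 0.06, 0.06,
              0.06, 0.05, 0.05, 0.05, 0.05, 0.05),
    other = c(0.01, 0.01, 0.01, 0.03, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
              0.05, 0.05, 0.05, 0.08, 0.05, 0.04))
  colnames(m) <- as.character(SIM_MONTHS)
  m
}

default_emotion_density <- function() {
  pos_total <- round(seq(0.4, 1.8, length.out = 16L), 3)
  neg_total <- round(seq(1.8, 0.4, length.out = 16L), 3)
  m <- rbind(matrix(rep(pos_total / 8, each = 8), nrow = 8),
             matrix(rep(neg_total / 8, each = 8), nrow = 8))
  dimnames(m) <- list(emotion_categories(), as.character(SIM_MONTHS))
  m
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    abort(paste0("invalid simulation config field '", field, "': ", msg),
          class = "osgminer_bad_config")
  }
  if (cfg$n_patients < 1L) fail("n_patients", "must be >= 1")
  for (f in c("group_mix", "treatment_mix")) {
    p <- cfg[[f]]
    if (any(p < 0 | p > 1)) fail(f, "probabilities must be in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) fail(f, "must sum to 1")
  }
  if (!setequal(names(cfg$group_mix), DECISION_GROUPS)) {
    fail("group_mix", "must be named over the four decision groups")
  }
  if (!setequal(names(cfg$treatment_mix), TREATMENT_CATEGORIES)) {
    fail("treatment_mix", "must be named over the treatment categories")
  }
  for (f in c("side_effect_hazard", "advice_prob", "disclosure_probs",
              "noise_decoy_prob")) {
    p <- cfg[[f]]
    if (any(p < 0 | p > 1)) fail(f, "probabilities must be in [0, 1]")
  }
  if (!identical(dim(cfg$posting_rate), c(4L, 16L))) {
    fail("posting_rate", "must be a 4 x 16 groups-by-months matrix")
  }
  if (!identical(dim(cfg$side_effect_hazard), c(4L, 16L))) {
    fail("side_effect_hazard", "must be a 4 x 16 categories-by-months matrix")
  }
  if (!identical(dim(cfg$emotion_density), c(16L, 16L))) {
    fail("emotion_density", "must be a 16 x 16 categories-by-months matrix")
  }
  if (any(cfg$posting_rate < 0)) fail("posting_rate", "rates must be >= 0")
  if (any(cfg$emotion_density < 0)) fail("emotion_density", "must be >= 0")
  structure(cfg, class = "osg_sim_config")
}

largest_remainder <- function(p, n) {
  exact <- p * n
  base <- floor(exact)
  rem <- exact - base
  need <- n - sum(base)
  if (need > 0) {
    add <- order(-rem)[seq_len(need)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

read_phrasebook <- function() {
  readr::read_tsv(extdata_path("phrasebook.tsv"),
                  col_types = readr::cols(.default = "c"), progress = FALSE)
}

AUTONOMOUS_REALIZATIONS <- list(
  c("decided", "on"), c("opted", "for"), c("went for", ""),
  c("settled", "on"), c("chose", ""))
AUTONOMOUS_TAILS <- c("", " in the end", " after a lot of reading",
                      " this spring")
PATERNALISTIC_VERBS <- c("recommended", "advised", "endorsed", "prescribed")
PATERNALISTIC_DOCTORS <- c("doctor", "doc", "surgeon", "urologist",
                           "specialist", "consultant", "oncologist")
PATERNALISTIC_TAILS <- c("", " at the last review", " straight away",
                         " quite firmly")

FACTOR_SENTENCES <- c(
  `doctor experience` = "his experience with these cases mattered to us.",
  `side effects` = "we went over the possible side effects at length.",
  `best cancer control` = "cancer control was the main priority for me.",
  age = "at my age it seemed the sensible route.",
  `fast recovery` = "a quick recovery was important given work.",
  `financial concerns` = "insurance covered most of the fees.",
  `bowel symptoms` = "bowel problems were something i wanted to avoid.",
  `radiation oncologist` = "the radiation oncologist walked us through the plan.")

DECOY_SENTENCES <- c("i have not decided on surgery yet.",
                     "i never went for radiation in the end.",
                     "my doctor never recommended surgery.")

realize_autonomous <- function(treat_term) {
  r <- AUTONOMOUS_REALIZATIONS[[sample.int(length(AUTONOMOUS_REALIZATIONS), 1)]]
  conn <- if (nzchar(r[2])) paste0(r[2], " ") else ""
  paste0("i ", r[1], " ", conn, treat_term,
         sample(AUTONOMOUS_TAILS, 1), ".")
}

realize_paternalistic <- function(treat_term) {
  paste0("my ", sample(PATERNALISTIC_DOCTORS, 1), " ",
         sample(PATERNALISTIC_VERBS, 1), " ", treat_term,
         sample(PATERNALISTIC_TAILS, 1), ".")
}

realize_age <- function(a) {
  switch(sample.int(4L, 1),
         sprintf("i am %d and still getting my head around it.", a),
         sprintf("i'm %d years old.", a),
         sprintf("%d yo here and learning as i go.", a),
         sprintf("age %d and starting to read up.", a))
}

realize_gleason <- function(primary, secondary, total) {
  if (!is.na(primary)) {
    core <- switch(sample.int(2L, 1),
                   sprintf("gleason %d+%d", primary, secondary),
                   sprintf("gs%d+%d", primary, secondary))
  } else {
    core <- switch(sample.int(3L, 1),
                   sprintf("gleason %d", total),
                   sprintf("gs %d", total),
                   sprintf("gleason score of %d", total))
  }
  paste0("the biopsy came back ", core, ".")
}

realize_psa <- function(v) {
  s <- sprintf("%.1f", v)
  switch(sample.int(4L, 1),
         paste0("my psa was ", s, "."),
         paste0("psa of ", s, " at the last check."),
         paste0("psa ", s, " at diagnosis."),
         paste0("psa=", s, " per the letter."))
}

#' Generate a synthetic OSG corpus with planted ground truth
#'
#' See [simulation_config()] for the study conditions the generator
#' emulates. Every planted item (decision sentence, clinical disclosure,
#' factor sentence, side-effect term, emotion term, advice styling) is
#' realized verbatim in a dialect the extractors support, so on the default
#' noiseless configuration a correct pipeline recovers the ground truth
#' exactly. Identical config and seed give a byte-identical corpus.
#'
#' @param config An [simulation_config()] object.
#' @return A list of class `osg_simulation` with `posts` (a corpus tibble),
#'   `truth` (ground-truth tables: `patients`, `factors`, `side_effects`,
#'   `emotions`, `advice`, `witnesses`) and `config`.
#' @export
generate_corpus <- function(config = simulation_config()) {
  if (!inherits(config, "osg_sim_config")) config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  months <- SIM_MONTHS
  groups <- DECISION_GROUPS

  counts <- largest_remainder(config$group_mix[groups], n)
  patients <- tibble(
    patient_id = sprintf("pt%04d", seq_len(n)),
    group = rep(groups, counts),
    anchor_idx = sample(seq(month_to_idx("2009-01"), month_to_idx("2011-12")),
                        n, replace = TRUE))
  included_mask <- patients$group != "Unclassified"
  patients$treatment <- NA_character_
  patients$treatment[included_mask] <-
    sample(names(config$treatment_mix), sum(included_mask), replace = TRUE,
           prob = config$treatment_mix)
  patients$t0_month <- ifelse(included_mask,
                              idx_to_month(patients$anchor_idx), NA)

  # clinical disclosures
  patients$age <- ifelse(runif(n) < config$disclosure_probs[["age"]],
                         sample(45:78, n, replace = TRUE), NA_integer_)
  has_gleason <- runif(n) < config$disclosure_probs[["gleason"]]
  comp_form <- runif(n) < 0.6
  patients$gleason_primary <- ifelse(has_gleason & comp_form,
                                     sample(3:5, n, replace = TRUE), NA_integer_)
  patients$gleason_secondary <- ifelse(has_gleason & comp_form,
                                       sample(3:5, n, replace = TRUE),
                                       NA_integer_)
  patients$gleason_total <- ifelse(
    has_gleason,
    ifelse(comp_form, patients$gleason_primary + patients$gleason_secondary,
           sample(6:9, n, replace = TRUE)),
    NA_integer_)
  patients$psa <- ifelse(runif(n) < config$disclosure_probs[["psa"]],
                         round(runif(n, 2, 25), 1), NA_real_)

  # post skeleton: patient x relative month
  skel <- tidyr::expand_grid(patient_id = patients$patient_id,
                             rel_month = months) |>
    dplyr::left_join(patients[, c("patient_id", "group", "anchor_idx")],
                     by = "patient_id")
  rate <- config$posting_rate[cbind(skel$group, as.character(skel$rel_month))]
  skel$n_posts <- rpois(nrow(skel), rate)
  skel$n_posts[skel$rel_month == 0L] <-
    pmax(skel$n_posts[skel$rel_month == 0L], 1L)
  if (config$out_of_window_rate > 0) {
    extra <- tidyr::expand_grid(patient_id = patients$patient_id,
                                rel_month = c(13L, 14L)) |>
      dplyr::left_join(patients[, c("patient_id", "group", "anchor_idx")],
                       by = "patient_id")
    extra$n_posts <- rpois(nrow(extra), config$out_of_window_rate)
    skel <- dplyr::bind_rows(skel, extra)
  }

  # side-effect planting: exact counts over included patients per cell
  included_ids <- patients$patient_id[included_mask]
  n_inc <- length(included_ids)
  planted_se <- list()
  for (cat in rownames(config$side_effect_hazard)) {
    for (mi in seq_along(months)) {
      k <- as.integer(floor(config$side_effect_hazard[cat, mi] * n_inc + 0.5))
      if (k == 0L) next
      sel <- sample(included_ids, k)
      planted_se[[length(planted_se) + 1L]] <-
        tibble(patient_id = sel, rel_month = months[mi], category = cat)
    }
  }
  planted_se <- dplyr::bind_rows(planted_se)
  # make sure every planted (patient, month) cell has a post to carry it
  if (nrow(planted_se) > 0L) {
    need <- dplyr::distinct(planted_se, .data$patient_id, .data$rel_month)
    skel <- skel |>
      dplyr::left_join(dplyr::mutate(need, .need = TRUE),
                       by = c("patient_id", "rel_month")) |>
      dplyr::mutate(n_posts = ifelse(!is.na(.data$.need) & .data$n_posts == 0L,
                                     1L, .data$n_posts)) |>
      dplyr::select(-".need")
  }

  posts <- skel[rep(seq_len(nrow(skel)), skel$n_posts),
                c("patient_id", "rel_month", "group", "anchor_idx")]
  posts$cal_idx <- posts$anchor_idx + posts$rel_month
  month_start <- as.POSIXct(paste0(idx_to_month(posts$cal_idx), "-01"),
                            tz = "UTC")
  posts$timestamp <- month_start + floor(runif(nrow(posts), 0, 28 * 86400))
  posts <- posts[order(posts$timestamp, posts$patient_id), , drop = FALSE]
  posts$post_id <- sprintf("p%06d", seq_len(nrow(posts)))

  # threads: consecutive same-calendar-month posts, thread_size at a time
  posts <- posts |>
    dplyr::group_by(.data$cal_idx) |>
    dplyr::mutate(.slice = (dplyr::row_number() - 1L) %/% config$thread_size,
                  thread_id = sprintf("th_%s_%03d", idx_to_month(.data$cal_idx[1]),
                                      .data$.slice),
                  is_opener = dplyr::row_number() %% config$thread_size == 1L |
                    config$thread_size == 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".slice")

  # roles of special posts
  posts <- posts |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.ord = dplyr::row_number(),
                  is_first = .data$.ord == 1L) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(is_decision = .data$group != "Unclassified" &
                    .data$rel_month == 0L &
                    .data$.ord == min(.data$.ord[.data$rel_month == 0L])) |>
    dplyr::ungroup()

  # advice flags (replies only, in-window months only)
  adv_p <- rep(0, nrow(posts))
  inw <- posts$rel_month >= months[1] & posts$rel_month <= months[length(months)]
  adv_p[inw] <- config$advice_prob[match(posts$rel_month[inw], months)]
  posts$advice <- !posts$is_opener & runif(nrow(posts)) < adv_p

  # factor planting
  factors <- list()
  f_range <- config$factor_count_range
  for (pid in included_ids) {
    nf <- sample(seq(f_range[1], f_range[2]), 1)
    factors[[pid]] <- sample(names(config$factor_weights), nf,
                             prob = config$factor_weights)
  }
  truth_factors <- tibble(
    patient_id = rep(included_ids, lengths(factors)),
    factor = unlist(factors, use.names = FALSE))

  # map planted side effects to the patient's first post of that month
  first_post_of_month <- posts |>
    dplyr::group_by(.data$patient_id, .data$rel_month) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "rel_month", "post_id")
  se_thesaurus <- side_effect_thesaurus()
  if (nrow(planted_se) > 0L) {
    planted_se <- planted_se |>
      dplyr::left_join(first_post_of_month, by = c("patient_id", "rel_month"))
    planted_se$term <- vapply(planted_se$category, function(cat) {
      sample(se_thesaurus[[cat]], 1)
    }, character(1))
  }

  # emotion planting: Poisson counts per post x category
  lex <- emotion_lexicon()
  cat_terms <- split(lex$term, lex$category)
  dens_col <- pmin(pmax(posts$rel_month, months[1]), months[length(months)])
  dens <- config$emotion_density[, match(dens_col, months), drop = FALSE]
  emo_counts <- matrix(rpois(length(dens), as.numeric(dens)),
                       nrow = nrow(config$emotion_density))
  rownames(emo_counts) <- rownames(config$emotion_density)
  nz <- which(emo_counts > 0, arr.ind = TRUE)
  truth_emotions <- tibble(
    post_id = posts$post_id[nz[, "col"]],
    category = rownames(emo_counts)[nz[, "row"]],
    count = emo_counts[nz])

  # decision sentence realization
  dec_lex <- decision_lexicon()
  phrase <- read_phrasebook()
  fillers <- phrase$text[phrase$kind == "filler"]
  questions <- phrase$text[phrase$kind == "question"]
  advice_sents <- phrase$text[phrase$kind == "advice"]
  emo_carriers <- phrase$text[phrase$kind == "emotion_carrier"]
  se_carriers <- phrase$text[phrase$kind == "side_effect_carrier"]

  sample_treat_term <- function(treatment) {
    sample(dec_lex$treatment[[treatment]], 1)
  }

  witnesses <- list()
  note_witness <- function(pid, post, kind, text) {
    witnesses[[length(witnesses) + 1L]] <<-
      tibble(patient_id = pid, post_id = post, kind = kind, text = text)
  }

  # factor sentence placement: decision post, or the next post after it
  patient_posts <- split(posts$post_id, posts$patient_id)
  decision_post <- setNames(rep(NA_character_, n), patients$patient_id)
  dp <- posts$patient_id[posts$is_decision]
  decision_post[dp] <- posts$post_id[posts$is_decision]
  factor_placement <- list()
  for (pid in included_ids) {
    dpost <- decision_post[[pid]]
    seq_posts <- patient_posts[[pid]]
    nxt <- seq_posts[which(seq_posts == dpost) + 1L]
    for (f in factors[[pid]]) {
      target <- if (!is.na(nxt) && length(nxt) == 1L && runif(1) < 0.3) nxt
                else dpost
      factor_placement[[length(factor_placement) + 1L]] <-
        tibble(patient_id = pid, post_id = target, factor = f)
    }
  }
  factor_placement <- dplyr::bind_rows(factor_placement)

  # decoys
  decoy_posts <- character()
  if (config$noise_decoy_prob > 0) {
    hit <- runif(n) < config$noise_decoy_prob
    decoy_posts <- vapply(patients$patient_id[hit], function(pid) {
      sample(patient_posts[[pid]], 1)
    }, character(1))
  }

  se_by_post <- if (nrow(planted_se) > 0L) split(seq_len(nrow(planted_se)),
                                                 planted_se$post_id) else list()
  emo_by_post <- split(seq_len(nrow(truth_emotions)), truth_emotions$post_id)
  fac_by_post <- if (nrow(factor_placement) > 0L)
    split(factor_placement$factor, factor_placement$post_id) else list()
  pat_idx <- match(posts$patient_id, patients$patient_id)

  texts <- character(nrow(posts))
  for (i in seq_len(nrow(posts))) {
    pid <- posts$patient_id[i]
    post <- posts$post_id[i]
    pi <- pat_idx[i]
    sents <- character()
    if (posts$is_opener[i]) sents <- c(sents, sample(questions, 1))
    if (posts$is_first[i]) {
      if (!is.na(patients$age[pi])) {
        s <- realize_age(patients$age[pi])
        sents <- c(sents, s); note_witness(pid, post, "age", s)
      }
      if (!is.na(patients$gleason_total[pi])) {
        s <- realize_gleason(patients$gleason_primary[pi],
                             patients$gleason_secondary[pi],
                             patients$gleason_total[pi])
        sents <- c(sents, s); note_witness(pid, post, "gleason", s)
      }
      if (!is.na(patients$psa[pi])) {
        s <- realize_psa(patients$psa[pi])
        sents <- c(sents, s); note_witness(pid, post, "psa", s)
      }
    }
    if (posts$is_decision[i]) {
      grp <- patients$group[pi]
      trt <- patients$treatment[pi]
      if (grp %in% c("Autonomous", "Shared")) {
        s <- realize_autonomous(sample_treat_term(trt))
        sents <- c(sents, s); note_witness(pid, post, "decision_autonomous", s)
      }
      if (grp %in% c("Paternalistic", "Shared")) {
        s <- realize_paternalistic(sample_treat_term(trt))
        sents <- c(sents, s); note_witness(pid, post, "decision_paternalistic", s)
      }
    }
    facs <- fac_by_post[[post]]
    if (!is.null(facs)) {
      for (f in unique(facs)) {
        s <- FACTOR_SENTENCES[[f]]
        sents <- c(sents, s); note_witness(pid, post, paste0("factor:", f), s)
      }
    }
    ses <- se_by_post[[post]]
    if (!is.null(ses)) {
      for (j in ses) {
        s <- sub("{term}", planted_se$term[j], sample(se_carriers, 1),
                 fixed = TRUE)
        sents <- c(sents, s)
      }
    }
    emos <- emo_by_post[[post]]
    if (!is.null(emos)) {
      for (j in emos) {
        cat <- truth_emotions$category[j]
        terms <- sample(cat_terms[[cat]], truth_emotions$count[j],
                        replace = TRUE)
        for (tm in terms) {
          sents <- c(sents, sub("{term}", tm, sample(emo_carriers, 1),
                                fixed = TRUE))
        }
      }
    }
    if (posts$advice[i]) sents <- c(sents, sample(advice_sents, 1))
    if (post %in% decoy_posts) sents <- c(sents, sample(DECOY_SENTENCES, 1))
    sents <- c(sents, sample(fillers, 1 + rpois(1, 0.7), replace = TRUE))
    texts[i] <- paste(sents, collapse = " ")
  }

  corpus <- tibble(
    post_id = posts$post_id,
    patient_id = posts$patient_id,
    thread_id = posts$thread_id,
    forum = "synthetic-osg",
    timestamp = posts$timestamp,
    text = texts)

  truth <- list(
    patients = patients |>
      dplyr::mutate(included = .data$group != "Unclassified") |>
      dplyr::select("patient_id", "group", "treatment", "t0_month",
                    "included", "age", "gleason_primary", "gleason_secondary",
                    "gleason_total", "psa"),
    factors = dplyr::arrange(dplyr::distinct(truth_factors),
                             .data$patient_id, .data$factor),
    side_effects = if (nrow(planted_se) > 0L) {
      planted_se[, c("patient_id", "rel_month", "category", "term", "post_id")]
    } else {
      tibble(patient_id = character(), rel_month = integer(),
             category = character(), term = character(), post_id = character())
    },
    emotions = truth_emotions,
    advice = tibble(post_id = posts$post_id, advice = posts$advice,
                    is_opener = posts$is_opener),
    witnesses = dplyr::bind_rows(witnesses))

  structure(list(posts = corpus, truth = truth, config = config),
            class = "osg_simulation")
}

#' @export
print.osg_simulation <- function(x, ...) {
  cat("<osg_simulation> ", nrow(x$posts), " posts from ",
      x$config$n_patients, " patients (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a sentence corpus with planted synonym pairs
#'
#' Builds a tokenized corpus for embedding training in which each planted
#' synonym pair shares a dedicated context vocabulary: sentences are
#' `context context WORD context context`, with WORD drawn from one pair
#' and the contexts from that pair's private word set. Words of a pair are
#' therefore distributionally near-identical, and a sound skip-gram
#' embedding places each partner among its mate's nearest neighbours.
#'
#' @param n_sentences Number of sentences.
#' @param pairs A list of length-2 character vectors (the synonym pairs).
#' @param context_size Context words per pair.
#' @param seed Integer seed.
#' @return A list of character token vectors.
#' @export
simulate_embedding_corpus <- function(n_sentences = 10000L,
                                      pairs = list(
                                        c("glad", "happy"),
                                        c("terrible", "awful"),
                                        c("doctor", "physician"),
                                        c("worried", "anxious"),
                                        c("tired", "fatigued")),
                                      context_size = 8L, seed = 1L) {
  stopifnot(n_sentences >= 1L, length(pairs) >= 1L)
  set.seed(seed)
  ctx <- lapply(seq_along(pairs), function(k) {
    sprintf("ctx%02d_%02d", k, seq_len(context_size))
  })
  pair_of <- sample.int(length(pairs), n_sentences, replace = TRUE)
  lapply(pair_of, function(k) {
    w <- sample(pairs[[k]], 1)
    c(sample(ctx[[k]], 2, replace = TRUE), w,
      sample(ctx[[k]], 2, replace = TRUE))
  })
}
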
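#' Check that every planted ground-truth item has a verbatim witness
#'
#' Exhaustively verifies the generator's realization guarantee: each
#' recorded witness sentence, each planted side-effect term and each
#' planted emotion term occurs verbatim in the text of its designated post.
#'
#' @param sim An `osg_simulation` from [generate_corpus()].
#' @return `TRUE` invisibly; aborts listing the first missing witnesses
#'   otherwise.
#' @export
verify_realization <- function(sim) {
  text_of <- setNames(sim$posts$text, sim$posts$post_id)
  problems <- character()
  w <- sim$truth$witnesses
  for (i in seq_len(nrow(w))) {
    if (!grepl(w$text[i], text_of[[w$post_id[i]]], fixed = TRUE)) {
      problems <- c(problems, paste0(w$kind[i], " in ", w$post_id[i]))
    }
  }
  se <- sim$truth$side_effects
  for (i in seq_len(nrow(se))) {
    if (!grepl(se$term[i], text_of[[se$post_id[i]]], fixed = TRUE)) {
      problems <- c(problems, paste0("side effect '", se$term[i], "' in ",
                                     se$post_id[i]))
    }
  }
  if (length(problems) > 0L) {
    abort(paste0("unrealized planted item(s): ",
                 paste(head(problems, 10), collapse = "; ")),
          class = "osgminer_unrealized")
  }
  invisible(TRUE)
}

binom_ci_contains <- function(k, n, p) {
  if (n == 0L) return(NA)
  lo <- if (k == 0L) 0 else stats::qbeta(0.025, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(0.975, k + 1, n - k)
  p >= lo & p <= hi
}

#' Score pipeline recovery against planted ground truth
#'
#' Compares every stage of a pipeline run with the generator's ground
#' truth: decision-group/treatment/t0 accuracy, inclusion percentage,
#' clinical recall and precision, per-month side-effect prevalence error
#' (with exact binomial 95% CI coverage of the planted hazards),
#' rank correlation of the monthly emotion composites against the planted
#' density schedule, and advice-label accuracy.
#'
#' @param sim An `osg_simulation`.
#' @param result An `osg_pipeline` from [run_pipeline()] on `sim$posts`.
#' @return An `osg_recovery` object; `tidy()` gives the metric table, and
#'   `$side_effect_cells` / `$emotion_months` hold the per-cell detail.
#' @export
score_recovery <- function(sim, result) {
  truth <- sim$truth
  tp <- truth$patients
  assess <- result$assessments
  if (!setequal(tp$patient_id, assess$patient_id)) {
    abort("ground truth and pipeline cover different patient sets",
          class = "osgminer_universe_mismatch")
  }
  j <- dplyr::left_join(tp, assess, by = "patient_id",
                        suffix = c(".true", ".est"))
  inc <- j[j$included, , drop = FALSE]

  group_accuracy <- mean(j$group.true == j$group.est)
  treatment_accuracy <- mean(inc$treatment.true == inc$treatment.est,
                             na.rm = FALSE)
  t0_exact_rate <- mean(inc$t0_month.true == inc$t0_month.est)

  incl <- inclusion_summary(result$included)
  planted_pct <- 100 * sum(tp$included) / nrow(tp)

  # factor sets: exact set equality per included patient
  est_factors <- assess |>
    dplyr::select("patient_id", "factors")
  truth_f <- split(truth$factors$factor, truth$factors$patient_id)
  factor_exact <- vapply(inc$patient_id, function(pid) {
    est <- sort(est_factors$factors[[match(pid, est_factors$patient_id)]])
    setequal(est, truth_f[[pid]] %||% character())
  }, logical(1))

  # clinical recall / precision
  clin <- result$clinical
  cj <- dplyr::left_join(tp, clin, by = "patient_id")
  age_recall <- mean(cj$age.y[!is.na(cj$age.x)] == cj$age.x[!is.na(cj$age.x)],
                     na.rm = FALSE)
  age_precision <- {
    got <- !is.na(cj$age.y)
    if (any(got)) mean(cj$age.x[got] == cj$age.y[got], na.rm = FALSE) else NA
  }
  gl_truth <- !is.na(cj$gleason_total)
  gleason_recall <- mean(cj$first_gleason_total[gl_truth] ==
                           cj$gleason_total[gl_truth] &
                         (is.na(cj$gleason_primary[gl_truth]) |
                            (cj$first_gleason_primary[gl_truth] ==
                               cj$gleason_primary[gl_truth] &
                             cj$first_gleason_secondary[gl_truth] ==
                               cj$gleason_secondary[gl_truth])))
  gleason_precision <- {
    got <- cj$n_gleason_mentions > 0L
    if (any(got)) mean(gl_truth[got]) else NA
  }
  psa_recall <- {
    has <- !is.na(cj$psa)
    mean(abs(cj$max_psa[has] - cj$psa[has]) < 1e-9, na.rm = FALSE)
  }
  psa_precision <- {
    got <- cj$n_psa_mentions > 0L
    if (any(got)) mean(!is.na(cj$psa[got])) else NA
  }

  # side-effect prevalence per cell
  n_inc <- sum(tp$included)
  hazard <- sim$config$side_effect_hazard
  tl <- result$timelines
  cells <- list()
  for (cat in SIDE_EFFECT_CATEGORIES) {
    for (m in SIM_MONTHS) {
      k_rec <- sum(tl[[cat]][tl$rel_month == m] > 0L)
      k_pl <- sum(truth$side_effects$category == cat &
                    truth$side_effects$rel_month == m)
      p <- hazard[cat, as.character(m)]
      cells[[length(cells) + 1L]] <- tibble(
        category = cat, rel_month = m, planted_hazard = p,
        planted_count = k_pl, recovered_count = k_rec,
        recovered_prevalence = k_rec / n_inc,
        abs_error = abs(k_rec / n_inc - p),
        ci_contains_hazard = binom_ci_contains(k_rec, n_inc, p))
    }
  }
  cells <- dplyr::bind_rows(cells)

  # emotion composite vs planted density schedule (included posts, monthly)
  anchors <- result$included[, c("patient_id", "t0_month")]
  monthly <- result$scores |>
    dplyr::left_join(sim$posts[, c("post_id", "patient_id", "timestamp")],
                     by = "post_id") |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::mutate(rel_month = relative_month(.data$t0_month,
                                             post_month(.data$timestamp))) |>
    dplyr::filter(in_window(.data$rel_month)) |>
    dplyr::group_by(.data$rel_month) |>
    dplyr::summarise(positive = mean(.data$positive),
                     negative = mean(.data$negative), .groups = "drop") |>
    dplyr::arrange(.data$rel_month)
  dens <- sim$config$emotion_density
  sched_pos <- colSums(dens[POSITIVE_EMOTIONS, , drop = FALSE])
  sched_neg <- colSums(dens[NEGATIVE_EMOTIONS, , drop = FALSE])
  mm <- match(as.character(monthly$rel_month), colnames(dens))
  pos_cor <- cor(monthly$positive, sched_pos[mm], method = "spearman")
  neg_cor <- cor(monthly$negative, sched_neg[mm], method = "spearman")

  adv <- dplyr::left_join(truth$advice, result$roles, by = "post_id")
  advice_accuracy <- mean(adv$advice == (adv$role == "advice"))

  summary <- tibble(
    metric = c("group_accuracy", "treatment_accuracy", "t0_exact_rate",
               "inclusion_pct", "planted_inclusion_pct", "factor_exact_rate",
               "age_recall", "age_precision", "gleason_recall",
               "gleason_precision", "psa_recall", "psa_precision",
               "sideeffect_max_abs_error", "sideeffect_ci_coverage",
               "emotion_pos_rank_cor", "emotion_neg_rank_cor",
               "advice_accuracy"),
    value = c(group_accuracy, treatment_accuracy, t0_exact_rate,
              incl$pct_included, planted_pct, mean(factor_exact),
              age_recall, age_precision, gleason_recall, gleason_precision,
              psa_recall, psa_precision,
              max(cells$abs_error), mean(cells$ci_contains_hazard),
              pos_cor, neg_cor, advice_accuracy))

  structure(list(summary = summary, side_effect_cells = cells,
                 emotion_months = monthly,
                 n_patients = nrow(tp), n_included = n_inc),
            class = "osg_recovery")
}

#' @export
print.osg_recovery <- function(x, ...) {
  cat("<osg_recovery> ", x$n_patients, " patients (", x$n_included,
      " included)\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy a recovery report
#'
#' @param x An `osg_recovery`.
#' @param ... Unused.
#' @return The metric/value tibble.
#' @export
tidy.osg_recovery <- function(x, ...) x$summary
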
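#' Plot group trajectories over relative months
#'
#' Line plot of one trajectory metric per group from t-3 to t+12, with the
#' decision month marked.
#'
#' @param trajectories An `osg_trajectories` tibble from
#'   [build_group_trajectories()].
#' @param metric Column to plot (e.g. `"n_active_patients"`,
#'   `"advice_post_pct"`, `"positive_mean"`, `"urinary_pct"`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, metric = "n_active_patients") {
  if (!metric %in% names(trajectories)) {
    abort(paste0("unknown trajectory metric: ", metric))
  }
  ggplot(trajectories,
         aes(x = .data$rel_month, y = .data[[metric]],
             colour = .data$group)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "month relative to decision (t0 = 0)", y = metric,
         colour = trajectories$grouping[1] %||% "group") +
    theme_minimal()
}

#' @rdname plot_trajectories
#' @param object An `osg_trajectories`.
#' @param ... Passed on; `metric` is honoured.
#' @export
autoplot.osg_trajectories <- function(object, ...) {
  plot_trajectories(object, ...)
}

#' Plot a group's mean emotion profile
#'
#' Bar chart of the 16 mean emotion intensities for each group in an
#' aggregated emotion table.
#'
#' @param aggregated Output of [aggregate_emotions()] with a grouping
#'   column.
#' @param group_col Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_emotion_profile <- function(aggregated, group_col = "group") {
  cats <- emotion_categories()
  long <- aggregated |>
    tidyr::pivot_longer(dplyr::all_of(cats), names_to = "emotion",
                        values_to = "intensity") |>
    dplyr::mutate(emotion = factor(.data$emotion, levels = cats),
                  valence = ifelse(.data$emotion %in% POSITIVE_EMOTIONS,
                                   "positive", "negative"))
  ggplot(long, aes(x = .data$emotion, y = .data$intensity,
                   fill = .data$valence)) +
    geom_col() +
    facet_wrap(stats::reformulate(group_col)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1)) +
    labs(x = NULL, y = "mean intensity")
}
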
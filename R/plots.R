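#' Spatial response heat map of a ROI set
#'
#' Tiles coloured by the response-window mean dF/F, faceted by animal and
#' field of view — the spatial summary view of an odour response.
#'
#' @param object a `roi_trace_set`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot roi_trace_set
#' @export
autoplot.roi_trace_set <- function(object, ...) {
  gd <- attr(object, "grid_dims") %||% c(6L, 6L)
  df <- object %>%
    mutate(row = (.data$roi - 1L) %/% gd[2] + 1L,
           col = (.data$roi - 1L) %% gd[2] + 1L)
  ggplot(df, aes(.data$col, .data$row, fill = .data$response_stat)) +
    geom_tile() +
    facet_grid(animal_id ~ fov_id) +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 0) +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL, fill = "dF/F",
         title = "Response-window dF/F per ROI") +
    theme_minimal()
}

#' Plot an animal grand-average trace
#'
#' @param ga tibble from [grand_average()] (columns `frame`, `dff`).
#' @param win an [analysis_windows()] used to mark the stimulus frame.
#' @return A ggplot object.
#' @export
plot_grand_average <- function(ga, win = analysis_windows()) {
  ggplot(ga, aes(.data$frame, .data$dff)) +
    geom_line() +
    geom_vline(xintercept = win$stim_frame, linetype = "dashed") +
    labs(x = "frame", y = "dF/F", title = "Animal grand-average response") +
    theme_minimal()
}

#' Nose-to-tip distance over a session
#'
#' @param object a `behavior_session` with a `dist_cm` column.
#' @param radius zone radius drawn as a reference line.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot behavior_session
#' @export
autoplot.behavior_session <- function(object, radius = 2, ...) {
  fps <- attr(object, "fps") %||% 1
  ggplot(object, aes(.data$frame / fps, .data$dist_cm)) +
    geom_line() +
    geom_hline(yintercept = radius, linetype = "dashed") +
    labs(x = "time (s)", y = "nose-tip distance (cm)",
         title = "Odour investigation") +
    theme_minimal()
}

#' Per-slice density records by group
#'
#' @param records tidy density tibble (`group`, `animal_id`, `value`).
#' @return A ggplot object.
#' @export
plot_density_records <- function(records) {
  ggplot(records, aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    labs(x = NULL, y = "area (%)", title = "Staining density per slice") +
    theme_minimal()
}

#' Group uptake curves of a phagocytosis series
#'
#' @param series uptake tibble (index computed when absent).
#' @return A ggplot object.
#' @export
plot_uptake <- function(series) {
  if (!"index" %in% names(series)) series <- phagocytic_index(series)
  df <- series %>%
    filter(!is.na(.data$index)) %>%
    group_by(.data$group, .data$time_h) %>%
    summarise(mean_index = mean(.data$index),
              sem = sd(.data$index) / sqrt(dplyr::n()), .groups = "drop")
  ggplot(df, aes(.data$time_h, .data$mean_index, colour = .data$group)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean_index - .data$sem,
                      ymax = .data$mean_index + .data$sem), width = 0.3) +
    labs(x = "time (h)", y = "phagocytic index",
         title = "Cargo uptake per cell") +
    theme_minimal()
}
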
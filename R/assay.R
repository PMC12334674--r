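#' Simulate a phagocytosis uptake time course
#'
#' Per-well, per-image time series of total integrated cargo fluorescence
#' and adherent cell count, following a saturating (logistic-shaped in
#' time) mean uptake curve. The case group's curve is the control's times
#' `fold` at every timepoint; an optional actin-polymerisation-blocked
#' group (`cytoD`) has intensity pinned near zero. Each well contributes
#' `n_images` technical images per timepoint, mirroring live-cell scans
#' that acquire several fields per well.
#'
#' @param plateau_control control-group plateau of the phagocytic index
#'   (intensity per cell), index units.
#' @param fold case-over-control ratio at every timepoint.
#' @param timepoints hours; must include 12 h.
#' @param noise_cv per-image multiplicative noise cv.
#' @param n_wells wells per group.
#' @param n_images technical images per well and timepoint.
#' @param cells_per_image mean adherent cells per image.
#' @param include_cytod add the blocked-uptake control group.
#' @param t_half,hill shape of the saturating curve (index reaches
#'   `plateau * t^hill / (t^hill + t_half^hill)`).
#' @param seed integer seed.
#' @return A tibble with `group`, `well_id`, `image`, `time_h`,
#'   `total_intensity`, `cell_count`.
#' @export
gen_phago_series <- function(plateau_control = 20, fold = 1.33,
                             timepoints = 0:24, noise_cv = 0.10,
                             n_wells = 12L, n_images = 3L,
                             cells_per_image = 150, include_cytod = FALSE,
                             t_half = 6, hill = 2, seed = 1L) {
  ns_check(plateau_control > 0, "`plateau_control` must be > 0")
  ns_check(12 %in% timepoints, "`timepoints` must include the 12 h point")
  set.seed(ns_substream(seed, 99L))
  curve <- function(t) plateau_control * t^hill / (t^hill + t_half^hill)
  groups <- c(control = 1, case = fold)
  if (include_cytod) groups <- c(groups, cytoD = 1e-4)
  rows <- list()
  for (g in names(groups)) {
    for (w in seq_len(n_wells)) {
      cells <- max(1, round(rnorm(1, cells_per_image, cells_per_image * 0.05)))
      for (tm in timepoints) {
        mu <- curve(tm) * groups[[g]]
        eps <- if (noise_cv > 0) rnorm(n_images, 1, noise_cv) else rep(1, n_images)
        rows[[length(rows) + 1L]] <- tibble(
          group = g, well_id = sprintf("%s_w%02d", g, w),
          image = seq_len(n_images), time_h = tm,
          total_intensity = pmax(0, mu * cells * eps),
          cell_count = cells
        )
      }
    }
  }
  bind_rows(rows)
}

#' Phagocytic index
#'
#' Total integrated cargo intensity per image divided by the number of
#' adherent cells in that image. Rows with zero cells are flagged missing
#' (`NA`), never coerced to zero.
#'
#' @param series an uptake tibble with `total_intensity` and `cell_count`
#'   columns (e.g. from [gen_phago_series()]).
#' @return The input with an added `index` column (intensity units per
#'   cell).
#' @export
phagocytic_index <- function(series) {
  ns_check(all(c("total_intensity", "cell_count") %in% names(series)),
           "`series` needs total_intensity and cell_count columns")
  mutate(series, index = ifelse(.data$cell_count > 0,
                                .data$total_intensity / .data$cell_count,
                                NA_real_))
}

#' Normalise group uptake to the control group at one timepoint
#'
#' Technical images are averaged within well first, then well indices are
#' averaged per group at `at_time`; each group's mean is expressed as a
#' fold of the control group's and as a percent difference.
#'
#' @param series uptake tibble (with or without an `index` column; it is
#'   computed when absent).
#' @param control control group label.
#' @param at_time timepoint in hours (default 12).
#' @return A tibble with one row per group: `group`, `mean_index`,
#'   `fold`, `percent_difference`.
#' @export
normalize_to_control <- function(series, control = "control", at_time = 12) {
  if (!"index" %in% names(series)) series <- phagocytic_index(series)
  at <- filter(series, .data$time_h == at_time, !is.na(.data$index))
  ns_check(nrow(at) > 0, "no data at the requested timepoint")
  ns_check(control %in% at$group, "control group '", control, "' missing")
  wells <- at %>%
    group_by(.data$group, .data$well_id) %>%
    summarise(well_index = mean(.data$index), .groups = "drop")
  gmeans <- wells %>%
    group_by(.data$group) %>%
    summarise(mean_index = mean(.data$well_index), .groups = "drop")
  ctrl <- gmeans$mean_index[gmeans$group == control]
  gmeans %>%
    mutate(fold = .data$mean_index / ctrl,
           percent_difference = 100 * (.data$fold - 1))
}
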
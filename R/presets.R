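#' Simulation presets
#'
#' A `sim_preset` bundles a generator's full parameter set with a name and a
#' seed, so a whole study condition can be referenced by one identifier.
#' The built-in presets encode the study scenarios the package's acceptance
#' checks recover: a control-like and an amyloidosis-like two-photon cohort,
#' fibre-density cohorts with planted relative losses at three ages plus an
#' LC-restricted transgene scenario, a buried-food latency contrast and a
#' phagocytosis uptake time course.
#'
#' @param name identifier for the preset.
#' @param params named list of generator parameters.
#' @param seed integer seed; together with `params` it fully determines the
#'   generated data.
#' @return An object of class `sim_preset` (a named list with `name`,
#'   `params`, `seed`).
#' @examples
#' p <- preset("wt_fig2")
#' p$params$p_inc
#' @export
sim_preset <- function(name, params = list(), seed = 42L) {
  ns_check(is.character(name) && length(name) == 1L, "`name` must be a single string")
  ns_check(is.list(params), "`params` must be a list")
  ns_check(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
           "`seed` must be a single integer")
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "sim_preset")
}

#' @export
print.sim_preset <- function(x, ...) {
  cat("<sim_preset> ", x$name, " (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    cat("  ", nm, ": ", paste(format(v), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# single source of truth for the named study conditions
ns_preset_table <- function() {
  twop_base <- list(
    n_animals = 3L, n_fovs = 3L, n_frames = 203L,
    height = 120L, width = 120L, n_z = 8L,
    frame_rate_hz = 1.13, stim_frame = 68L, stim_duration_s = 10,
    p_inc = 0.75, p_dec = 0.05,
    amp_inc = 0.04, amp_dec = -0.04,
    noise_sd = 0.005, baseline_mean = 100,
    n_vessels = 3L, rows = 6L, cols = 6L
  )
  fiber_base <- list(
    mean_control = 12, sd_control = 1,
    n_animals = 5L, n_slices = 4L, case_scale = 0.86,
    shape = c(192L, 192L), fibre_width = 2L, noise_sd = 8
  )
  list(
    wt_fig2  = sim_preset("wt_fig2",  twop_base, seed = 42L),
    app_fig2 = sim_preset("app_fig2",
                          modifyList(twop_base, list(p_inc = 0.40, p_dec = 0.15)),
                          seed = 42L),
    fiberloss_2m = sim_preset("fiberloss_2m", fiber_base, seed = 42L),
    fiberloss_3m = sim_preset("fiberloss_3m",
                              modifyList(fiber_base, list(case_scale = 0.73)),
                              seed = 42L),
    fiberloss_6m = sim_preset("fiberloss_6m",
                              modifyList(fiber_base, list(case_scale = 0.67)),
                              seed = 42L),
    dbh_app = sim_preset("dbh_app",
                         modifyList(fiber_base,
                                    list(case_scale = 0.85, n_slices = 3L)),
                         seed = 42L),
    buriedfood_3m = sim_preset("buriedfood_3m",
                               list(mean_control = 40, ratio = 1.60,
                                    n_control = 14L, n_case = 18L, cv = 0.30),
                               seed = 42L),
    phago_12h = sim_preset("phago_12h",
                           list(plateau_control = 20, fold = 1.33,
                                timepoints = 0:24, noise_cv = 0.10,
                                n_wells = 12L, n_images = 3L,
                                cells_per_image = 150, include_cytod = TRUE),
                           seed = 42L)
  )
}

#' Look up a built-in preset
#'
#' @param name preset name; see [list_presets()].
#' @param seed optional seed overriding the preset's documented default.
#' @return A [sim_preset()].
#' @export
preset <- function(name, seed = NULL) {
  tab <- ns_preset_table()
  ns_check(name %in% names(tab),
           "unknown preset '", name, "'; see list_presets()")
  p <- tab[[name]]
  if (!is.null(seed)) p$seed <- as.integer(seed)
  p
}

#' @rdname preset
#' @export
list_presets <- function() names(ns_preset_table())
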
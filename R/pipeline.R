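#' Build a pipeline run configuration
#'
#' One schema drives the end-to-end simulate-analyse-report runs. Every
#' default is echoed into the run report, so a report alone documents the
#' analysis that produced it.
#'
#' @param stages character subset of
#'   `c("twop", "histo", "behavior", "assay")` (default: all).
#' @param seed integer seed governing every generator in the run.
#' @param twop_preset,histo_presets,behavior_preset,assay_preset preset
#'   names per stage.
#' @param k dF/F classification dead-band width.
#' @param rows,cols ROI grid.
#' @param radius_cm investigation-zone radius.
#' @param at_time_h assay normalisation timepoint.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("twop", "histo", "behavior", "assay"),
                       seed = 42L,
                       twop_preset = "wt_fig2",
                       histo_presets = c("fiberloss_2m", "fiberloss_3m",
                                         "fiberloss_6m", "dbh_app"),
                       behavior_preset = "buriedfood_3m",
                       assay_preset = "phago_12h",
                       k = 2, rows = 6L, cols = 6L,
                       radius_cm = 2, at_time_h = 12) {
  stages <- match.arg(stages, several.ok = TRUE)
  known <- list_presets()
  for (p in c(twop_preset, histo_presets, behavior_preset, assay_preset)) {
    ns_check(p %in% known, "unknown preset '", p, "' in config")
  }
  structure(list(stages = stages, seed = as.integer(seed),
                 twop_preset = twop_preset, histo_presets = histo_presets,
                 behavior_preset = behavior_preset,
                 assay_preset = assay_preset, k = k, rows = rows,
                 cols = cols, radius_cm = radius_cm, at_time_h = at_time_h),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match
#'   [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, lst)
}

#' Run the simulate-analyse-report pipeline
#'
#' Executes the configured stages on their presets (every generator
#' seeded from `config$seed`), writes tidy per-stage CSVs plus a summary
#' JSON into `out_dir`, and returns the run report. A failing stage
#' aborts with that stage named; outputs of completed stages are
#' retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the report.
#' @return A `run_report` list: `config` (with every default filled in),
#'   `summary` (headline statistics), `outputs` (paths written) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  ns_check(inherits(config, "run_config"), "`config` must be a run_config")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  summary <- list(); outputs <- list()
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    outputs[[name]] <<- p
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "noradscope_error")
    })
  }

  if ("twop" %in% config$stages) {
    run_stage("twop", function() {
      cohort <- gen_twop_cohort(preset(config$twop_preset, seed = config$seed))
      rois <- twop_analyze(cohort$recordings, rows = config$rows,
                           cols = config$cols, k = config$k)
      fr <- response_fractions(rois)
      emit(select(rois, -"trace"), "twop_rois")
      emit(fr, "twop_fractions")
      summary$twop <<- list(preset = config$twop_preset,
                            n_rois = fr$n_rois,
                            pct_increase = fr$pct_increase,
                            pct_decrease = fr$pct_decrease)
    })
  }
  if ("histo" %in% config$stages) {
    run_stage("histo", function() {
      res <- purrr::map(config$histo_presets, function(pn) {
        hd <- histo_density(gen_fiber_cohort(preset(pn, seed = config$seed)))
        emit(hd$records, paste0("histo_", pn))
        tibble(preset = pn, loss_pct = hd$contrast$loss_pct,
               relative_density_pct = hd$contrast$relative_density_pct)
      }) %>% bind_rows()
      emit(res, "histo_loss")
      summary$histo <<- res
    })
  }
  if ("behavior" %in% config$stages) {
    run_stage("behavior", function() {
      pb <- preset(config$behavior_preset, seed = config$seed)
      lat <- do.call(gen_latencies, c(pb$params, list(seed = pb$seed)))
      ct <- latency_contrast(lat)
      emit(lat, "behavior_latencies")
      emit(ct, "behavior_contrast")
      summary$behavior <<- list(preset = config$behavior_preset,
                                percent_change = ct$percent_change)
    })
  }
  if ("assay" %in% config$stages) {
    run_stage("assay", function() {
      pa <- preset(config$assay_preset, seed = config$seed)
      ser <- do.call(gen_phago_series, c(pa$params, list(seed = pa$seed)))
      norm <- normalize_to_control(ser, at_time = config$at_time_h)
      emit(norm, "assay_normalized")
      fold <- norm$fold[norm$group == "case"]
      summary$assay <<- list(preset = config$assay_preset,
                             at_time_h = config$at_time_h,
                             fold = fold,
                             percent_difference = 100 * (fold - 1))
    })
  }

  report <- list(config = unclass(config), summary = summary,
                 outputs = outputs,
                 provenance = list(
                   package = "noradscope",
                   version = as.character(utils::packageVersion("noradscope")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC")
                 ))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report[c("config", "summary")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$summary), collapse = ", "), "\n")
  if (!is.null(x$summary$twop)) {
    cat(sprintf("  twop: %.1f%% increase / %.1f%% decrease (%d ROIs)\n",
                x$summary$twop$pct_increase, x$summary$twop$pct_decrease,
                x$summary$twop$n_rois))
  }
  if (!is.null(x$summary$histo)) {
    for (i in seq_len(nrow(x$summary$histo))) {
      cat(sprintf("  histo %s: %.1f%% loss\n", x$summary$histo$preset[i],
                  x$summary$histo$loss_pct[i]))
    }
  }
  if (!is.null(x$summary$behavior)) {
    cat(sprintf("  behavior: %+.1f%% latency change\n",
                x$summary$behavior$percent_change))
  }
  if (!is.null(x$summary$assay)) {
    cat(sprintf("  assay: fold %.3f at %g h\n", x$summary$assay$fold,
                x$summary$assay$at_time_h))
  }
  invisible(x)
}
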
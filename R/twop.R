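#' Two-photon recording container
#'
#' Holds one field of view's raw sensor movie as a 4-D intensity array
#' `(t, z, y, x)` together with the acquisition metadata the downstream
#' analysis needs.
#'
#' @param data numeric array with dimensions `(t, z, y, x)`; intensities
#'   must be non-negative.
#' @param frame_rate_hz volumetric frame rate in Hz.
#' @param stim_frame 1-based frame index of stimulus (odour puff) onset.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param animal_id,fov_id identifiers used when pooling recordings.
#' @return An object of class `twop_recording`.
#' @export
twop_recording <- function(data, frame_rate_hz = 1.13, stim_frame = 68L,
                           pixel_size_um = 1, animal_id = "a1", fov_id = "f1") {
  ns_check(is.array(data) && length(dim(data)) == 4L,
           "`data` must be a 4-D (t, z, y, x) array")
  ns_check(all(data >= 0), "intensities must be non-negative")
  ns_check(stim_frame >= 1L && stim_frame <= dim(data)[1],
           "`stim_frame` must lie within the recorded frames")
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 stim_frame = as.integer(stim_frame),
                 pixel_size_um = pixel_size_um,
                 animal_id = animal_id, fov_id = fov_id),
            class = "twop_recording")
}

#' @export
print.twop_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<twop_recording> %s/%s: %d frames x %d z x %d x %d px @ %.2f Hz (stim frame %d)\n",
              x$animal_id, x$fov_id, d[1], d[2], d[3], d[4],
              x$frame_rate_hz, x$stim_frame))
  invisible(x)
}

#' Analysis windows for the dF/F pipeline
#'
#' All frame indices are 1-based and ranges inclusive, matching how frames
#' are counted on the acquisition: baseline frames 20-67, stimulus onset at
#' frame 68, response window frames 89-91, and the first 20 frames flagged
#' invalid (kept in arrays so frame numbering is unchanged, but excluded
#' from downstream statistics; frame 20 itself is retained and belongs to
#' the baseline as printed).
#'
#' @param drop_first number of initial frames flagged invalid (default 20;
#'   frames 1..drop_first-1 are dropped, i.e. frame 20 is the first valid).
#' @param baseline inclusive frame range used for F0 (default `c(20, 67)`).
#' @param response inclusive frame range for the response statistic
#'   (default `c(89, 91)`).
#' @param stim_frame stimulus-onset frame (default 68).
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(drop_first = 20L, baseline = c(20L, 67L),
                             response = c(89L, 91L), stim_frame = 68L) {
  baseline <- as.integer(baseline); response <- as.integer(response)
  ns_check(length(baseline) == 2L && baseline[1] <= baseline[2],
           "`baseline` must be an inclusive c(first, last) range")
  ns_check(length(response) == 2L && response[1] <= response[2],
           "`response` must be an inclusive c(first, last) range")
  ns_check(baseline[2] < stim_frame,
           "baseline window must end before the stimulus frame")
  ns_check(response[1] >= stim_frame,
           "response window must start at or after the stimulus frame")
  structure(list(drop_first = as.integer(drop_first), baseline = baseline,
                 response = response, stim_frame = as.integer(stim_frame)),
            class = "analysis_windows")
}

#' Sum-project a 4-D recording over z
#'
#' Each time point's z-stack is collapsed by summation over all slices,
#' yielding a 2-D movie `(t, y, x)`.
#'
#' @param rec a [twop_recording()] or a bare `(t, z, y, x)` array.
#' @return A 3-D numeric array `(t, y, x)`.
#' @export
project_z <- function(rec) {
  a <- if (inherits(rec, "twop_recording")) rec$data else rec
  ns_check(is.array(a) && length(dim(a)) == 4L, "need a 4-D (t, z, y, x) array")
  ns_check(all(dim(a) > 0L), "empty stack")
  colSums(aperm(a, c(2L, 1L, 3L, 4L)), dims = 1L)
}

# shift a matrix by (dy, dx) with edge (replicate) padding
ns_shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  yi <- pmin(pmax(seq_len(h) - dy, 1L), h)
  xi <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[yi, xi, drop = FALSE]
}

#' Rigid (integer-shift) motion correction
#'
#' Estimates one integer `(dy, dx)` translation per frame by FFT
#' cross-correlation against the movie's temporal mean, clamps it to
#' `max_shift`, and applies the opposite shift with edge padding. This is a
#' deliberately simple rigid stand-in; non-rigid registration is out of
#' scope.
#'
#' @param movie 3-D `(t, y, x)` array.
#' @param max_shift maximum allowed shift magnitude per axis, in pixels;
#'   `max_shift = 0` is the identity.
#' @param reference `"mean"` (temporal mean, default; robust when most
#'   frames are still) or `"first"` (first frame; recovers a displacement
#'   shared by every later frame, which a moving-average reference would
#'   absorb into itself).
#' @return A list with `movie` (corrected array) and `shifts` (a tibble
#'   with columns `frame`, `dy`, `dx` — the estimated displacement of each
#'   frame relative to the reference).
#' @export
rigid_correct <- function(movie, max_shift = 5L,
                          reference = c("mean", "first")) {
  reference <- match.arg(reference)
  ns_check(is.array(movie) && length(dim(movie)) == 3L,
           "`movie` must be a (t, y, x) array")
  ns_check(max_shift >= 0, "`max_shift` must be >= 0")
  nt <- dim(movie)[1]
  if (max_shift == 0) {
    return(list(movie = movie,
                shifts = tibble(frame = seq_len(nt), dy = 0L, dx = 0L)))
  }
  ref <- if (reference == "mean") colMeans(movie) else movie[1, , ]
  h <- nrow(ref); w <- ncol(ref)
  fref <- fft(ref)
  out <- movie
  dys <- integer(nt); dxs <- integer(nt)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  for (t in seq_len(nt)) {
    fr <- movie[t, , ]
    cc <- Re(fft(fref * Conj(fft(fr)), inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc)) - 1L  # 0-based peak
    dy <- -wrap(pk[1], h); dx <- -wrap(pk[2], w) # frame displacement vs ref
    dy <- max(-max_shift, min(max_shift, dy))
    dx <- max(-max_shift, min(max_shift, dx))
    dys[t] <- dy; dxs[t] <- dx
    out[t, , ] <- ns_shift_matrix(fr, -dy, -dx)  # undo the displacement
  }
  list(movie = out, shifts = tibble(frame = seq_len(nt), dy = dys, dx = dxs))
}

#' Baseline-normalised dF/F
#'
#' Normalises a projected movie to its baseline window: for every pixel,
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean of `F` over the baseline
#' frames. Frames before `win$drop_first` are retained in the array but
#' flagged invalid (attribute `valid_frames`), so frame numbering still
#' matches the acquisition. Pixels whose `F0` falls at or below a floor of
#' `1e-6` times the movie's global mean (e.g. dead or vessel-dark pixels)
#' are flagged invalid (attribute `valid_pixels`) and excluded from tile
#' means; with `on_low_f0 = "error"` they abort with the affected pixel
#' count instead.
#'
#' @param movie 3-D `(t, y, x)` array of raw fluorescence.
#' @param win an [analysis_windows()].
#' @param normalization `"pixel"` (per-pixel F0, default — supports spatial
#'   response maps) or `"frame_mean"` (one scalar F0, the baseline mean of
#'   the whole-frame mean brightness).
#' @param on_low_f0 `"exclude"` (default) or `"error"`.
#' @return A 3-D dF/F array with attributes `valid_frames`, `valid_pixels`
#'   and `windows`.
#' @export
compute_dff <- function(movie, win = analysis_windows(),
                        normalization = c("pixel", "frame_mean"),
                        on_low_f0 = c("exclude", "error")) {
  normalization <- match.arg(normalization)
  on_low_f0 <- match.arg(on_low_f0)
  ns_check(is.array(movie) && length(dim(movie)) == 3L,
           "`movie` must be a (t, y, x) array")
  d <- dim(movie); nt <- d[1]
  ns_check(win$baseline[2] <= nt, "baseline window exceeds the recording")
  bidx <- win$baseline[1]:win$baseline[2]
  M <- movie; dim(M) <- c(nt, d[2] * d[3])
  floor_f0 <- 1e-6 * mean(M)
  if (normalization == "pixel") {
    f0 <- colMeans(M[bidx, , drop = FALSE])
    bad <- f0 <= floor_f0
    if (any(bad) && on_low_f0 == "error") {
      abort(sprintf("%d pixel(s) have baseline F0 at or below the floor (%.3g)",
                    sum(bad), floor_f0), class = "noradscope_error")
    }
    f0s <- f0; f0s[bad] <- 1   # placeholder; flagged pixels never enter stats
    dff <- sweep(M, 2L, f0s, "-")
    dff <- sweep(dff, 2L, f0s, "/")
    valid_px <- matrix(!bad, d[2], d[3])
  } else {
    b <- rowMeans(M)                 # per-frame mean brightness
    f0 <- mean(b[bidx])
    ns_check(f0 > floor_f0, "whole-frame baseline mean is at or below the floor")
    dff <- (M - f0) / f0
    valid_px <- matrix(TRUE, d[2], d[3])
  }
  dim(dff) <- d
  attr(dff, "valid_frames") <- seq_len(nt) >= win$drop_first
  attr(dff, "valid_pixels") <- valid_px
  attr(dff, "windows") <- win
  dff
}

#' dF/F with the long-recording baseline
#'
#' Identical to [compute_dff()] but with the alternate baseline range used
#' for long sensitivity recordings (frames 20-300 by default).
#'
#' @inheritParams compute_dff
#' @param baseline inclusive frame range, default `c(20, 300)`.
#' @export
long_mode_dff <- function(movie, baseline = c(20L, 300L),
                          normalization = c("pixel", "frame_mean")) {
  nt <- dim(movie)[1]
  win <- analysis_windows(baseline = baseline,
                          response = c(nt, nt), stim_frame = nt)
  compute_dff(movie, win, normalization = match.arg(normalization))
}

#' Partition a field of view into a grid of ROI tiles
#'
#' Splits an `height x width` image into `rows x cols` near-equal,
#' disjoint, covering tiles (the default 6x6 grid yields the 36 subtile
#' ROIs used throughout). When an axis does not divide evenly, the
#' remainder pixels are given one each to the first tiles along that axis.
#' Tiles are ordered row-major (ROI 1 is top-left).
#'
#' @param height,width image size in pixels.
#' @param rows,cols grid size (defaults 6x6).
#' @return A `tile_grid`: a tibble with columns `roi`, `row`, `col`,
#'   `y0`, `y1`, `x0`, `x1` (1-based inclusive pixel bounds).
#' @export
tile_grid <- function(height, width, rows = 6L, cols = 6L) {
  ns_check(height >= rows && width >= cols, "grid larger than image")
  cuts <- function(n, k) {
    base <- n %/% k; extra <- n %% k
    len <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    e <- cumsum(len)
    tibble(i0 = c(1L, head(e, -1L) + 1L), i1 = e)
  }
  ry <- cuts(height, rows); rx <- cuts(width, cols)
  g <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols)) %>%
    mutate(roi = dplyr::row_number(),
           y0 = ry$i0[.data$row], y1 = ry$i1[.data$row],
           x0 = rx$i0[.data$col], x1 = rx$i1[.data$col]) %>%
    select("roi", "row", "col", "y0", "y1", "x0", "x1")
  structure(g, class = c("tile_grid", class(g)),
            height = as.integer(height), width = as.integer(width))
}

# column indices (into a t x (y*x) matrix, y fastest) of a tile's pixels
ns_tile_cols <- function(tile, height) {
  ys <- tile$y0:tile$y1; xs <- tile$x0:tile$x1
  as.vector(outer(ys, (xs - 1L) * height, `+`))
}

#' Per-ROI dF/F traces and response statistics
#'
#' Averages the dF/F movie over each tile's valid pixels to one trace per
#' ROI, and computes the per-ROI summaries the classification uses:
#' baseline brightness (mean raw F over the baseline window), baseline sd
#' (sd of the ROI dF/F trace over the baseline window) and the
#' response-window mean dF/F, plus the increase/decrease/none label from
#' [classify_response()].
#'
#' @param dff 3-D dF/F array from [compute_dff()].
#' @param raw the matching raw `(t, y, x)` movie (for baseline brightness).
#' @param grid a [tile_grid()] matching the movie's spatial size.
#' @param win an [analysis_windows()].
#' @param k classification dead-band width in baseline standard deviations.
#' @param animal_id,fov_id identifiers carried into the output.
#' @return A `roi_trace_set`: a tibble with one row per ROI and columns
#'   `animal_id`, `fov_id`, `roi`, `baseline_brightness`, `baseline_sd`,
#'   `response_stat`, `label` and the list-column `trace`.
#' @export
roi_traces <- function(dff, raw, grid, win = analysis_windows(), k = 2,
                       animal_id = "a1", fov_id = "f1") {
  d <- dim(dff)
  ns_check(identical(dim(raw), d), "raw and dF/F movies differ in shape")
  ns_check(attr(grid, "height") == d[2] && attr(grid, "width") == d[3],
           "tile grid does not match the movie's spatial size")
  nt <- d[1]
  ns_check(win$response[2] <= nt, "response window exceeds the recording")
  valid_px <- attr(dff, "valid_pixels") %||% matrix(TRUE, d[2], d[3])
  Md <- dff; dim(Md) <- c(nt, d[2] * d[3])
  Mr <- raw; dim(Mr) <- c(nt, d[2] * d[3])
  bidx <- win$baseline[1]:win$baseline[2]
  vflat <- as.vector(valid_px)
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    cols <- ns_tile_cols(grid[i, ], d[2])
    cols <- cols[vflat[cols]]
    if (length(cols) == 0L) {
      return(tibble(roi = grid$roi[i], baseline_brightness = NA_real_,
                    baseline_sd = NA_real_, response_stat = NA_real_,
                    trace = list(rep(NA_real_, nt))))
    }
    tr <- rowMeans(Md[, cols, drop = FALSE])
    tibble(roi = grid$roi[i],
           baseline_brightness = mean(Mr[bidx, cols]),
           baseline_sd = sd(tr[bidx]),
           response_stat = window_response(tr, win),
           trace = list(tr))
  }) %>% bind_rows()
  out <- res %>%
    mutate(animal_id = animal_id, fov_id = fov_id,
           label = classify_response(.data$response_stat,
                                     .data$baseline_sd, k = k)) %>%
    select("animal_id", "fov_id", "roi", "baseline_brightness",
           "baseline_sd", "response_stat", "label", "trace")
  structure(out, class = c("roi_trace_set", class(out)),
            windows = win, k = k,
            grid_dims = c(max(grid$row), max(grid$col)))
}

#' Response-window statistic of one trace
#'
#' Arithmetic mean of the dF/F trace over the inclusive response window
#' (frames 89-91 by default).
#'
#' @param trace numeric dF/F trace.
#' @param win an [analysis_windows()].
#' @return A single number.
#' @export
window_response <- function(trace, win = analysis_windows()) {
  ns_check(win$response[2] <= length(trace), "response window outside trace")
  mean(trace[win$response[1]:win$response[2]])
}

#' Classify a ROI response against its baseline variability
#'
#' A ROI is an `increase` if its response statistic exceeds `k` baseline
#' standard deviations, a `decrease` if it falls below `-k` of them, and
#' `none` otherwise. The dead-band width `k` (default 2) is this package's
#' documented choice; a pure sign rule would force increase + decrease to
#' sum to 100%.
#'
#' @param response_stat numeric vector of response-window mean dF/F.
#' @param baseline_sd matching vector of baseline-window trace sd (>= 0).
#' @param k dead-band width in baseline sd units.
#' @return A character vector in `c("increase", "decrease", "none")`.
#' @export
classify_response <- function(response_stat, baseline_sd, k = 2) {
  ns_check(all(baseline_sd >= 0, na.rm = TRUE), "`baseline_sd` must be >= 0")
  case_when(
    is.na(response_stat) | is.na(baseline_sd) ~ NA_character_,
    response_stat > k * baseline_sd ~ "increase",
    response_stat < -k * baseline_sd ~ "decrease",
    .default = "none"
  )
}

#' Fractions of ROI response classes
#'
#' @param labels character vector of ROI labels (or a `roi_trace_set`).
#' @return A one-row tibble with `n_rois`, `pct_increase`, `pct_decrease`,
#'   `pct_none`; the three percentages sum to 100.
#' @export
response_fractions <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- labels[!is.na(labels)]
  ns_check(length(labels) > 0L, "no ROI labels supplied")
  n <- length(labels)
  tibble(n_rois = n,
         pct_increase = 100 * sum(labels == "increase") / n,
         pct_decrease = 100 * sum(labels == "decrease") / n,
         pct_none = 100 * sum(labels == "none") / n)
}

#' Animal-level grand-average trace
#'
#' For each field of view, the `n_brightest` ROIs with the highest raw
#' baseline brightness are selected (avoiding blood-vessel tiles; ties
#' broken by ascending ROI index) and their traces averaged; the per-FOV
#' averages are then averaged again frame-wise into one animal trace.
#'
#' @param fov_sets a list of `roi_trace_set`s (typically 3 FOVs of one
#'   animal), or one pooled `roi_trace_set` which is split by `fov_id`.
#' @param n_brightest ROIs selected per FOV (default 3).
#' @return A tibble with columns `frame` and `dff`.
#' @export
grand_average <- function(fov_sets, n_brightest = 3L) {
  if (is.data.frame(fov_sets)) {
    fov_sets <- split(fov_sets, fov_sets$fov_id)
  }
  ns_check(length(fov_sets) >= 1L, "need at least one FOV")
  fov_traces <- purrr::map(fov_sets, function(s) {
    ok <- !is.na(s$baseline_brightness)
    s <- s[ok, , drop = FALSE]
    ns_check(nrow(s) >= n_brightest,
             "each FOV needs at least ", n_brightest, " ROIs")
    ord <- order(-s$baseline_brightness, s$roi)
    sel <- s$trace[ord[seq_len(n_brightest)]]
    Reduce(`+`, sel) / n_brightest
  })
  gr <- Reduce(`+`, fov_traces) / length(fov_traces)
  tibble(frame = seq_along(gr), dff = gr)
}

#' Run the full dF/F pipeline over a cohort of recordings
#'
#' Convenience wrapper: for every recording it sum-projects over z,
#' optionally applies rigid motion correction, computes baseline-window
#' dF/F, tiles the field of view and extracts per-ROI traces, statistics
#' and labels, then pools everything into one table.
#'
#' @param recordings a list of [twop_recording()]s (e.g. from
#'   [gen_twop_cohort()]).
#' @param win an [analysis_windows()].
#' @param rows,cols ROI grid (default 6x6).
#' @param k classification dead-band width.
#' @param motion_correct apply [rigid_correct()] before dF/F.
#' @param normalization passed to [compute_dff()].
#' @return A pooled `roi_trace_set` tibble (one row per animal x FOV x ROI).
#' @export
twop_analyze <- function(recordings, win = analysis_windows(),
                         rows = 6L, cols = 6L, k = 2,
                         motion_correct = FALSE,
                         normalization = c("pixel", "frame_mean")) {
  normalization <- match.arg(normalization)
  if (inherits(recordings, "twop_recording")) recordings <- list(recordings)
  sets <- purrr::map(recordings, function(rec) {
    raw <- project_z(rec)
    if (motion_correct) raw <- rigid_correct(raw)$movie
    dff <- compute_dff(raw, win, normalization = normalization)
    grid <- tile_grid(dim(raw)[2], dim(raw)[3], rows, cols)
    roi_traces(dff, raw, grid, win, k = k,
               animal_id = rec$animal_id, fov_id = rec$fov_id)
  })
  out <- bind_rows(sets)
  structure(out, class = c("roi_trace_set", class(tibble())),
            windows = win, k = k, grid_dims = c(rows, cols))
}
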
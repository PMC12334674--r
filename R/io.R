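#' Write / read a recording as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered t-major, then z (all slices of frame 1, then frame
#' 2, ...). TIFF samples are stored as 32-bit floats scaled into `[0, 1]`
#' by the movie's maximum; the scale factor and all acquisition metadata
#' (`frame_rate_hz`, `stim_frame`, `pixel_size_um`, ids, dimensions) go
#' into the sidecar JSON, so the round trip is lossless up to float
#' precision.
#'
#' @param rec a [twop_recording()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording_tiff <- function(rec, path) {
  ns_check(inherits(rec, "twop_recording"), "`rec` must be a twop_recording")
  d <- dim(rec$data)
  mx <- max(rec$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- rec$data[t, z, , ] / mx
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(frame_rate_hz = rec$frame_rate_hz, stim_frame = rec$stim_frame,
               pixel_size_um = rec$pixel_size_um, animal_id = rec$animal_id,
               fov_id = rec$fov_id, dims = as.integer(d), scale_max = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_tiff
#' @export
read_recording_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dims
  ns_check(length(pages) == d[1] * d[2],
           "page count does not match the sidecar dimensions")
  a <- array(0, dim = d)
  k <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      a[t, z, , ] <- pages[[k]] * meta$scale_max
    }
  }
  twop_recording(a, frame_rate_hz = meta$frame_rate_hz,
                 stim_frame = meta$stim_frame,
                 pixel_size_um = meta$pixel_size_um,
                 animal_id = meta$animal_id, fov_id = meta$fov_id)
}

#' Write / read a histology image as TIFF
#'
#' Single-page 32-bit float TIFF scaled by the image maximum (recorded in
#' a JSON sidecar together with pixel size, channel and ids).
#'
#' @param img a [histo_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_histo_tiff <- function(img, path) {
  ns_check(inherits(img, "histo_image"), "`img` must be a histo_image")
  mx <- max(img$pixels, 1e-12)
  tiff::writeTIFF(img$pixels / mx, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = img$pixel_size_um, channel = img$channel,
               animal_id = img$animal_id, slice_id = img$slice_id,
               scale_max = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_histo_tiff
#' @export
read_histo_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale_max
  histo_image(px, pixel_size_um = meta$pixel_size_um, channel = meta$channel,
              animal_id = meta$animal_id, slice_id = meta$slice_id)
}

#' Write / read camera-view trajectory CSVs
#'
#' Plain CSV with columns `frame`, `x`, `y` (top view) or `frame`, `x`,
#' `z` (side view), units cm.
#'
#' @param view a camera-view tibble.
#' @param path CSV path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_view_csv <- function(view, path) {
  utils::write.csv(view, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_view_csv
#' @export
read_view_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' Export per-ROI traces as a wide CSV matrix
#'
#' One row per ROI (animal, FOV, ROI index, then one column per frame),
#' the layout used for heat-map export.
#'
#' @param rois a `roi_trace_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(rois, path) {
  tr <- do.call(rbind, rois$trace)
  colnames(tr) <- paste0("frame", seq_len(ncol(tr)))
  out <- cbind(rois[, c("animal_id", "fov_id", "roi")], as.data.frame(tr))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
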
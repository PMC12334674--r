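#' Histology image container
#'
#' A single-channel 2-D intensity image with pixel size, marker name,
#' optional named region masks (e.g. olfactory-bulb layers) and sample
#' identifiers.
#'
#' @param pixels numeric `(y, x)` matrix of intensities.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param channel marker name (e.g. `"NET"`, `"Iba1"`).
#' @param region_masks optional named list of logical matrices matching
#'   `pixels` in shape.
#' @param animal_id,slice_id identifiers.
#' @return An object of class `histo_image`.
#' @export
histo_image <- function(pixels, pixel_size_um = 1, channel = "NET",
                        region_masks = NULL, animal_id = "a1",
                        slice_id = "s1") {
  ns_check(is.matrix(pixels), "`pixels` must be a (y, x) matrix")
  ns_check(pixel_size_um > 0, "`pixel_size_um` must be > 0")
  if (!is.null(region_masks)) {
    ns_check(is.list(region_masks) && !is.null(names(region_masks)),
             "`region_masks` must be a named list")
    for (m in region_masks) {
      ns_check(identical(dim(m), dim(pixels)),
               "region masks must match the image shape")
    }
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel, region_masks = region_masks,
                 animal_id = animal_id, slice_id = slice_id),
            class = "histo_image")
}

#' @export
print.histo_image <- function(x, ...) {
  cat(sprintf("<histo_image> %s %s/%s: %d x %d px @ %.3g um/px, %d region mask(s)\n",
              x$channel, x$animal_id, x$slice_id, nrow(x$pixels),
              ncol(x$pixels), x$pixel_size_um,
              length(x$region_masks %||% list())))
  invisible(x)
}
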
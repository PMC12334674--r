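#' Simulate a fibre-stain image with a planted area fraction
#'
#' Draws random-walk polyline "axon fibres" of a given width onto a dim
#' background until the foreground mask reaches the requested area
#' fraction, then adds Gaussian noise (clipped at zero). The true mask is
#' returned alongside the image, so thresholding pipelines can be checked
#' against a known ground truth. Stroke lengths are chosen adaptively, so
#' the realised mask fraction lands within +-1.5 percentage points of the
#' request (rasterisation tolerance).
#'
#' @param area_fraction target foreground percentage, in `[0, 60]`.
#' @param shape image size `c(height, width)` in pixels (each >= 64).
#' @param fibre_width stroke width in pixels.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param fg,bg mean foreground / background intensities.
#' @param pixel_size_um pixel size carried into the [histo_image()].
#' @param seed integer seed.
#' @param animal_id,slice_id identifiers for the output image.
#' @return A list with `image` (a [histo_image()]) and `mask` (logical
#'   matrix, the true foreground).
#' @export
gen_fiber_image <- function(area_fraction, shape = c(192L, 192L),
                            fibre_width = 2L, noise_sd = 8, fg = 180,
                            bg = 40, pixel_size_um = 0.4, seed = 1L,
                            animal_id = "a1", slice_id = "s1") {
  ns_check(area_fraction >= 0 && area_fraction <= 60,
           "`area_fraction` must be in [0, 60] %")
  ns_check(all(shape >= 64L), "`shape` must be at least 64 x 64")
  ns_check(fibre_width >= 1L, "`fibre_width` must be >= 1 pixel")
  set.seed(ns_substream(seed, 11L))
  h <- shape[1]; w <- shape[2]; npix <- h * w
  target <- round(area_fraction / 100 * npix)
  mask <- matrix(FALSE, h, w)
  brush <- seq_len(fibre_width) - 1L          # square brush offsets
  max_strokes <- 4000L; strokes <- 0L
  while (sum(mask) < target - fibre_width && strokes < max_strokes) {
    strokes <- strokes + 1L
    remaining <- target - sum(mask)
    len <- max(10L, min(200L, ceiling(remaining / fibre_width)))
    ang <- runif(1, 0, 2 * pi)
    pos <- c(runif(1, 1, h), runif(1, 1, w))
    pts <- matrix(0, len, 2L)
    for (s in seq_len(len)) {
      ang <- ang + rnorm(1, 0, 0.25)
      pos <- pos + c(sin(ang), cos(ang))
      pos[1] <- min(max(pos[1], 1), h); pos[2] <- min(max(pos[2], 1), w)
      pts[s, ] <- pos
    }
    yy <- rep(round(pts[, 1]), each = length(brush)^2) +
      rep(rep(brush, length(brush)), len)
    xx <- rep(round(pts[, 2]), each = length(brush)^2) +
      rep(rep(brush, each = length(brush)), len)
    keep <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    idx <- unique((xx[keep] - 1L) * h + yy[keep])
    new_needed <- remaining            # never overshoot past the target
    idx <- idx[!mask[idx]]
    if (length(idx) > new_needed) idx <- idx[seq_len(new_needed)]
    mask[idx] <- TRUE
  }
  ns_check(abs(100 * sum(mask) / npix - area_fraction) <= 1.5,
           sprintf("area fraction %.1f%% unreachable at width %d on a %dx%d image",
                   area_fraction, fibre_width, h, w))
  img <- matrix(bg, h, w); img[mask] <- fg
  if (noise_sd > 0) img <- img + matrix(rnorm(npix, 0, noise_sd), h, w)
  img[img < 0] <- 0
  list(image = histo_image(img, pixel_size_um = pixel_size_um,
                           channel = "NET", animal_id = animal_id,
                           slice_id = slice_id),
       mask = mask)
}

#' Simulate a two-group fibre-density cohort
#'
#' Generates the control and case groups of a fibre-loss study: per-slice
#' true area fractions are drawn `Normal(mean_control, sd_control)` for
#' controls and `Normal(mean_control * case_scale, sd_control)` for cases
#' (truncated at 0.5%), with `n_slices` sections from each of `n_animals`
#' animals per group, and one synthetic fibre image rendered per slice.
#'
#' @param preset a [sim_preset()] such as `preset("fiberloss_2m")`; its
#'   `params` hold `mean_control`, `sd_control`, `case_scale`, `n_animals`,
#'   `n_slices`, `shape`, `fibre_width`, `noise_sd`.
#' @return A tibble with columns `group`, `animal_id`, `slice_id`,
#'   `true_fraction`, and list-columns `image` ([histo_image()]) and
#'   `mask`.
#' @export
gen_fiber_cohort <- function(preset) {
  pp <- modifyList(ns_preset_table()$fiberloss_2m$params, preset$params)
  # all true fractions come from one seeded stream per call
  set.seed(ns_substream(preset$seed, 21L))
  n_per_grp <- pp$n_animals * pp$n_slices
  af_tab <- list(
    control = pmax(0.5, rnorm(n_per_grp, pp$mean_control, pp$sd_control)),
    case = pmax(0.5, rnorm(n_per_grp, pp$mean_control * pp$case_scale,
                           pp$sd_control))
  )
  rows <- list(); k <- 0L
  for (grp in c("control", "case")) {
    for (a in seq_len(pp$n_animals)) {
      for (s in seq_len(pp$n_slices)) {
        k <- k + 1L
        sub <- ns_substream(preset$seed, match(grp, c("control", "case")), a, s)
        af <- af_tab[[grp]][(a - 1L) * pp$n_slices + s]
        fib <- gen_fiber_image(af, shape = pp$shape,
                               fibre_width = pp$fibre_width,
                               noise_sd = pp$noise_sd, seed = sub,
                               animal_id = sprintf("%s%02d", grp, a),
                               slice_id = sprintf("s%d", s))
        rows[[k]] <- tibble(group = grp,
                            animal_id = sprintf("%s%02d", grp, a),
                            slice_id = sprintf("s%d", s),
                            true_fraction = 100 * sum(fib$mask) / prod(pp$shape),
                            image = list(fib$image), mask = list(fib$mask))
      }
    }
  }
  bind_rows(rows)
}
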
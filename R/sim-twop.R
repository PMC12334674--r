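#' Simulate a two-photon sensor-movie cohort with known ROI ground truth
#'
#' Generates `n_animals x n_fovs` raw 4-D recordings emulating odour-evoked
#' neuromodulator-sensor imaging: a textured, strictly positive baseline
#' field with dark vessel patches, a smooth per-slice depth profile, and a
#' per-ROI evoked component — a plateau kernel starting at the stimulus
#' frame — whose amplitude and sign are drawn per ROI from the preset's
#' class probabilities. Pixel noise is multiplicative Gaussian, so the
#' planted amplitude is expressed directly in dF/F units.
#'
#' Per-ROI classes are sampled with probabilities `p_inc` (increase,
#' amplitude `amp_inc`), `p_dec` (decrease, amplitude `amp_dec`) and
#' `1 - p_inc - p_dec` (none, amplitude 0), on the same `rows x cols` tile
#' geometry the analysis uses. The kernel rises linearly over
#' `rise_frames` frames from the stimulus frame, holds at 1 through the
#' response window, and decays afterwards, so the response-window mean of
#' a noiseless ROI equals its planted amplitude exactly.
#'
#' @param preset a [sim_preset()]; see [preset("wt_fig2")][preset] for the
#'   parameter list and defaults.
#' @return A list with `recordings` (list of [twop_recording()]s) and
#'   `truth` (tibble: `animal_id`, `fov_id`, `roi`, `label`, `amplitude`).
#' @examples
#' p <- preset("wt_fig2")
#' p$params[c("n_animals", "n_fovs", "height")] <-
#'   list(1L, 1L, 24L)  # tiny example
#' p$params$width <- 24L
#' cohort <- gen_twop_cohort(p)
#' cohort$truth
#' @export
gen_twop_cohort <- function(preset) {
  pp <- modifyList(ns_preset_table()$wt_fig2$params, preset$params)
  win <- analysis_windows()
  ns_check(pp$n_frames >= win$response[2],
           "frame count must reach the end of the response window")
  ns_check(pp$p_inc + pp$p_dec <= 1, "p_inc + p_dec must not exceed 1")
  ns_check(pp$stim_frame >= 1L && pp$stim_frame <= pp$n_frames,
           "stimulus frame outside the recording")

  kernel <- ns_plateau_kernel(pp$n_frames, pp$stim_frame,
                              hold = win$response[2] - pp$stim_frame + 10L)
  zw <- exp(-((seq_len(pp$n_z) - (pp$n_z + 1) / 2)^2) / (2 * (pp$n_z / 3)^2))
  zw <- zw / sum(zw) * pp$n_z      # per-slice weights, mean 1
  grid <- tile_grid(pp$height, pp$width, pp$rows, pp$cols)

  recordings <- list(); truth <- list()
  for (a in seq_len(pp$n_animals)) {
    for (f in seq_len(pp$n_fovs)) {
      set.seed(ns_substream(preset$seed, a, f))
      n_roi <- nrow(grid)
      cls <- sample(c("increase", "decrease", "none"), n_roi, replace = TRUE,
                    prob = c(pp$p_inc, pp$p_dec, 1 - pp$p_inc - pp$p_dec))
      amp <- ifelse(cls == "increase", pp$amp_inc,
                    ifelse(cls == "decrease", pp$amp_dec, 0))
      base <- ns_baseline_field(pp$height, pp$width,
                                pp$baseline_mean, pp$n_vessels)
      # amplitude map (y, x): each tile carries its ROI's amplitude
      amap <- matrix(0, pp$height, pp$width)
      for (i in seq_len(n_roi)) {
        amap[grid$y0[i]:grid$y1[i], grid$x0[i]:grid$x1[i]] <- amp[i]
      }
      npix <- pp$height * pp$width
      sig <- 1 + outer(kernel, as.vector(amap))       # (t, y*x)
      dat <- array(0, dim = c(pp$n_frames, pp$n_z, pp$height, pp$width))
      bflat <- as.vector(base)
      for (z in seq_len(pp$n_z)) {
        eps <- if (pp$noise_sd > 0) {
          matrix(rnorm(pp$n_frames * npix, 0, pp$noise_sd), pp$n_frames)
        } else 0
        fz <- sig * (1 + eps)
        fz <- sweep(fz, 2L, bflat * zw[z], "*")
        fz[fz < 0] <- 0
        dat[, z, , ] <- fz
      }
      id_a <- sprintf("animal%02d", a); id_f <- sprintf("fov%d", f)
      recordings[[length(recordings) + 1L]] <-
        twop_recording(dat, frame_rate_hz = pp$frame_rate_hz,
                       stim_frame = pp$stim_frame, pixel_size_um = 0.22,
                       animal_id = id_a, fov_id = id_f)
      truth[[length(truth) + 1L]] <-
        tibble(animal_id = id_a, fov_id = id_f, roi = grid$roi,
               label = cls, amplitude = amp)
    }
  }
  list(recordings = recordings, truth = bind_rows(truth))
}

# plateau kernel: 0 before stim, linear rise, hold at 1, linear decay
ns_plateau_kernel <- function(n_frames, stim_frame, rise = 10L, hold = 33L,
                              decay = 30L) {
  k <- numeric(n_frames)
  t_rel <- seq_len(n_frames) - stim_frame    # 0 at stimulus onset
  k[t_rel >= 0 & t_rel < rise] <- (t_rel[t_rel >= 0 & t_rel < rise] + 1) / rise
  k[t_rel >= rise & t_rel < rise + hold] <- 1
  tail_idx <- t_rel >= rise + hold
  k[tail_idx] <- pmax(0, 1 - (t_rel[tail_idx] - rise - hold + 1) / decay)
  k
}

# strictly positive textured baseline with dark vessel disks
ns_baseline_field <- function(h, w, mean_level, n_vessels) {
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  tex <- matrix(1, h, w)
  for (i in seq_len(8L)) {        # smooth blobs -> spatial texture
    cy <- runif(1, 1, h); cx <- runif(1, 1, w); s <- runif(1, h / 8, h / 3)
    tex <- tex + 0.25 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  }
  tex <- tex / mean(tex)
  if (n_vessels > 0) {
    for (i in seq_len(n_vessels)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w); r <- runif(1, 2, h / 15)
      tex[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 0.15 * mean(tex)
    }
  }
  pmax(tex * mean_level, 1e-3)
}
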
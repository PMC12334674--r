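#' Simulate a tracked odour-investigation session
#'
#' Random-walk nose trajectory in a box, with an optional drift toward a
#' fixed odour-tip point (`attraction = 0` gives a pure reflected random
#' walk). The two camera tables returned are exact orthogonal projections
#' of the true trajectory — top view `(frame, x, y)`, side view
#' `(frame, x, z)` — plus optional Gaussian pixel jitter.
#'
#' @param attraction dimensionless drift strength toward the tip (>= 0).
#' @param duration_s session length in seconds.
#' @param fps frame rate in Hz.
#' @param tip odour-tip coordinate `c(x, y, z)` in cm.
#' @param box arena extents `c(x, y, z)` in cm.
#' @param step_sd random-walk step sd per frame, cm.
#' @param jitter_sd camera jitter sd, cm (0 = noiseless projections).
#' @param start optional start position (defaults to the box centre).
#' @param seed integer seed.
#' @return A list with `top`, `side` (camera tibbles) and `truth`
#'   (tibble `frame`, `x`, `y`, `z` — the true 3-D trajectory).
#' @export
gen_behavior_session <- function(attraction = 0, duration_s = 120, fps = 30,
                                 tip = c(5, 5, 5), box = c(40, 25, 20),
                                 step_sd = 0.5, jitter_sd = 0,
                                 start = NULL, seed = 1L) {
  ns_check(fps > 0, "`fps` must be > 0")
  ns_check(attraction >= 0, "`attraction` must be >= 0")
  set.seed(ns_substream(seed, 55L))
  n <- round(duration_s * fps)
  pos <- matrix(0, n, 3L)
  p <- start %||% (box / 2)
  for (t in seq_len(n)) {
    drift <- tip - p
    nd <- sqrt(sum(drift^2))
    if (nd > 1e-9) drift <- drift / nd * attraction * step_sd else drift <- c(0, 0, 0)
    p <- p + drift + rnorm(3, 0, step_sd)
    # reflect at the walls
    for (k in 1:3) {
      if (p[k] < 0) p[k] <- -p[k]
      if (p[k] > box[k]) p[k] <- 2 * box[k] - p[k]
      p[k] <- min(max(p[k], 0), box[k])
    }
    pos[t, ] <- p
  }
  jit <- function(v) if (jitter_sd > 0) v + rnorm(length(v), 0, jitter_sd) else v
  truth <- tibble(frame = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3])
  list(top = tibble(frame = truth$frame, x = jit(truth$x), y = jit(truth$y)),
       side = tibble(frame = truth$frame, x = jit(truth$x), z = jit(truth$z)),
       truth = truth)
}

#' Simulate buried-food latencies for two groups
#'
#' Log-normal latency draws whose population means are `mean_control` for
#' the control group and `mean_control * ratio` for the case group, with
#' a common coefficient of variation (`cv = 0` degenerates to the exact
#' means).
#'
#' @param mean_control control population mean latency, seconds (> 0).
#' @param ratio case-over-control fold change of the mean (> 0).
#' @param n_control,n_case group sizes (>= 2).
#' @param cv coefficient of variation of the latency distribution (>= 0).
#' @param seed integer seed.
#' @return A tibble with `group` (`"control"`/`"case"`), `animal_id`,
#'   `latency_s`.
#' @export
gen_latencies <- function(mean_control = 40, ratio = 1.6, n_control = 14L,
                          n_case = 18L, cv = 0.30, seed = 1L) {
  ns_check(mean_control > 0 && ratio > 0, "means must be > 0")
  ns_check(n_control >= 2L && n_case >= 2L, "group sizes must be >= 2")
  ns_check(cv >= 0, "`cv` must be >= 0")
  set.seed(ns_substream(seed, 77L))
  draw <- function(m, n) {
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  bind_rows(
    tibble(group = "control", animal_id = sprintf("control%02d", seq_len(n_control)),
           latency_s = draw(mean_control, n_control)),
    tibble(group = "case", animal_id = sprintf("case%02d", seq_len(n_case)),
           latency_s = draw(mean_control * ratio, n_case))
  )
}
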
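#' Fuse two orthogonal camera views into a 3-D nose trajectory
#'
#' Combines a top view (`frame`, `x`, `y`) and a side view (`frame`, `x`,
#' `z`) sharing the x axis: the fused x is the mean of the two scaled
#' views, y comes from the top view and z from the side view. Frames seen
#' by only one camera are linearly interpolated in the other and flagged.
#'
#' @param top data frame with columns `frame`, `x`, `y` (top camera).
#' @param side data frame with columns `frame`, `x`, `z` (side camera).
#' @param scale_top,scale_side cm-per-pixel scale of each view (applied
#'   multiplicatively; default 1 = already in cm).
#' @param fps frame rate in Hz.
#' @param tip odour-source (cotton-tip) coordinate `c(x, y, z)` in cm.
#' @param phases optional tibble with `frame`, `phase` labels to join.
#' @return A `behavior_session`: tibble with `frame`, `x`, `y`, `z`,
#'   `interpolated`, and optional `phase`; attributes `fps`, `tip`.
#' @export
fuse_views <- function(top, side, scale_top = 1, scale_side = 1,
                       fps = 30, tip = c(0, 0, 0), phases = NULL) {
  ns_check(all(c("frame", "x", "y") %in% names(top)),
           "`top` needs columns frame, x, y")
  ns_check(all(c("frame", "x", "z") %in% names(side)),
           "`side` needs columns frame, x, z")
  ns_check(fps > 0, "`fps` must be > 0")
  fr <- intersect(top$frame, side$frame)
  ns_check(length(fr) > 0, "camera frame ranges do not overlap")
  all_fr <- seq(min(top$frame, side$frame), max(top$frame, side$frame))
  interp <- function(frames, values, at) {
    stats::approx(frames, values, xout = at, rule = 2)$y
  }
  xt <- interp(top$frame, top$x * scale_top, all_fr)
  yt <- interp(top$frame, top$y * scale_top, all_fr)
  xs <- interp(side$frame, side$x * scale_side, all_fr)
  zs <- interp(side$frame, side$z * scale_side, all_fr)
  out <- tibble(frame = all_fr,
                x = (xt + xs) / 2, y = yt, z = zs,
                interpolated = !(all_fr %in% top$frame) |
                  !(all_fr %in% side$frame))
  if (!is.null(phases)) out <- left_join(out, phases, by = "frame")
  structure(out, class = c("behavior_session", class(out)),
            fps = fps, tip = tip)
}

#' Per-frame distance from nose to odour tip
#'
#' @param session a `behavior_session` from [fuse_views()] (or any tibble
#'   with `x`, `y`, `z` plus a `tip` attribute or explicit `tip`).
#' @param tip optional `c(x, y, z)` overriding the session's tip.
#' @return The session tibble with an added `dist_cm` column.
#' @export
distance_to_tip <- function(session, tip = NULL) {
  tip <- tip %||% attr(session, "tip")
  ns_check(!is.null(tip) && length(tip) == 3L, "odour-tip coordinate not set")
  out <- mutate(session,
                dist_cm = sqrt((.data$x - tip[1])^2 + (.data$y - tip[2])^2 +
                                 (.data$z - tip[3])^2))
  attributes(out)$fps <- attr(session, "fps")
  attributes(out)$tip <- tip
  class(out) <- class(session)
  out
}

ns_dist_vec <- function(x, fps = NULL) {
  if (is.data.frame(x)) {
    ns_check("dist_cm" %in% names(x),
             "run distance_to_tip() first (no `dist_cm` column)")
    list(d = x$dist_cm, fps = attr(x, "fps") %||% fps,
         phase = x[["phase"]])
  } else {
    list(d = x, fps = fps, phase = NULL)
  }
}

#' Time spent in the investigation zone
#'
#' Seconds with the nose strictly closer than `radius` (2 cm by default)
#' to the odour tip: a frame at exactly the radius is outside.
#'
#' @param x a `behavior_session` with a `dist_cm` column, or a bare
#'   distance vector.
#' @param radius zone radius in cm.
#' @param fps frame rate (taken from the session when omitted).
#' @param phase optional phase label(s); only frames in those phases count.
#' @return Seconds in zone.
#' @export
zone_time <- function(x, radius = 2, fps = NULL, phase = NULL) {
  v <- ns_dist_vec(x, fps)
  ns_check(!is.null(v$fps) && v$fps > 0, "`fps` must be supplied and > 0")
  inz <- v$d < radius
  if (!is.null(phase)) {
    ns_check(!is.null(v$phase), "no phase labels on this session")
    inz <- inz & v$phase %in% phase
  }
  sum(inz) / v$fps
}

#' Number of investigation-zone entries
#'
#' Counts outside-to-inside transitions of the nose-tip distance series,
#' merging re-entries separated by fewer than `min_gap` frames outside
#' (debounce). A session that starts inside counts as one entry.
#'
#' @param x a `behavior_session` with `dist_cm`, or a distance vector.
#' @param radius zone radius in cm (strict inequality).
#' @param min_gap minimum number of consecutive outside frames for the
#'   next entry to count as new (default 5; 0 disables debouncing).
#' @return Integer entry count.
#' @export
zone_entries <- function(x, radius = 2, min_gap = 5L) {
  ns_check(min_gap >= 0, "`min_gap` must be >= 0")
  v <- ns_dist_vec(x)
  inz <- v$d < radius
  if (!any(inz)) return(0L)
  r <- rle(inz)
  # drop outside runs shorter than min_gap (except leading/trailing)
  if (min_gap > 0 && length(r$lengths) > 2L) {
    inner <- seq(2L, length(r$lengths) - 1L)
    short <- inner[!r$values[inner] & r$lengths[inner] < min_gap]
    if (length(short)) {
      r$values[short] <- TRUE
      inz <- inverse.rle(r)
      r <- rle(inz)
    }
  }
  sum(r$values)
}

#' Group contrast of buried-food latencies
#'
#' Means with standard errors per group and the percent change of the
#' case group's mean latency over the control's.
#'
#' @param table data frame with columns `group`, `latency_s` (and
#'   typically `animal_id`).
#' @param control,case group labels.
#' @return A one-row tibble: `mean_control`, `sem_control`, `mean_case`,
#'   `sem_case`, `percent_change`.
#' @export
latency_contrast <- function(table, control = "control", case = "case") {
  ns_check(all(c("group", "latency_s") %in% names(table)),
           "`table` needs columns group, latency_s")
  lc <- table$latency_s[table$group == control]
  lk <- table$latency_s[table$group == case]
  ns_check(length(lc) > 0, "control group '", control, "' missing or empty")
  ns_check(length(lk) > 0, "case group '", case, "' missing or empty")
  tibble(mean_control = mean(lc), sem_control = sd(lc) / sqrt(length(lc)),
         mean_case = mean(lk), sem_case = sd(lk) / sqrt(length(lk)),
         percent_change = 100 * (mean(lk) - mean(lc)) / mean(lc))
}

#' Default odour-presentation phase schedule
#'
#' Encodes the sensitivity test's timing: each odour concentration is
#' presented for 2 minutes consecutively with a 1-minute break in
#' between, after an initial baseline.
#'
#' @param fps frame rate in Hz.
#' @param baseline_s initial baseline duration (default 60 s).
#' @param odour_s presentation duration per concentration (default 120 s).
#' @param break_s break between concentrations (default 60 s).
#' @param concentrations labels, low to high.
#' @return A tibble with `frame`, `phase`.
#' @export
phase_schedule <- function(fps = 30, baseline_s = 60, odour_s = 120,
                           break_s = 60,
                           concentrations = c("odour_low", "odour_high")) {
  blocks <- list(c("baseline", baseline_s))
  for (i in seq_along(concentrations)) {
    blocks[[length(blocks) + 1L]] <- c(concentrations[i], odour_s)
    if (i < length(concentrations)) {
      blocks[[length(blocks) + 1L]] <- c("break", break_s)
    }
  }
  phases <- unlist(lapply(blocks, function(b) {
    rep(b[1], round(as.numeric(b[2]) * fps))
  }))
  tibble(frame = seq_along(phases), phase = phases)
}
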
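test_that("noiseless projections fuse back to the true trajectory", {
  g <- gen_behavior_session(attraction = 0, duration_s = 10, fps = 20,
                            jitter_sd = 0, seed = 3)
  s <- fuse_views(g$top, g$side, fps = 20, tip = c(5, 5, 5))
  expect_equal(s$x, g$truth$x, tolerance = 1e-12)
  expect_equal(s$y, g$truth$y, tolerance = 1e-12)
  expect_equal(s$z, g$truth$z, tolerance = 1e-12)
  expect_false(any(s$interpolated))
})

test_that("fused x is the midpoint when views disagree", {
  top <- tibble::tibble(frame = 1:5, x = rep(10, 5), y = 1:5)
  side <- tibble::tibble(frame = 1:5, x = rep(12, 5), z = 5:1)
  s <- fuse_views(top, side, fps = 10)
  expect_equal(s$x, rep(11, 5))
})

test_that("frames missing from one view are interpolated and flagged", {
  top <- tibble::tibble(frame = 1:10, x = 1:10, y = rep(2, 10))
  side <- tibble::tibble(frame = c(1:4, 7:10), x = c(1:4, 7:10),
                         z = rep(3, 8))
  s <- fuse_views(top, side, fps = 10)
  expect_equal(nrow(s), 10)
  expect_true(all(s$interpolated[5:6]))
  expect_equal(s$x[5:6], c(5, 6))   # linear interpolation on the shared axis
  expect_error(fuse_views(top, dplyr::mutate(side, frame = frame + 100),
                          fps = 10), "overlap")
})

test_that("jittered fusion lands closer to truth than the jitter itself", {
  g <- gen_behavior_session(duration_s = 60, fps = 30, jitter_sd = 0.4,
                            seed = 9)
  s <- fuse_views(g$top, g$side, fps = 30, tip = c(5, 5, 5))
  rmse_x <- sqrt(mean((s$x - g$truth$x)^2))
  expect_lt(rmse_x, 0.4)   # x averages two views, so its error shrinks
})

test_that("nose-tip distance is plain 3-D Euclidean distance", {
  s <- structure(tibble::tibble(frame = 1:3,
                                x = c(5, 8, 2), y = c(5, 5, 3), z = c(5, 5, 1)),
                 class = c("behavior_session", class(tibble::tibble())),
                 fps = 10, tip = c(5, 5, 5))
  d <- distance_to_tip(s)
  expect_equal(d$dist_cm[1], 0)
  expect_equal(d$dist_cm[2], 3)
  expect_equal(d$dist_cm[3], sqrt(9 + 4 + 16))
})

test_that("zone time counts strict sub-radius frames over fps", {
  expect_equal(zone_time(rep(1, 300), radius = 2, fps = 30), 10)
  expect_equal(zone_time(rep(5, 300), radius = 2, fps = 30), 0)
  # a frame at exactly the radius is outside
  expect_equal(zone_time(c(2, 2, 1.99), radius = 2, fps = 1), 1)
  set.seed(14)
  d <- runif(500, 0, 6)
  n <- 0L; for (v in d) if (v < 2) n <- n + 1L
  expect_equal(zone_time(d, radius = 2, fps = 25), n / 25)
})

test_that("zone time plus out-of-zone time is the phase duration", {
  set.seed(15)
  d <- runif(400, 0, 5)
  fps <- 20
  inz <- zone_time(d, fps = fps)
  out <- sum(d >= 2) / fps
  expect_equal(inz + out, length(d) / fps)
})

test_that("zone entries count debounced outside-to-inside transitions", {
  expect_equal(zone_entries(c(3, 1, 3, 1, 3), min_gap = 0), 2)
  expect_equal(zone_entries(rep(1, 50)), 1)
  expect_equal(zone_entries(rep(5, 50)), 0)
  # a 2-frame excursion out is merged at min_gap 5 but kept at min_gap 0
  d <- c(5, 1, 1, 5, 5, 1, 1)
  expect_equal(zone_entries(d, min_gap = 0), 2)
  expect_equal(zone_entries(d, min_gap = 5), 1)
  # transition-count oracle at min_gap 0
  set.seed(16)
  d <- runif(300, 0, 4)
  inz <- d < 2
  oracle <- sum(diff(c(FALSE, inz)) == 1)
  expect_equal(zone_entries(d, min_gap = 0), oracle)
  # increasing the gap never increases the count
  for (gap in c(1, 3, 8, 20)) {
    expect_lte(zone_entries(d, min_gap = gap),
               zone_entries(d, min_gap = 0))
  }
})

test_that("attraction to the tip increases zone occupancy (paired seeds)", {
  diffs <- sapply(1:20, function(sd_) {
    tip <- c(5, 5, 5)
    g0 <- gen_behavior_session(attraction = 0, duration_s = 30, fps = 10,
                               tip = tip, seed = sd_)
    g1 <- gen_behavior_session(attraction = 3, duration_s = 30, fps = 10,
                               tip = tip, seed = sd_)
    zt <- function(g) {
      s <- distance_to_tip(fuse_views(g$top, g$side, fps = 10, tip = tip))
      zone_time(s)
    }
    zt(g1) - zt(g0)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.6)
})

test_that("latency contrast reports the percent change of group means", {
  tab <- tibble::tibble(group = rep(c("control", "case"), c(3, 2)),
                        latency_s = c(40, 40, 40, 64, 64))
  ct <- latency_contrast(tab)
  expect_equal(ct$percent_change, 60)
  expect_equal(latency_contrast(tibble::tibble(
    group = c("control", "case"), latency_s = c(33, 33)))$percent_change, 0)
  set.seed(17)
  tab2 <- tibble::tibble(group = sample(c("control", "case"), 30, TRUE),
                         latency_s = runif(30, 20, 90))
  ct2 <- latency_contrast(tab2)
  mc <- mean(tab2$latency_s[tab2$group == "control"])
  mk <- mean(tab2$latency_s[tab2$group == "case"])
  expect_equal(ct2$percent_change, 100 * (mk - mc) / mc)
  expect_error(latency_contrast(tab, case = "missing"), "missing")
})

test_that("latency generator plants the mean ratio and is seed-deterministic", {
  g <- gen_latencies(cv = 0, seed = 1)
  expect_true(all(g$latency_s[g$group == "control"] == 40))
  expect_true(all(g$latency_s[g$group == "case"] == 64))

  # ratio = 1 -> percent change shrinks with n (population identity)
  big <- gen_latencies(ratio = 1, n_control = 10000L, n_case = 10000L,
                       cv = 0.3, seed = 2)
  expect_lt(abs(latency_contrast(big)$percent_change), 2)

  expect_identical(gen_latencies(seed = 5), gen_latencies(seed = 5))
})

test_that("phase schedule encodes 2-min presentations with 1-min breaks", {
  ps <- phase_schedule(fps = 10)
  r <- rle(ps$phase)
  expect_equal(r$values, c("baseline", "odour_low", "break", "odour_high"))
  expect_equal(r$lengths / 10, c(60, 120, 60, 120))
  # phase-restricted zone time only counts matching frames
  d <- rep(1, nrow(ps))
  s <- structure(tibble::tibble(frame = ps$frame, dist_cm = d,
                                phase = ps$phase),
                 class = c("behavior_session", class(tibble::tibble())),
                 fps = 10)
  expect_equal(zone_time(s, phase = "odour_low"), 120)
})
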
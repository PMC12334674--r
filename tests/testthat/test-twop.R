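test_that("z-projection sums all slices and matches a per-pixel loop", {
  a <- array(1, dim = c(4, 3, 5, 6))
  expect_equal(project_z(a), array(3, dim = c(4, 5, 6)))

  a1 <- array(runif(4 * 1 * 5 * 6), dim = c(4, 1, 5, 6))
  expect_equal(project_z(a1), array(a1[, 1, , ], dim = c(4, 5, 6)))

  set.seed(3)
  ar <- array(runif(5 * 4 * 6 * 7), dim = c(5, 4, 6, 7))
  oracle <- array(0, dim = c(5, 6, 7))
  for (t in 1:5) for (y in 1:6) for (x in 1:7) {
    oracle[t, y, x] <- sum(ar[t, , y, x])
  }
  expect_equal(project_z(ar), oracle)
})

test_that("rigid correction recovers planted shifts and is identity at max_shift 0", {
  set.seed(11)
  ref <- matrix(runif(48 * 40), 48, 40)
  mov <- array(0, dim = c(6, 48, 40))
  for (t in 1:6) mov[t, , ] <- ref
  rc <- rigid_correct(mov, max_shift = 4)
  expect_true(all(rc$shifts$dy == 0) && all(rc$shifts$dx == 0))

  # every frame after the first displaced by (2, -1): a first-frame
  # reference recovers it (a mean reference would absorb a shared shift)
  for (t in 2:6) mov[t, , ] <- noradscope:::ns_shift_matrix(ref, 2, -1)
  rc <- rigid_correct(mov, max_shift = 4, reference = "first")
  expect_equal(rc$shifts$dy[2:6], rep(2, 5))
  expect_equal(rc$shifts$dx[2:6], rep(-1, 5))

  # a minority of displaced frames is recovered against the temporal mean
  mov2 <- array(0, dim = c(8, 48, 40))
  for (t in 1:8) mov2[t, , ] <- ref
  mov2[4, , ] <- noradscope:::ns_shift_matrix(ref, 2, -1)
  rcm <- rigid_correct(mov2, max_shift = 4)
  expect_equal(c(rcm$shifts$dy[4], rcm$shifts$dx[4]), c(2, -1))
  # and correction restores the frame in the unpadded interior
  expect_equal(rcm$movie[4, 5:44, 5:36], ref[5:44, 5:36], tolerance = 1e-12)

  rc0 <- rigid_correct(mov, max_shift = 0)
  expect_identical(rc0$movie, mov)
})

test_that("dF/F matches arithmetic and a per-pixel loop oracle", {
  win <- analysis_windows(baseline = c(2, 4), response = c(6, 7),
                          stim_frame = 5, drop_first = 1)
  # F0 = 100, frame value 110 -> 0.10
  m <- array(100, dim = c(8, 1, 1)); m[6, 1, 1] <- 110
  expect_equal(compute_dff(m, win)[6, 1, 1], 0.10)

  const <- array(77, dim = c(8, 3, 3))
  expect_true(all(compute_dff(const, win) == 0))

  mv <- random_movie(95, 7, 6, seed = 5)
  win2 <- analysis_windows()
  expect_equal(
    as.vector(compute_dff(mv, win2)),
    as.vector(loop_dff(mv, win2$baseline)),
    tolerance = 1e-12
  )
})

test_that("dF/F flags the first frames but keeps them, and floors dead pixels", {
  mv <- random_movie(95, 6, 6, seed = 8)
  dff <- compute_dff(mv, analysis_windows())
  vf <- attr(dff, "valid_frames")
  expect_length(vf, 95)
  expect_false(any(vf[1:19]))
  expect_true(all(vf[20:95]))

  mv[, 2, 3] <- 0   # dead pixel
  dff <- compute_dff(mv, analysis_windows())
  expect_false(attr(dff, "valid_pixels")[2, 3])
  expect_error(compute_dff(mv, analysis_windows(), on_low_f0 = "error"),
               "1 pixel")
})

test_that("frame-mean normalization uses one scalar F0", {
  mv <- random_movie(95, 6, 6, seed = 9)
  dff <- compute_dff(mv, normalization = "frame_mean")
  f0 <- mean(rowMeans(matrix(mv, 95))[20:67])
  expect_equal(dff[50, 3, 4], (mv[50, 3, 4] - f0) / f0)
})

test_that("long-recording mode equals dF/F with the alternate baseline", {
  mv <- random_movie(320, 5, 5, seed = 10)
  expect_equal(
    as.vector(long_mode_dff(mv)),
    as.vector(loop_dff(mv, c(20, 300))),
    tolerance = 1e-12
  )
  const <- array(5, dim = c(320, 4, 4))
  expect_true(all(long_mode_dff(const) == 0))
})

test_that("tile grid partitions the image for even, standard and ragged sizes", {
  g <- tile_grid(12, 12)
  expect_equal(nrow(g), 36)
  expect_true(all(g$y1 - g$y0 == 1) && all(g$x1 - g$x0 == 1))

  g <- tile_grid(120, 120)
  expect_equal(nrow(g), 36)
  expect_true(all(g$y1 - g$y0 == 19) && all(g$x1 - g$x0 == 19))

  g <- tile_grid(13, 12)
  heights <- (g$y1 - g$y0 + 1)[g$col == 1]
  expect_equal(heights, c(3, 2, 2, 2, 2, 2))

  # partition property over several shapes: each pixel in exactly one tile
  for (hw in list(c(13, 12), c(17, 23), c(6, 6), c(120, 120))) {
    g <- tile_grid(hw[1], hw[2])
    cover <- matrix(0L, hw[1], hw[2])
    for (i in seq_len(nrow(g))) {
      cover[g$y0[i]:g$y1[i], g$x0[i]:g$x1[i]] <-
        cover[g$y0[i]:g$y1[i], g$x0[i]:g$x1[i]] + 1L
    }
    expect_true(all(cover == 1L))
  }
  expect_error(tile_grid(5, 12), "grid larger")
})

test_that("ROI traces are tile means of dF/F (loop oracle)", {
  mv <- random_movie(95, 13, 12, seed = 12)
  win <- analysis_windows()
  dff <- compute_dff(mv, win)
  grid <- tile_grid(13, 12)
  rois <- roi_traces(dff, mv, grid, win)
  expect_equal(nrow(rois), 36)
  for (i in c(1, 7, 36)) {
    ys <- grid$y0[i]:grid$y1[i]; xs <- grid$x0[i]:grid$x1[i]
    oracle <- sapply(seq_len(95), function(t) mean(dff[t, ys, xs]))
    expect_equal(rois$trace[[i]], oracle, tolerance = 1e-12)
    expect_equal(rois$baseline_brightness[i], mean(mv[20:67, ys, xs]))
    expect_equal(rois$response_stat[i], mean(oracle[89:91]))
  }
  # zero movie -> zero traces and stats
  z <- array(0, dim = c(95, 12, 12))
  attr(z, "valid_pixels") <- matrix(TRUE, 12, 12)
  rz <- roi_traces(z, array(1, dim = c(95, 12, 12)), tile_grid(12, 12), win)
  expect_true(all(sapply(rz$trace, function(tr) all(tr == 0))))
  expect_true(all(rz$response_stat == 0))
})

test_that("window response is the inclusive 3-frame mean", {
  tr <- numeric(95); tr[89:91] <- c(0.03, 0.04, 0.05)
  expect_equal(window_response(tr), mean(c(0.03, 0.04, 0.05)))
  expect_equal(window_response(rep(0.7, 95)), 0.7)
  set.seed(4); tr <- rnorm(95)
  expect_equal(window_response(tr), sum(tr[89:91]) / 3)
  expect_error(window_response(rnorm(50)), "outside")
})

test_that("classification applies a k-sd dead band", {
  expect_equal(classify_response(3, 1), "increase")
  expect_equal(classify_response(-3, 1), "decrease")
  expect_equal(classify_response(0.5, 1), "none")
  expect_equal(classify_response(c(3, -3, 0.5), c(1, 1, 1)),
               c("increase", "decrease", "none"))
  # k is configurable: same statistic, wider band -> none
  expect_equal(classify_response(3, 1, k = 4), "none")
})

test_that("response fractions count labels and sum to 100", {
  labs <- c(rep("increase", 27), rep("none", 9))
  fr <- response_fractions(labs)
  expect_equal(fr$pct_increase, 75)
  expect_equal(fr$pct_decrease, 0)

  fr <- response_fractions(rep("none", 10))
  expect_equal(c(fr$pct_increase, fr$pct_decrease, fr$pct_none), c(0, 0, 100))

  set.seed(21)
  labs <- sample(c("increase", "decrease", "none"), 101, replace = TRUE)
  fr <- response_fractions(labs)
  expect_equal(fr$pct_increase, 100 * sum(labs == "increase") / 101)
  expect_equal(fr$pct_increase + fr$pct_decrease + fr$pct_none, 100,
               tolerance = 1e-9)
  expect_error(response_fractions(character(0)), "no ROI")
})

test_that("grand average picks the 3 brightest ROIs per FOV then averages FOVs", {
  mk_set <- function(fov, brightness, traces) {
    tibble::tibble(animal_id = "a1", fov_id = fov,
                   roi = seq_along(brightness),
                   baseline_brightness = brightness,
                   baseline_sd = 0, response_stat = 0, label = "none",
                   trace = traces)
  }
  # one FOV, 3 ROIs with constant traces 1, 2, 3 -> constant 2
  s1 <- mk_set("f1", c(5, 6, 7), list(rep(1, 10), rep(2, 10), rep(3, 10)))
  ga <- grand_average(list(s1))
  expect_equal(ga$dff, rep(2, 10))

  # identical traces everywhere -> that trace
  tr <- sin(seq_len(10))
  s2 <- mk_set("f1", c(1, 2, 3, 4), replicate(4, tr, simplify = FALSE))
  expect_equal(grand_average(list(s2))$dff, tr)

  # random case vs explicit sort-select-average oracle over 2 FOVs
  set.seed(33)
  br1 <- runif(6); br2 <- runif(6)
  tr1 <- replicate(6, rnorm(10), simplify = FALSE)
  tr2 <- replicate(6, rnorm(10), simplify = FALSE)
  ga <- grand_average(list(mk_set("f1", br1, tr1), mk_set("f2", br2, tr2)))
  pick <- function(br, trs) {
    sel <- order(-br)[1:3]
    Reduce(`+`, trs[sel]) / 3
  }
  expect_equal(ga$dff, (pick(br1, tr1) + pick(br2, tr2)) / 2)

  # ties broken by ascending ROI index
  s3 <- mk_set("f1", c(1, 1, 1, 1), list(rep(1, 5), rep(2, 5), rep(3, 5), rep(100, 5)))
  expect_equal(grand_average(list(s3))$dff, rep(2, 5))

  expect_error(grand_average(list(mk_set("f1", c(1, 2), list(1:5, 1:5)))),
               "at least 3")
})

test_that("pipeline output is invariant to positive rescaling of the raw movie", {
  p <- tiny_twop_preset()
  co <- gen_twop_cohort(p)
  rois1 <- twop_analyze(co$recordings)
  rec2 <- co$recordings[[1]]
  rec2$data <- rec2$data * 3.7
  rois2 <- twop_analyze(list(rec2))
  expect_equal(rois1$response_stat, rois2$response_stat, tolerance = 1e-12)
  expect_equal(rois1$label, rois2$label)
  expect_equal(do.call(rbind, rois1$trace), do.call(rbind, rois2$trace),
               tolerance = 1e-12)
})
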
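# shared fixture builders; everything is generated in code at test time

# a wt_fig2-style preset shrunk to one tiny FOV for fast unit tests
tiny_twop_preset <- function(seed = 42L, ...) {
  p <- preset("wt_fig2", seed = seed)
  p$params <- utils::modifyList(
    p$params,
    list(n_animals = 1L, n_fovs = 1L, height = 36L, width = 36L, n_z = 3L)
  )
  p$params <- utils::modifyList(p$params, list(...))
  p
}

# deterministic random (t, y, x) movie with strictly positive baseline
random_movie <- function(nt = 95L, h = 12L, w = 12L, seed = 1L) {
  set.seed(seed)
  array(runif(nt * h * w, 50, 150), dim = c(nt, h, w))
}

# brute-force per-pixel dF/F oracle (triple loop, no vectorisation)
loop_dff <- function(movie, baseline) {
  d <- dim(movie)
  out <- array(NA_real_, d)
  for (y in seq_len(d[2])) {
    for (x in seq_len(d[3])) {
      f0 <- mean(movie[baseline[1]:baseline[2], y, x])
      for (t in seq_len(d[1])) out[t, y, x] <- (movie[t, y, x] - f0) / f0
    }
  }
  out
}

# random 3-D logical mask
random_mask3 <- function(d = c(8L, 9L, 10L), p = 0.3, seed = 1L) {
  set.seed(seed)
  array(runif(prod(d)) < p, dim = d)
}
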
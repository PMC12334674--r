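vox1 <- c(1, 1, 1)

test_that("segmentation recovers a bright sphere's analytic volume", {
  d <- c(24L, 24L, 24L); r <- 6
  zz <- array(rep(1:24, times = 24 * 24), d)
  yy <- array(rep(rep(1:24, each = 24), times = 24), d)
  xx <- array(rep(1:24, each = 24 * 24), d)
  raw <- ifelse((zz - 12)^2 + (yy - 12)^2 + (xx - 12)^2 <= r^2, 200, 10)
  set.seed(1); raw <- raw + array(rnorm(prod(d), 0, 5), d)
  mask <- segment_volume(raw, voxel_size_um = vox1)
  expect_lt(abs(sum(mask) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.10)

  # min_object bigger than everything -> empty
  mask2 <- segment_volume(raw, min_object_um3 = 1e6, voxel_size_um = vox1)
  expect_false(any(mask2))

  # exact separation of a two-level volume
  two <- array(10, d); two[1:5, 1:5, 1:5] <- 200
  expect_equal(sum(segment_volume(two, voxel_size_um = vox1)), 125)
  expect_error(segment_volume(array(1, c(4, 4, 4))), "constant")
})

test_that("colocalised volume matches brute-force voxel counts", {
  a <- array(FALSE, c(6, 6, 6)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[5:6, , ] <- TRUE
  expect_equal(coloc_volume(a, b, vox1)$volume_um3, 0)

  sub <- array(FALSE, c(6, 6, 6)); sub[1:2, 1:2, 1:2] <- TRUE
  res <- coloc_volume(sub, a, vox1)
  expect_equal(res$volume_um3, sum(sub))
  expect_equal(res$pct_of_a, 100)

  ra <- random_mask3(seed = 2); rb <- random_mask3(seed = 3)
  n <- 0L
  for (i in seq_along(ra)) if (ra[i] && rb[i]) n <- n + 1L
  vox <- c(0.5, 0.25, 0.25)
  expect_equal(coloc_volume(ra, rb, vox)$volume_um3, n * prod(vox))
  expect_error(coloc_volume(ra, array(TRUE, c(2, 2, 2)), vox1), "shape")
})

test_that("colocalisation is symmetric and monotone in mask growth", {
  ra <- random_mask3(seed = 4); rb <- random_mask3(seed = 5)
  expect_equal(coloc_volume(ra, rb, vox1)$volume_um3,
               coloc_volume(rb, ra, vox1)$volume_um3)
  rb_big <- rb | random_mask3(seed = 6)
  expect_gte(coloc_volume(ra, rb_big, vox1)$volume_um3,
             coloc_volume(ra, rb, vox1)$volume_um3)
})

test_that("engulfed volume is the triple intersection", {
  empty <- array(FALSE, c(6, 6, 6))
  any1 <- random_mask3(c(6L, 6L, 6L), seed = 7)
  expect_equal(engulfed_volume(empty, any1, any1, vox1), 0)

  cell <- array(FALSE, c(10, 10, 10)); cell[2:9, 2:9, 2:9] <- TRUE
  lyso <- array(FALSE, c(10, 10, 10)); lyso[4:7, 4:7, 4:7] <- TRUE
  tube <- array(FALSE, c(10, 10, 10)); tube[5:6, 5:6, 5:6] <- TRUE
  expect_equal(engulfed_volume(tube, lyso, cell, vox1), sum(tube))

  m1 <- random_mask3(seed = 8); m2 <- random_mask3(seed = 9)
  m3 <- random_mask3(seed = 10)
  expect_equal(engulfed_volume(m1, m2, m3, vox1), sum(m1 & m2 & m3))
})

test_that("contact volume reduces to colocalisation at zero dilation", {
  ra <- random_mask3(seed = 11); rb <- random_mask3(seed = 12)
  expect_equal(contact_volume(ra, rb, dilation_um = 0, vox1)$volume_um3,
               coloc_volume(ra, rb, vox1)$volume_um3)
})

test_that("contact volume counts the hand-enumerated interface shell", {
  # two touching cuboids in a 10^3 volume, 1-voxel dilation
  a <- array(FALSE, c(10, 10, 10)); a[, , 1:4] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[, , 5:8] <- TRUE
  res <- contact_volume(a, b, dilation_um = 1, vox1)
  # dilate(a) reaches x-slab 5 only; minus direct overlap (none) -> 100 voxels
  expect_equal(res$volume_um3, 100)
  expect_equal(res$n_contacts, 1)

  # masks separated by more than the dilation -> 0
  far <- array(FALSE, c(10, 10, 10)); far[, , 9:10] <- TRUE
  expect_equal(contact_volume(a, far, dilation_um = 1, vox1)$volume_um3, 0)
})

test_that("density normalisation is volume over NET fraction", {
  expect_equal(normalize_to_density(5, 10, 100), 50)
  expect_equal(normalize_to_density(7.7, 100, 100), 7.7)
  set.seed(13)
  v <- runif(1, 1, 10); nv <- runif(1, 5, 20); tv <- runif(1, 50, 100)
  expect_equal(normalize_to_density(v, nv, tv), v / (nv / tv))
  expect_error(normalize_to_density(5, 0, 100), "NET")
})

test_that("generated volumes store truth equal to an independent recount", {
  g <- gen_coloc_volumes(list(shape = c(24L, 28L, 28L)), seed = 3)
  m <- g$volumes$masks
  vv <- prod(g$volumes$voxel_size_um)
  for (pr in g$truth$pair[g$truth$pair != "net:cd68:iba1"]) {
    nm <- strsplit(pr, ":")[[1]]
    expect_equal(g$truth$volume_um3[g$truth$pair == pr],
                 sum(m[[nm[1]]] & m[[nm[2]]]) * vv)
  }
  expect_equal(g$truth$volume_um3[g$truth$pair == "net:cd68:iba1"],
               engulfed_volume(m$net, m$cd68, m$iba1, g$volumes$voxel_size_um))
  # lysosomes are nested: cd68 within iba1 entirely
  expect_equal(sum(m$cd68 & m$iba1), sum(m$cd68))
  # determinism
  g2 <- gen_coloc_volumes(list(shape = c(24L, 28L, 28L)), seed = 3)
  expect_identical(g$volumes$masks, g2$volumes$masks)
  # impossible nesting rejected
  expect_error(gen_coloc_volumes(list(lyso_radius_um = 10, cell_radius_um = 4)),
               "parent")
})
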
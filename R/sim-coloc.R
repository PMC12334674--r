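#' Simulate labelled 3-D marker volumes with known intersections
#'
#' Builds a co-registered set of binary 3-D channels emulating an
#' engulfment imaging field: spherical microglia somata (`iba1`),
#' lysosome spheres planted strictly inside them (`cd68`), random-walk
#' axon tubes (`net`) threaded through the volume, and an auxiliary
#' marker (`aux`, e.g. an eat-me signal) as small blobs seeded on the
#' axons. The returned ground truth is obtained by brute-force voxel
#' recount of every pairwise intersection plus the triple
#' `net & cd68 & iba1`, so any downstream measurement can be checked
#' exactly.
#'
#' @param params named list overriding the defaults: `shape` (voxels,
#'   `c(z, y, x)`), `voxel_size_um` `(dz, dy, dx)`, `n_cells`,
#'   `cell_radius_um`, `n_lyso_per_cell`, `lyso_radius_um`, `n_tubes`,
#'   `tube_radius_um`, `n_aux`, `aux_radius_um`.
#' @param seed integer seed.
#' @return A list with `volumes` (a [coloc_volumes()]) and `truth`
#'   (tibble: `pair`, `volume_um3`).
#' @export
gen_coloc_volumes <- function(params = list(), seed = 1L) {
  pp <- modifyList(list(
    shape = c(40L, 48L, 48L), voxel_size_um = c(0.5, 0.5, 0.5),
    n_cells = 3L, cell_radius_um = 4, n_lyso_per_cell = 2L,
    lyso_radius_um = 1.2, n_tubes = 4L, tube_radius_um = 0.6,
    n_aux = 6L, aux_radius_um = 0.8
  ), params)
  ns_check(pp$lyso_radius_um < pp$cell_radius_um,
           "requested lysosome cannot exceed its parent cell: ",
           "intersection would be larger than the smaller parent")
  set.seed(ns_substream(seed, 33L))
  d <- pp$shape; vs <- pp$voxel_size_um
  zz <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d) * vs[1]
  yy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d) * vs[2]
  xx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d) * vs[3]
  sphere <- function(c_um, r_um) {
    (zz - c_um[1])^2 + (yy - c_um[2])^2 + (xx - c_um[3])^2 <= r_um^2
  }
  ext <- d * vs
  iba1 <- array(FALSE, d); cd68 <- array(FALSE, d)
  centres <- list()
  for (i in seq_len(pp$n_cells)) {
    ctr <- c(runif(1, pp$cell_radius_um, ext[1] - pp$cell_radius_um),
             runif(1, pp$cell_radius_um, ext[2] - pp$cell_radius_um),
             runif(1, pp$cell_radius_um, ext[3] - pp$cell_radius_um))
    centres[[i]] <- ctr
    iba1 <- iba1 | sphere(ctr, pp$cell_radius_um)
    for (j in seq_len(pp$n_lyso_per_cell)) {
      # lysosome centre kept inside the soma so the nesting is exact
      off <- stats::rnorm(3); off <- off / sqrt(sum(off^2)) *
        runif(1, 0, pp$cell_radius_um - pp$lyso_radius_um)
      cd68 <- cd68 | sphere(ctr + off, pp$lyso_radius_um)
    }
  }
  net <- array(FALSE, d)
  tube_pts <- NULL
  for (i in seq_len(pp$n_tubes)) {
    pos <- c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), runif(1, 0, ext[3]))
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (s in seq_len(80L)) {
      dir <- dir + stats::rnorm(3, 0, 0.15); dir <- dir / sqrt(sum(dir^2))
      pos <- pmin(pmax(pos + dir * 0.5, 0), ext)
      net <- net | sphere(pos, pp$tube_radius_um)
      tube_pts <- rbind(tube_pts, pos)
    }
  }
  aux <- array(FALSE, d)
  if (pp$n_aux > 0 && !is.null(tube_pts)) {
    picks <- sample(nrow(tube_pts), min(pp$n_aux, nrow(tube_pts)))
    for (i in picks) aux <- aux | sphere(tube_pts[i, ], pp$aux_radius_um)
  }
  masks <- list(net = net, iba1 = iba1, cd68 = cd68, aux = aux)
  vols <- coloc_volumes(masks, vs)
  vv <- prod(vs)
  pairs <- utils::combn(names(masks), 2L)
  truth <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(pair = paste(a, b, sep = ":"),
           volume_um3 = sum(masks[[a]] & masks[[b]]) * vv)
  }) %>% bind_rows()
  truth <- bind_rows(truth, tibble(
    pair = "net:cd68:iba1",
    volume_um3 = sum(net & cd68 & iba1) * vv
  ))
  list(volumes = vols, truth = truth)
}
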
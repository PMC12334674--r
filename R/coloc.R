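#' Co-registered 3-D marker masks
#'
#' Named binary volumes `(z, y, x)` for a set of markers (e.g. NET axons,
#' Iba1 microglia, CD68 lysosomes) sharing one voxel geometry.
#'
#' @param masks named list of logical/0-1 3-D arrays, all the same shape.
#' @param voxel_size_um voxel edge lengths `c(dz, dy, dx)` in micrometres.
#' @return An object of class `coloc_volumes`.
#' @export
coloc_volumes <- function(masks, voxel_size_um = c(0.5, 0.5, 0.5)) {
  ns_check(is.list(masks) && length(masks) > 0 && !is.null(names(masks)),
           "`masks` must be a non-empty named list")
  shp <- dim(masks[[1]])
  ns_check(length(shp) == 3L, "masks must be 3-D (z, y, x) arrays")
  for (m in masks) ns_check(identical(dim(m), shp), "all masks must share one shape")
  ns_check(all(voxel_size_um > 0) && length(voxel_size_um) == 3L,
           "`voxel_size_um` must be three positive lengths (dz, dy, dx)")
  masks <- lapply(masks, function(m) { storage.mode(m) <- "logical"; m })
  structure(list(masks = masks, voxel_size_um = voxel_size_um),
            class = "coloc_volumes")
}

#' @export
print.coloc_volumes <- function(x, ...) {
  shp <- dim(x$masks[[1]])
  cat(sprintf("<coloc_volumes> %s: %d x %d x %d voxels @ (%.2f, %.2f, %.2f) um\n",
              paste(names(x$masks), collapse = ", "), shp[1], shp[2], shp[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

ns_voxvol <- function(voxel_size_um) prod(voxel_size_um)

# zero-padded integer shift of a 3-D logical array
ns_shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- function(n, s) {
    i0 <- max(1L, 1L - s); i1 <- min(n, n - s)
    if (i0 > i1) integer(0) else i0:i1
  }
  zi <- src(d[1], dz); yi <- src(d[2], dy); xi <- src(d[3], dx)
  if (!length(zi) || !length(yi) || !length(xi)) return(out)
  out[zi + dz, yi + dy, xi + dx] <- a[zi, yi, xi]
  out
}

# 26-connected component labels of a 3-D logical array (igraph backend)
ns_label3d <- function(mask) {
  idx <- which(mask)
  lab <- array(0L, dim(mask))
  if (!length(idx)) return(lab)
  rank <- array(0L, dim(mask)); rank[idx] <- seq_along(idx)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[seq_len(13L), , drop = FALSE]   # half-space of the 26
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    sh <- ns_shift3(mask, offs$dz[i], offs$dy[i], offs$dx[i])
    both <- which(mask & sh)
    if (!length(both)) next
    d <- dim(mask)
    src <- both - offs$dz[i] - offs$dy[i] * d[1] - offs$dx[i] * d[1] * d[2]
    edges[[length(edges) + 1L]] <- cbind(rank[src], rank[both])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment a raw 3-D channel into a binary surface mask
#'
#' Threshold-plus-components stand-in for commercial surface
#' reconstruction: voxels above an Otsu (or fixed) threshold are kept,
#' then 26-connected components smaller than `min_object_um3` are removed.
#'
#' @param raw numeric 3-D `(z, y, x)` array.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold required for `method = "fixed"`.
#' @param min_object_um3 minimum component volume retained.
#' @param voxel_size_um voxel edge lengths `c(dz, dy, dx)`.
#' @return A logical 3-D mask with attribute `threshold`.
#' @export
segment_volume <- function(raw, method = c("otsu", "fixed"),
                           fixed_threshold = NULL, min_object_um3 = 0,
                           voxel_size_um = c(0.5, 0.5, 0.5)) {
  method <- match.arg(method)
  ns_check(is.array(raw) && length(dim(raw)) == 3L,
           "`raw` must be a 3-D (z, y, x) array")
  if (method == "otsu") {
    ns_check(diff(range(raw)) > 0, "cannot Otsu-threshold a constant volume")
    x <- (raw - min(raw)) / diff(range(raw))
    flat <- matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])  # one global histogram
    thr01 <- EBImage::otsu(EBImage::Image(flat), range = c(0, 1), levels = 256L)
    thr <- min(raw) + thr01 * diff(range(raw))
  } else {
    ns_check(!is.null(fixed_threshold),
             "`fixed_threshold` is required for method = \"fixed\"")
    thr <- fixed_threshold
  }
  mask <- raw > thr
  if (min_object_um3 > 0 && any(mask)) {
    lab <- ns_label3d(mask)
    vol <- tabulate(lab[lab > 0L]) * ns_voxvol(voxel_size_um)
    keep <- which(vol >= min_object_um3)
    mask <- array(lab %in% keep, dim(mask))
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Colocalised volume of two marker masks
#'
#' @param a,b logical 3-D masks of the same shape.
#' @param voxel_size_um voxel edge lengths `c(dz, dy, dx)`.
#' @param pair optional `c(nameA, nameB)` carried into the output.
#' @return A one-row tibble: `pair`, `volume_um3` (volume of the
#'   intersection) and `pct_of_a` (percentage of `a`'s volume inside `b`;
#'   `NA` if `a` is empty).
#' @export
coloc_volume <- function(a, b, voxel_size_um = c(0.5, 0.5, 0.5),
                         pair = c("A", "B")) {
  ns_check(identical(dim(a), dim(b)), "masks differ in shape")
  vv <- ns_voxvol(voxel_size_um)
  inter <- sum(a & b)
  na <- sum(a)
  tibble(pair = paste(pair, collapse = ":"),
         volume_um3 = inter * vv,
         pct_of_a = if (na > 0) 100 * inter / na else NA_real_)
}

#' Engulfed axon volume (triple intersection)
#'
#' Volume of axonal signal inside lysosomes inside microglia: the voxel
#' intersection of the NET, CD68 and Iba1 masks.
#'
#' @param net,cd68,iba1 logical 3-D masks of the same shape.
#' @param voxel_size_um voxel edge lengths `c(dz, dy, dx)`.
#' @return Volume in cubic micrometres.
#' @export
engulfed_volume <- function(net, cd68, iba1,
                            voxel_size_um = c(0.5, 0.5, 0.5)) {
  ns_check(identical(dim(net), dim(cd68)) && identical(dim(net), dim(iba1)),
           "masks differ in shape")
  sum(net & cd68 & iba1) * ns_voxvol(voxel_size_um)
}

# ellipsoidal (physical-radius) binary dilation
ns_dilate3d <- function(mask, radius_um, voxel_size_um) {
  if (radius_um <= 0) return(mask)
  rv <- pmax(0L, round(radius_um / voxel_size_um))   # per-axis voxel radii
  offs <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  keep <- (offs$dz * voxel_size_um[1])^2 + (offs$dy * voxel_size_um[2])^2 +
    (offs$dx * voxel_size_um[3])^2 <= radius_um^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | ns_shift3(mask, offs$dz[i], offs$dy[i], offs$dx[i])
  }
  out
}

#' Contact volume between two markers
#'
#' Volume of the interface shell: the part of `net` reached by dilating
#' `iba1` outward by `dilation_um` that is not already direct overlap.
#' With `dilation_um = 0` this reduces to the plain colocalised volume.
#' Also reports the number of 26-connected interface components
#' ("contact points").
#'
#' @param iba1,net logical 3-D masks of the same shape.
#' @param dilation_um outward dilation radius in micrometres (>= 0).
#' @param voxel_size_um voxel edge lengths `c(dz, dy, dx)`.
#' @return A one-row tibble: `volume_um3`, `n_contacts`.
#' @export
contact_volume <- function(iba1, net, dilation_um = 0.5,
                           voxel_size_um = c(0.5, 0.5, 0.5)) {
  ns_check(identical(dim(iba1), dim(net)), "masks differ in shape")
  ns_check(dilation_um >= 0, "`dilation_um` must be >= 0")
  if (dilation_um == 0) {
    inter <- iba1 & net
  } else {
    inter <- ns_dilate3d(iba1, dilation_um, voxel_size_um) & net & !iba1
  }
  n_comp <- if (any(inter)) max(ns_label3d(inter)) else 0L
  tibble(volume_um3 = sum(inter) * ns_voxvol(voxel_size_um),
         n_contacts = n_comp)
}

#' Normalise a colocalised volume to axon density
#'
#' Divides a volume by the NET axon density (NET volume over the imaged
#' volume), so engulfment readouts are comparable between samples with
#' different axonal content.
#'
#' @param volume_um3 volume to normalise.
#' @param net_volume_um3 total NET mask volume (> 0).
#' @param total_volume_um3 imaged volume.
#' @return Dimensionless normalised volume.
#' @export
normalize_to_density <- function(volume_um3, net_volume_um3,
                                 total_volume_um3) {
  ns_check(net_volume_um3 > 0, "NET volume must be > 0")
  ns_check(total_volume_um3 > 0, "total volume must be > 0")
  volume_um3 / (net_volume_um3 / total_volume_um3)
}
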
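#' Percentile intensity normalisation
#'
#' Rescales an image so its 1st percentile maps to 0 and its 99th to 1
#' (clipped), a reproducible stand-in for manual brightness/contrast
#' adjustment before thresholding.
#'
#' @param img a [histo_image()] or numeric matrix.
#' @param probs lower/upper percentile pair (default `c(0.01, 0.99)`).
#' @return A numeric matrix in `[0, 1]`.
#' @export
normalize_percentile <- function(img, probs = c(0.01, 0.99)) {
  m <- if (inherits(img, "histo_image")) img$pixels else img
  q <- quantile(m, probs, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(m), ncol(m)))
  pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Threshold a stain image to a foreground mask
#'
#' Separates stained foreground from background either by Otsu's method
#' (on the percentile-normalised image) or at a user-supplied fixed
#' threshold on raw intensities. The threshold actually applied is
#' recorded in the result's `threshold` attribute.
#'
#' @param img a [histo_image()] or numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold raw-intensity cutoff, required for
#'   `method = "fixed"`; foreground is strictly above the threshold.
#' @param normalize percentile-normalise before Otsu (default `TRUE`).
#' @return A logical matrix with attribute `threshold`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, normalize = TRUE) {
  method <- match.arg(method)
  m <- if (inherits(img, "histo_image")) img$pixels else img
  ns_check(is.matrix(m), "image must be a matrix")
  if (method == "fixed") {
    ns_check(!is.null(fixed_threshold),
             "`fixed_threshold` is required for method = \"fixed\"")
    mask <- m > fixed_threshold
    attr(mask, "threshold") <- fixed_threshold
    return(mask)
  }
  ns_check(diff(range(m)) > 0, "cannot Otsu-threshold a constant image")
  x <- if (normalize) normalize_percentile(m) else {
    (m - min(m)) / diff(range(m))
  }
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  mask <- x > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Foreground area fraction of a mask
#'
#' The staining density readout: percentage of foreground pixels, over the
#' whole image or within a named region mask.
#'
#' @param mask logical foreground matrix (e.g. from [binarize()]).
#' @param region optional logical matrix restricting the denominator.
#' @return Area percentage in `[0, 100]`.
#' @export
area_fraction <- function(mask, region = NULL) {
  ns_check(is.matrix(mask), "`mask` must be a matrix")
  if (is.null(region)) return(100 * sum(mask) / length(mask))
  ns_check(identical(dim(region), dim(mask)), "region must match mask shape")
  ns_check(sum(region) > 0, "empty region")
  100 * sum(mask & region) / sum(region)
}

#' Per-layer staining densities of one image
#'
#' Applies [area_fraction()] within each of the image's named region masks
#' (e.g. olfactory-bulb layers). Layers must not overlap.
#'
#' @param img a [histo_image()] carrying `region_masks`.
#' @param mask optional precomputed foreground mask; by default the image
#'   is thresholded with [binarize()].
#' @param ... passed to [binarize()].
#' @return A tibble of density records: `animal_id`, `slice_id`, `region`,
#'   `value` (area %).
#' @export
layer_density <- function(img, mask = NULL, ...) {
  ns_check(inherits(img, "histo_image"), "`img` must be a histo_image")
  ns_check(!is.null(img$region_masks), "image carries no region masks")
  overlap <- Reduce(`+`, lapply(img$region_masks, function(m) m * 1L))
  ns_check(max(overlap) <= 1L, "region masks overlap")
  if (is.null(mask)) mask <- binarize(img, ...)
  purrr::imap(img$region_masks, function(rm, nm) {
    tibble(animal_id = img$animal_id, slice_id = img$slice_id,
           region = nm, value = area_fraction(mask, rm))
  }) %>% bind_rows()
}

#' Average slice densities to one value per animal
#'
#' @param records tibble of density records with at least `animal_id` and
#'   `value`; optional `group` and `region` columns are preserved.
#' @return A tibble with one row per animal (x region), column `mean_value`.
#' @export
animal_summary <- function(records) {
  ns_check(is.data.frame(records) && nrow(records) > 0,
           "`records` must be a non-empty data frame")
  grp_cols <- intersect(c("group", "animal_id", "region"), names(records))
  records %>%
    group_by(across(dplyr::all_of(grp_cols))) %>%
    summarise(n_slices = dplyr::n(), mean_value = mean(.data$value),
              .groups = "drop")
}

#' Relative density and loss between two groups
#'
#' Relative density is the case group's mean (of per-animal means)
#' expressed as a percentage of the control group's; loss is its
#' complement.
#'
#' @param case_means,control_means numeric vectors of per-animal mean
#'   densities.
#' @return A one-row tibble: `mean_control`, `mean_case`,
#'   `relative_density_pct`, `loss_pct`.
#' @export
relative_loss <- function(case_means, control_means) {
  ns_check(length(case_means) > 0 && length(control_means) > 0,
           "both groups must be non-empty")
  mc <- mean(control_means); mk <- mean(case_means)
  ns_check(mc > 0, "control mean must be > 0")
  rel <- 100 * mk / mc
  tibble(mean_control = mc, mean_case = mk,
         relative_density_pct = rel, loss_pct = 100 - rel)
}

#' Count stained objects per area
#'
#' Optional cell-count readout (e.g. microglia somata): thresholded
#' foreground is labelled by 8-connected components, components smaller
#' than `min_size_um2` are discarded, and the count is reported per mm^2.
#'
#' @param img a [histo_image()].
#' @param min_size_um2 minimum object area in square micrometres.
#' @param ... passed to [binarize()].
#' @return A one-row tibble: `n_objects`, `area_mm2`, `objects_per_mm2`.
#' @export
count_objects <- function(img, min_size_um2 = 0, ...) {
  ns_check(inherits(img, "histo_image"), "`img` must be a histo_image")
  mask <- binarize(img, ...)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(lab))
  min_px <- min_size_um2 / img$pixel_size_um^2
  n <- sum(sizes >= min_px & sizes > 0)
  area_mm2 <- length(mask) * img$pixel_size_um^2 / 1e6
  tibble(n_objects = n, area_mm2 = area_mm2, objects_per_mm2 = n / area_mm2)
}

#' Full fibre-density pipeline over a two-group cohort
#'
#' Thresholds each slice image, computes its area %, averages slices per
#' animal, and contrasts case against control with [relative_loss()].
#'
#' @param cohort tibble from [gen_fiber_cohort()] (or any tibble with
#'   `group`, `animal_id`, `slice_id` and a list-column `image`).
#' @param control,case group labels.
#' @param ... passed to [binarize()].
#' @return A list with `records` (per-slice densities), `animals`
#'   (per-animal means) and `contrast` (the [relative_loss()] row).
#' @export
histo_density <- function(cohort, control = "control", case = "case", ...) {
  ns_check(all(c("group", "animal_id", "image") %in% names(cohort)),
           "cohort needs `group`, `animal_id` and `image` columns")
  records <- cohort %>%
    mutate(value = purrr::map_dbl(.data$image,
                                  function(im) area_fraction(binarize(im, ...)))) %>%
    select(dplyr::any_of(c("group", "animal_id", "slice_id")), "value")
  animals <- animal_summary(records)
  contrast <- relative_loss(
    animals$mean_value[animals$group == case],
    animals$mean_value[animals$group == control]
  )
  list(records = records, animals = animals, contrast = contrast)
}
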
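#' Tidy a ROI trace set into long format
#'
#' @param x a `roi_trace_set`.
#' @param ... unused.
#' @return A tibble with `animal_id`, `fov_id`, `roi`, `label`, `frame`,
#'   `dff` — one row per ROI and frame.
#' @method tidy roi_trace_set
#' @export
tidy.roi_trace_set <- function(x, ...) {
  x %>%
    select("animal_id", "fov_id", "roi", "label", "trace") %>%
    mutate(frame = purrr::map(.data$trace, seq_along)) %>%
    rename(dff = "trace") %>%
    unnest(c("frame", "dff")) %>%
    select("animal_id", "fov_id", "roi", "label", "frame", "dff")
}

#' One-row summary of a ROI trace set
#'
#' @param x a `roi_trace_set`.
#' @param ... unused.
#' @return A one-row tibble: ROI count, class percentages and the
#'   classification dead-band `k` used.
#' @method glance roi_trace_set
#' @export
glance.roi_trace_set <- function(x, ...) {
  response_fractions(x) %>% mutate(k = attr(x, "k") %||% NA_real_)
}
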
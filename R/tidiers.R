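#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted state model into a long centroid table
#'
#' @param x A `dfc_state_model`.
#' @param ... Unused.
#' @return Tibble: `state`, `region_a`, `region_b`, `z`.
#' @export
tidy.dfc_state_model <- function(x, ...) {
  idx <- edge_index(x$n_regions)
  purrr::map_dfr(seq_len(x$k), function(s) {
    tibble(state = s,
           region_a = x$region_labels[idx[, 1L]],
           region_b = x$region_labels[idx[, 2L]],
           z = x$centroids[s, ])
  })
}

#' @rdname tidy.dfc_state_model
#' @return For `glance()`: one-row tibble with `k`, `inertia`,
#'   `n_windows`, `n_subjects`, `seed`.
#' @export
glance.dfc_state_model <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, n_windows = nrow(x$labels),
         n_subjects = length(unique(x$labels$subject_id)), seed = x$seed)
}

#' @rdname tidy.dfc_state_model
#' @param object A `dfc_state_model`.
#' @export
autoplot.dfc_state_model <- function(object, ...) {
  df <- tidy(object) |>
    mutate(state = sprintf("state %d (%.1f%%)", .data$state,
                           100 * object$occupancy[.data$state]))
  full <- bind_rows(df,
                    df |> rename(region_a = "region_b", region_b = "region_a"))
  ggplot2::ggplot(full, ggplot2::aes(.data$region_a, .data$region_b,
                                     fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_fill_gradient2(name = "z", low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, title = "Connectivity state centroids") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Tidy K-selection results
#'
#' @param x A `dfc_kselect`.
#' @param ... Unused.
#' @return The criterion curve tibble (`k`, `inertia`, `criterion_value`).
#' @export
tidy.dfc_kselect <- function(x, ...) x$curve

#' @rdname tidy.dfc_kselect
#' @export
glance.dfc_kselect <- function(x, ...) {
  tibble(k = x$k, criterion = x$criterion, flag = x$flag)
}

#' Tidy an NBS result into an edge table
#'
#' @param x A `dfc_nbs`.
#' @param ... Unused.
#' @return Tibble: `component`, `region_a`, `region_b`, `t`, `size`,
#'   `fwe_p` (empty when no suprathreshold edges exist).
#' @export
tidy.dfc_nbs <- function(x, ...) {
  if (length(x$components) == 0) {
    return(tibble(component = integer(0), region_a = character(0),
                  region_b = character(0), t = numeric(0),
                  size = integer(0), fwe_p = numeric(0)))
  }
  purrr::map_dfr(seq_along(x$components), function(i) {
    x$components[[i]] |>
      mutate(component = i, size = x$component_sizes[i], fwe_p = x$fwe_p[i],
             .before = 1L)
  })
}

#' @rdname tidy.dfc_nbs
#' @export
glance.dfc_nbs <- function(x, ...) {
  tibble(state = x$state, n_components = length(x$components),
         min_fwe_p = if (length(x$fwe_p) > 0) min(x$fwe_p) else NA_real_,
         edge_p = x$edge_p, n_perm = x$n_perm)
}

#' Tidy edgewise group statistics
#'
#' @param x A `dfc_edge_stats`.
#' @param ... Unused.
#' @return Tibble: `region_a`, `region_b`, `estimate`, `t`, `p`.
#' @export
tidy.dfc_edge_stats <- function(x, ...) {
  idx <- edge_index(x$n_regions)
  tibble(region_a = x$region_labels[idx[, 1L]],
         region_b = x$region_labels[idx[, 2L]],
         estimate = x$estimate, t = x$t, p = x$p)
}
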